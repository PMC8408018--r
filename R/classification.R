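MODEL_ORDER <- c("pwm", "dipwm", "markov", "pruned_markov")

PAIRWISE_LABELS <- c("only_A", "only_B", "intersection", "no_intersection",
                     "no_sites")

# do any two intervals from the two sets share >= 1 base (half-open)?
any_interval_overlap <- function(sa, ea, sb, eb) {
  for (i in seq_along(sa)) {
    if (any(sa[i] < eb & sb < ea[i])) return(TRUE)
  }
  FALSE
}

#' Pairwise peak classification with positional intersection
#'
#' For one pair of models, labels every peak as one of: `no_sites` (neither
#' model has a hit), `only_A` / `only_B` (one model only), `intersection`
#' (both models have hits and at least one pair of hits shares at least one
#' base position), or `no_intersection` (both have hits but no two hits
#' overlap). Intersection is strand-agnostic; intervals are half-open, so
#' adjacent hits do not intersect.
#'
#' @param hits_A,hits_B hit data.frames (from [scan_peaks()], one model
#'   each).
#' @param peak_ids character vector of all peak identifiers (the label
#'   universe — peaks without hits are labelled `no_sites`).
#' @return factor of labels, one per peak, levels
#'   `only_A, only_B, intersection, no_intersection, no_sites`.
#' @export
classify_pair <- function(hits_A, hits_B, peak_ids) {
  a_by <- split(hits_A[, c("start", "end")], hits_A$peak_id)
  b_by <- split(hits_B[, c("start", "end")], hits_B$peak_id)
  lab <- vapply(peak_ids, function(p) {
    a <- a_by[[p]]
    b <- b_by[[p]]
    if (is.null(a) && is.null(b)) return("no_sites")
    if (is.null(b)) return("only_A")
    if (is.null(a)) return("only_B")
    if (any_interval_overlap(a$start, a$end, b$start, b$end)) {
      "intersection"
    } else {
      "no_intersection"
    }
  }, character(1))
  factor(unname(lab), levels = PAIRWISE_LABELS)
}

#' Combinatorial (Venn) peak classification
#'
#' Labels every peak by the subset of models with at least one hit in it,
#' ignoring positions. All 2^k subsets are possible, including the empty
#' subset (peak recognised by no model).
#'
#' @param hits hit data.frame over all models (from [scan_peaks()]).
#' @param peak_ids all peak identifiers.
#' @param models model names defining the subset universe.
#' @return list with `labels` (character vector per peak: models joined by
#'   `+`, `""` for the empty subset) and `venn` (data.frame `subset`,
#'   `count` over all 2^k subsets).
#' @export
classify_combinatorial <- function(hits, peak_ids,
                                   models = intersect(MODEL_ORDER,
                                                      unique(hits$model))) {
  if (length(models) == 0L) models <- MODEL_ORDER
  per_peak <- split(hits$model, hits$peak_id)
  labels <- vapply(peak_ids, function(p) {
    present <- intersect(models, unique(per_peak[[p]]))
    paste(present, collapse = "+")
  }, character(1))
  labels <- unname(labels)
  # enumerate all subsets in canonical model order
  k <- length(models)
  subsets <- unlist(lapply(0:k, function(sz) {
    if (sz == 0L) return("")
    combn(models, sz, paste, collapse = "+")
  }))
  venn <- data.frame(subset = subsets,
                     count = as.integer(table(factor(labels,
                                                     levels = subsets))),
                     stringsAsFactors = FALSE)
  list(labels = labels, venn = venn)
}

#' Fraction summary of classification categories
#'
#' Converts category counts (or per-peak labels) into percentages of the
#' total peak count. Percentages are exact (`100 * count / total`); report
#' writers round for display only.
#'
#' @param x either a named numeric vector of category counts or a vector of
#'   per-peak labels to tabulate.
#' @param total total peak count.
#' @return data.frame with `category`, `count`, `fraction` (percent).
#' @export
summarize_fractions <- function(x, total) {
  stopifnot(total >= 1)
  if (is.numeric(x)) {
    counts <- x
    if (is.null(names(counts))) {
      names(counts) <- paste0("category_", seq_along(counts))
    }
  } else {
    tab <- table(x)
    counts <- as.numeric(tab)
    names(counts) <- names(tab)
  }
  data.frame(category = names(counts), count = as.numeric(counts),
             fraction = 100 * as.numeric(counts) / total,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate fractions of a combinatorial classification
#'
#' Derived summaries of a Venn count table: the recognised fraction
#' (non-empty subset), the all-models overlap, and each single-model-only
#' contribution.
#'
#' @param venn Venn count data.frame from [classify_combinatorial()].
#' @param total total peak count.
#' @param models model names.
#' @return data.frame (`category`, `count`, `fraction`).
#' @export
venn_aggregates <- function(venn, total,
                            models = MODEL_ORDER) {
  recognized <- sum(venn$count[venn$subset != ""])
  all_models <- venn$count[venn$subset == paste(models, collapse = "+")]
  if (length(all_models) == 0L) all_models <- 0L
  counts <- c(recognized = recognized, all_models = all_models,
              setNames(vapply(models, function(m) {
                v <- venn$count[venn$subset == m]
                if (length(v) == 0L) 0L else v
              }, integer(1)), paste0("only_", models)))
  summarize_fractions(counts, total)
}

#' Extract the aligned sites of one classification category
#'
#' For every peak carrying a given combinatorial label, takes the
#' best-scoring hit of the requested model and cuts the corresponding L-bp
#' site out of the peak sequence (reverse-complemented for minus-strand
#' hits). The alignment feeds [frequency_matrix_from_sites()] for logo and
#' matrix export.
#'
#' @param labels per-peak combinatorial labels
#'   (from [classify_combinatorial()]).
#' @param peak_ids peak identifiers aligned with `labels`.
#' @param hits hit data.frame.
#' @param peak_seqs named character vector of peak sequences.
#' @param category the label to select (e.g. `"markov"` for
#'   the only-Markov fraction, or the full join for the all-models
#'   fraction).
#' @param model which model's hits to extract sites from.
#' @return character vector of sites (possibly empty, with a warning).
#' @export
per_fraction_sites <- function(labels, peak_ids, hits, peak_seqs, category,
                               model) {
  sel <- peak_ids[labels == category]
  if (length(sel) == 0L) {
    warning("category '", category, "' is empty")
    return(character(0))
  }
  h <- hits[hits$model == model & hits$peak_id %in% sel, , drop = FALSE]
  sites <- character(0)
  for (p in unique(h$peak_id)) {
    hp <- h[h$peak_id == p, , drop = FALSE]
    best <- hp[which.max(hp$score), , drop = FALSE]
    site <- substr(peak_seqs[[p]], best$start + 1L, best$end)
    if (best$strand == "-") site <- revcomp(site)
    if (!grepl("[^ACGT]", site)) sites <- c(sites, site)
  }
  sites
}

#' Classify peaks for all unordered model pairs
#'
#' Runs [classify_pair()] for each of the `choose(k, 2)` model pairs.
#'
#' @param hits hit data.frame over all models.
#' @param peak_ids all peak identifiers.
#' @param models model names.
#' @return named list of label factors, one per pair (`"A.vs.B"`).
#' @export
classify_all_pairs <- function(hits, peak_ids,
                               models = intersect(MODEL_ORDER,
                                                  unique(hits$model))) {
  if (length(models) < 2L) stop("need at least two models")
  prs <- combn(models, 2L)
  out <- list()
  for (k in seq_len(ncol(prs))) {
    a <- prs[1L, k]; b <- prs[2L, k]
    out[[paste0(a, ".vs.", b)]] <- classify_pair(
      hits[hits$model == a, , drop = FALSE],
      hits[hits$model == b, , drop = FALSE], peak_ids)
  }
  out
}
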