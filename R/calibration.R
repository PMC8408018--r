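#' Score a background sequence set at every position and strand
#'
#' The empirical null used for threshold calibration: every window position
#' on both strands of every background (promoter) sequence is scored; windows
#' containing N are skipped and do not count as available positions.
#'
#' @param model trained motif model.
#' @param promoters character vector of background sequences (e.g. 2000-bp
#'   regions upstream of transcription start sites).
#' @return list with `scores` (numeric vector over all scorable positions,
#'   both strands) and `n_positions = length(scores)`.
#' @export
background_scores <- function(model, promoters) {
  out <- vector("list", length(promoters))
  for (i in seq_along(promoters)) {
    if (nchar(promoters[[i]]) < model$L) {
      warning("background sequence ", i, " shorter than model length ",
              model$L, "; contributes no scores")
      next
    }
    sc <- scan_scores(model, promoters[[i]])
    out[[i]] <- c(sc$fwd, sc$rev)
  }
  scores <- unlist(out, use.names = FALSE)
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) stop("no scorable background positions")
  list(scores = scores, n_positions = length(scores))
}

#' Select a score threshold at a target false positive rate
#'
#' The FPR of a candidate threshold `t` is the fraction of background
#' positions scoring `>= t`. The selected threshold is the smallest unique
#' observed score whose FPR does not exceed `target_fpr` — the
#' sensitivity-maximising choice subject to the bound — so the achieved FPR
#' re-measured on the same background equals the reported value exactly.
#'
#' @param scores background score multiset from [background_scores()] (the
#'   `scores` element, or the list itself).
#' @param target_fpr target per-position false positive rate
#'   (default 1.9e-4).
#' @return list with `threshold`, `achieved_fpr`, `n_positions`.
#' @export
select_threshold <- function(scores, target_fpr = 1.9e-4) {
  if (is.list(scores)) scores <- scores$scores
  stopifnot(length(scores) > 0L, target_fpr > 0, target_fpr <= 1)
  n <- length(scores)
  if (1 / n > target_fpr) {
    stop("background too small for target FPR: minimum attainable FPR is 1/",
         n, " = ", signif(1 / n, 3), " > ", target_fpr)
  }
  uniq <- sort(unique(scores))            # ascending
  # count of scores >= each unique value: reverse cumulative of counts
  cnt <- tabulate(match(scores, uniq), nbins = length(uniq))
  ge <- rev(cumsum(rev(cnt)))
  fpr <- ge / n
  ok <- which(fpr <= target_fpr)          # fpr is non-increasing in t
  if (length(ok) == 0L) {
    stop("no threshold attains FPR <= ", target_fpr)
  }
  i <- ok[1L]                             # smallest qualifying threshold
  list(threshold = uniq[i], achieved_fpr = fpr[i], n_positions = n)
}

#' Calibrate every model of a bundle to a common background FPR
#'
#' @param bundle a [model_bundle()] of trained models.
#' @param promoters background sequences.
#' @param target_fpr common target per-position FPR.
#' @return the bundle with `thresholds` filled in, plus a `threshold_table`
#'   data.frame (model, threshold, achieved_fpr, n_background_positions).
#' @export
calibrate_bundle <- function(bundle, promoters, target_fpr = 1.9e-4) {
  stopifnot(inherits(bundle, "model_bundle"))
  tab <- do.call(rbind, lapply(names(bundle$models), function(nm) {
    bg <- background_scores(bundle$models[[nm]], promoters)
    th <- select_threshold(bg$scores, target_fpr)
    data.frame(model = nm, threshold = th$threshold,
               achieved_fpr = th$achieved_fpr,
               n_background_positions = th$n_positions,
               stringsAsFactors = FALSE)
  }))
  bundle$thresholds <- setNames(tab$threshold, tab$model)
  bundle$target_fpr <- target_fpr
  bundle$threshold_table <- tab
  bundle
}

#' FPR calibration curve for one model
#'
#' Threshold-versus-FPR over all unique background scores, for plotting or
#' export.
#'
#' @param model trained motif model.
#' @param promoters background sequences.
#' @return data.frame with `threshold` (ascending) and `fpr`
#'   (non-increasing).
#' @export
calibration_curve <- function(model, promoters) {
  scores <- background_scores(model, promoters)$scores
  uniq <- sort(unique(scores))
  cnt <- tabulate(match(scores, uniq), nbins = length(uniq))
  ge <- rev(cumsum(rev(cnt)))
  data.frame(threshold = uniq, fpr = ge / length(scores))
}

#' Scan peaks with a calibrated model bundle
#'
#' Scores every window on both strands of every peak sequence under every
#' model and emits each window whose score is greater than or equal to the
#' model's threshold (matching the FPR definition used in calibration).
#' Overlapping hits are all reported.
#'
#' @param bundle calibrated bundle (see [calibrate_bundle()]).
#' @param peak_seqs named character vector of peak sequences.
#' @return data.frame of hits with columns `peak_id`, `model`, `start`,
#'   `end` (0-based half-open offsets within the peak), `strand`, `score`,
#'   sorted by (peak, model, start, strand).
#' @export
scan_peaks <- function(bundle, peak_seqs) {
  stopifnot(inherits(bundle, "model_bundle"))
  if (is.null(bundle$thresholds)) {
    stop("bundle has no thresholds; run calibrate_bundle() first")
  }
  if (is.null(names(peak_seqs))) {
    names(peak_seqs) <- paste0("peak_", seq_along(peak_seqs))
  }
  rows <- list()
  for (nm in names(bundle$models)) {
    model <- bundle$models[[nm]]
    thr <- bundle$thresholds[[nm]]
    L <- model$L
    for (pid in names(peak_seqs)) {
      if (nchar(peak_seqs[[pid]]) < L) next
      sc <- scan_scores(model, peak_seqs[[pid]])
      for (strand in c("+", "-")) {
        s <- if (strand == "+") sc$fwd else sc$rev
        hit <- which(!is.na(s) & s >= thr)
        if (length(hit) == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
          peak_id = pid, model = nm, start = hit - 1L,
          end = hit - 1L + L, strand = strand, score = s[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(peak_id = character(), model = character(),
                      start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, rows)
  hits <- hits[order(match(hits$peak_id, names(peak_seqs)),
                     hits$model, hits$start, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

#' Convert peak-relative hits to genome-coordinate BED6 records
#'
#' @param hits hit data.frame from [scan_peaks()].
#' @param peaks peak data.frame (genome coordinates; `name` must cover every
#'   `peak_id` in `hits`).
#' @return data.frame in BED6 layout: chrom, start, end, name
#'   (`<peak>:<model>`), score, strand.
#' @export
hits_to_bed <- function(hits, peaks) {
  if (nrow(hits) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  miss <- setdiff(hits$peak_id, peaks$name)
  if (length(miss) > 0L) {
    stop("unresolvable peak id(s): ", paste(head(miss, 3), collapse = ", "))
  }
  i <- match(hits$peak_id, peaks$name)
  data.frame(chrom = peaks$chrom[i],
             start = peaks$start[i] + hits$start,
             end = peaks$start[i] + hits$end,
             name = paste0(hits$peak_id, ":", hits$model),
             score = hits$score,
             strand = hits$strand,
             stringsAsFactors = FALSE)
}

#' Write hits as a BED6 file
#'
#' @param bed BED6 data.frame from [hits_to_bed()] (or peak-relative hits).
#' @param path output path.
#' @export
write_bed <- function(bed, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chrom\tstart\tend\tname\tscore\tstrand", con)
  if (nrow(bed) > 0L) {
    write.table(bed, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}
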