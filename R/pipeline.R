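#' Pipeline configuration
#'
#' Paths and parameters of the five-stage pipeline: data preparation, model
#' building, accuracy assessment, threshold selection and site search, and
#' peak classification.
#'
#' @param peaks path to a peaks BED file (optional if `sequences` given).
#' @param genome path to a genome FASTA (needed with `peaks` unless
#'   `sequences` is given).
#' @param sequences path to a peak-sequence FASTA (alternative to
#'   `peaks` + `genome`; BED scores may still order peaks when both given).
#' @param promoters path to the background FASTA used for calibration.
#' @param reference_pfm optional path to a reference frequency matrix for
#'   the enrichment filter.
#' @param out output (run) directory.
#' @param n_top_peaks number of top-scoring peaks analysed.
#' @param target_fpr calibration false positive rate.
#' @param fpr_max pAUC integration bound.
#' @param length_grid candidate motif lengths; a single value skips length
#'   selection.
#' @param markov_order Markov model order.
#' @param cv_repeats cross-validation repeats.
#' @param n_seeds,seed_k,occupancy,em_max_iter,em_tol discovery settings
#'   (see [discovery_config()]).
#' @param seed master RNG seed; every downstream seed derives from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(peaks = NULL, genome = NULL, sequences = NULL,
                            promoters = NULL, reference_pfm = NULL,
                            out = "multimotif_run", n_top_peaks = 4000L,
                            target_fpr = 1.9e-4, fpr_max = 0.001,
                            length_grid = c(8, 10, 12, 14, 16, 18, 20),
                            markov_order = 2L, cv_repeats = 10L,
                            n_seeds = 5L, seed_k = 7L, occupancy = 0.8,
                            em_max_iter = 100L, em_tol = 1e-4, seed = 1L) {
  structure(list(peaks = peaks, genome = genome, sequences = sequences,
                 promoters = promoters, reference_pfm = reference_pfm,
                 out = out, n_top_peaks = as.integer(n_top_peaks),
                 target_fpr = target_fpr, fpr_max = fpr_max,
                 length_grid = as.integer(length_grid),
                 markov_order = as.integer(markov_order),
                 cv_repeats = as.integer(cv_repeats),
                 n_seeds = as.integer(n_seeds), seed_k = as.integer(seed_k),
                 occupancy = occupancy,
                 em_max_iter = as.integer(em_max_iter), em_tol = em_tol,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

as_discovery_config <- function(config) {
  discovery_config(length_grid = config$length_grid,
                   em_max_iter = config$em_max_iter, em_tol = config$em_tol,
                   n_seeds = config$n_seeds, seed_k = config$seed_k,
                   occupancy = config$occupancy,
                   markov_order = config$markov_order,
                   seed = config$seed)
}

PIPELINE_STAGES <- c("prepare", "discover", "evaluate", "calibrate", "scan",
                     "classify", "compare")

stage_prereqs <- list(
  prepare = character(0),
  discover = "prepared_sequences.fasta",
  evaluate = c("prepared_sequences.fasta", "length_selection.tsv"),
  calibrate = "bundle.rds",
  scan = c("bundle_calibrated.rds", "prepared_sequences.fasta"),
  classify = "hits.tsv",
  compare = "bundle.rds")

check_prereqs <- function(stage, out) {
  need <- stage_prereqs[[stage]]
  for (f in need) {
    if (!file.exists(file.path(out, f))) {
      prior <- switch(f,
                      "prepared_sequences.fasta" = "prepare",
                      "length_selection.tsv" = "discover",
                      "bundle.rds" = "discover",
                      "bundle_calibrated.rds" = "calibrate",
                      "hits.tsv" = "scan")
      stop("stage '", stage, "' requires output of stage '", prior,
           "' (missing ", f, ")")
    }
  }
}

#' Run a single pipeline stage
#'
#' Recomputes one stage from the cached outputs of its prerequisite stages
#' in the run directory, enabling resumable and partial re-runs (e.g.
#' re-calibrating at a new FPR without re-training).
#'
#' @param stage one of `prepare`, `discover`, `evaluate`, `calibrate`,
#'   `scan`, `classify`, `compare`.
#' @param config a [pipeline_config()].
#' @return invisibly, the stage's primary result.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  check_prereqs(stage, out)
  switch(stage,
         prepare = stage_prepare(config),
         discover = stage_discover(config),
         evaluate = stage_evaluate(config),
         calibrate = stage_calibrate(config),
         scan = stage_scan(config),
         classify = stage_classify(config),
         compare = stage_compare(config))
}

stage_prepare <- function(config) {
  out <- config$out
  if (!is.null(config$sequences)) {
    if (!file.exists(config$sequences)) {
      stop("sequence FASTA not found: ", config$sequences)
    }
    seqs <- read_fasta(config$sequences)
    if (!is.null(config$peaks)) {
      peaks <- read_bed_peaks(config$peaks)
      peaks <- select_top_peaks(peaks, config$n_top_peaks)
      seqs <- seqs[intersect(peaks$name, names(seqs))]
    } else {
      peaks <- data.frame(chrom = names(seqs), start = 0L,
                          end = nchar(seqs), name = names(seqs),
                          score = 0, stringsAsFactors = FALSE)
      peaks <- head(peaks, config$n_top_peaks)
      seqs <- head(seqs, config$n_top_peaks)
    }
  } else {
    if (is.null(config$peaks) || is.null(config$genome)) {
      stop("need either 'sequences' or both 'peaks' and 'genome'")
    }
    peaks <- read_bed_peaks(config$peaks)
    peaks <- select_top_peaks(peaks, config$n_top_peaks)
    seqs <- extract_sequences(config$genome, peaks)
    peaks <- peaks[peaks$name %in% names(seqs), , drop = FALSE]
  }
  write.table(peaks, file.path(out, "prepared_peaks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fasta(seqs, file.path(out, "prepared_sequences.fasta"))
  invisible(seqs)
}

load_prepared <- function(config) {
  list(seqs = read_fasta(file.path(config$out, "prepared_sequences.fasta")),
       peaks = read.table(file.path(config$out, "prepared_peaks.tsv"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE))
}

stage_discover <- function(config) {
  out <- config$out
  seqs <- load_prepared(config)$seqs
  cfg <- as_discovery_config(config)
  if (length(cfg$length_grid) > 1L) {
    sel <- select_optimal_length(seqs, cfg,
                                 repeats = min(config$cv_repeats, 5L),
                                 fpr_max = config$fpr_max)
    L <- sel$L
    tab <- sel$table
  } else {
    L <- cfg$length_grid[1L]
    tab <- data.frame(length = L, mean_pauc = NA_real_, sd_pauc = NA_real_,
                      n_repeats = 0L)
  }
  write.table(tab, file.path(out, "length_selection.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  bundle <- train_all_models(seqs, L, cfg)
  saveRDS(bundle, file.path(out, "bundle.rds"))
  write_fasta(setNames(bundle$alignment$sites,
                       paste0(bundle$alignment$peak_id, "_site")),
              file.path(out, "sites.fasta"))
  pfm <- frequency_matrix_from_sites(bundle$alignment$sites)
  write_pfm_meme(pfm, file.path(out, "discovered_pfm.meme"),
                 name = consensus_string(pfm),
                 nsites = length(bundle$alignment$sites))
  write_pfm_tsv(pfm, file.path(out, "discovered_pfm.tsv"))
  write_markov_model(bundle$models$markov,
                     file.path(out, "markov_model.txt"))
  write_markov_model(bundle$models$pruned_markov,
                     file.path(out, "pruned_markov_model.txt"))
  invisible(bundle)
}

stage_evaluate <- function(config) {
  out <- config$out
  seqs <- load_prepared(config)$seqs
  cfg <- as_discovery_config(config)
  tab <- read.table(file.path(out, "length_selection.tsv"), header = TRUE,
                    sep = "\t")
  L <- if (all(is.na(tab$mean_pauc))) tab$length[1L] else
    tab$length[which.max(tab$mean_pauc)]
  rows <- list()
  for (r in seq_len(config$cv_repeats)) {
    rep_seed <- derive_seed(config$seed, 7000L + r)
    rng <- local_rng(rep_seed)
    idx <- sample(length(seqs), max(1L, floor(0.9 * length(seqs))))
    rng()
    train <- seqs[idx]
    ctrl <- seqs[-idx]
    cfg2 <- cfg
    cfg2$seed <- rep_seed
    bundle <- tryCatch(train_all_models(train, L, cfg2),
                       error = function(e) NULL)
    if (is.null(bundle)) {
      warning("evaluation repeat ", r, " skipped")
      next
    }
    negs <- vapply(seq_along(ctrl), function(i) {
      shuffle_sequence(ctrl[[i]], derive_seed(rep_seed, 100000L + i))
    }, character(1))
    for (nm in names(bundle$models)) {
      model <- bundle$models[[nm]]
      pos <- vapply(ctrl, function(s) best_sequence_score(model, s),
                    numeric(1))
      neg <- vapply(negs, function(s) best_sequence_score(model, s),
                    numeric(1))
      pa <- partial_auc(roc_curve(pos, neg), config$fpr_max)
      rows[[length(rows) + 1L]] <- data.frame(model = nm, repeat_ = r,
                                              pauc = pa$pauc)
    }
  }
  tab <- do.call(rbind, rows)
  write.table(tab, file.path(out, "evaluation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(tab)
}

stage_calibrate <- function(config) {
  out <- config$out
  if (is.null(config$promoters) || !file.exists(config$promoters)) {
    stop("promoter background FASTA not found: ",
         config$promoters %||% "<missing>")
  }
  bundle <- readRDS(file.path(out, "bundle.rds"))
  promoters <- read_fasta(config$promoters)
  bundle <- calibrate_bundle(bundle, promoters, config$target_fpr)
  write.table(bundle$threshold_table, file.path(out, "thresholds.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  curve <- calibration_curve(bundle$models$pwm, promoters)
  write.table(curve, file.path(out, "calibration_curve_pwm.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  saveRDS(bundle, file.path(out, "bundle_calibrated.rds"))
  invisible(bundle)
}

stage_scan <- function(config) {
  out <- config$out
  bundle <- readRDS(file.path(out, "bundle_calibrated.rds"))
  prep <- load_prepared(config)
  hits <- scan_peaks(bundle, prep$seqs)
  write.table(hits, file.path(out, "hits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (nm in names(bundle$models)) {
    h <- hits[hits$model == nm, , drop = FALSE]
    bed <- hits_to_bed(h, prep$peaks)
    write_bed(bed, file.path(out, paste0("hits_", nm, ".bed")))
  }
  invisible(hits)
}

stage_classify <- function(config) {
  out <- config$out
  hits <- read.table(file.path(out, "hits.tsv"), header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  prep <- load_prepared(config)
  peak_ids <- names(prep$seqs)
  total <- length(peak_ids)
  models <- MODEL_ORDER
  comb <- classify_combinatorial(hits, peak_ids, models)
  pair_labels <- classify_all_pairs(hits, peak_ids, models)
  per_peak <- data.frame(peak_id = peak_ids,
                         combinatorial = comb$labels,
                         stringsAsFactors = FALSE)
  for (nm in names(pair_labels)) {
    per_peak[[nm]] <- as.character(pair_labels[[nm]])
  }
  write.table(per_peak, file.path(out, "peak_labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  venn <- comb$venn
  venn$fraction <- fmt_fraction(100 * venn$count / total)
  write.table(venn, file.path(out, "venn_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  agg <- venn_aggregates(comb$venn, total, models)
  agg$fraction <- fmt_fraction(agg$fraction)
  write.table(agg, file.path(out, "fraction_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  pw_rows <- lapply(names(pair_labels), function(nm) {
    s <- summarize_fractions(pair_labels[[nm]], total)
    s$pair <- nm
    s
  })
  pw <- do.call(rbind, pw_rows)
  pw$fraction <- fmt_fraction(pw$fraction)
  write.table(pw[, c("pair", "category", "count", "fraction")],
              file.path(out, "pairwise_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  # per-fraction site alignments for the single-model and all-model groups
  for (cat in c(models, paste(models, collapse = "+"))) {
    model <- if (cat %in% models) cat else models[1L]
    sites <- suppressWarnings(
      per_fraction_sites(comb$labels, peak_ids, hits, prep$seqs, cat, model))
    if (length(sites) > 0L) {
      safe <- gsub("\\+", "_", cat)
      write_pfm_tsv(frequency_matrix_from_sites(sites),
                    file.path(out, paste0("fraction_pfm_", safe, ".tsv")))
    }
  }
  invisible(list(combinatorial = comb, pairwise = pair_labels))
}

# percentages printed with up to 3 decimals, trailing zeros trimmed
fmt_fraction <- function(x) {
  sub("\\.?0+$", "", sprintf("%.3f", x))
}

stage_compare <- function(config) {
  out <- config$out
  if (is.null(config$reference_pfm)) {
    stop("no reference_pfm configured for the comparison stage")
  }
  bundle <- readRDS(file.path(out, "bundle.rds"))
  query <- frequency_matrix_from_sites(bundle$alignment$sites)
  reference <- read_pfm(config$reference_pfm)
  res <- comparison_pvalue(query, reference, n_perm = 9999L,
                           seed = derive_seed(config$seed, 42L))
  tab <- data.frame(best_similarity = res$best_similarity,
                    best_offset = res$best_offset,
                    orientation = res$orientation, p_value = res$p_value,
                    enriched = res$passed)
  write.table(tab, file.path(out, "comparison.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(res)
}

#' Run the full pipeline
#'
#' Executes all stages in order — prepare, discover, evaluate, calibrate,
#' scan, classify and (when a reference matrix is configured) compare —
#' and writes a JSON run manifest. A fixed seed makes the whole run
#' byte-reproducible.
#'
#' @param config a [pipeline_config()].
#' @param evaluate whether to run the (expensive) cross-validation stage.
#' @return invisibly, the run directory path.
#' @export
run_full_pipeline <- function(config, evaluate = TRUE) {
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (f in c(config$peaks, config$genome, config$sequences,
              config$promoters, config$reference_pfm)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  }
  stages <- c("prepare", "discover",
              if (evaluate) "evaluate",
              "calibrate", "scan", "classify",
              if (!is.null(config$reference_pfm)) "compare")
  counts <- list()
  for (st in stages) {
    message("[multimotif] stage: ", st)
    res <- run_stage(st, config)
    counts[[st]] <- if (is.data.frame(res)) nrow(res) else
      if (is.character(res)) length(res) else NA
  }
  enriched <- NA
  cmp <- file.path(out, "comparison.tsv")
  if (file.exists(cmp)) {
    enriched <- read.table(cmp, header = TRUE, sep = "\t")$enriched[1L]
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("multimotif")),
    seed = config$seed,
    config = Filter(Negate(is.null), unclass(config)),
    stage_row_counts = counts,
    enriched = enriched)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(out)
}
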