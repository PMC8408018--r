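#' Best window score of a sequence under a model
#'
#' Maximum score over all window positions and both strands — the
#' per-sequence classification score used in ROC evaluation.
#'
#' @param model trained motif model.
#' @param seq DNA string.
#' @return numeric scalar; `-Inf` if no window is scorable.
#' @export
best_sequence_score <- function(model, seq) {
  sc <- scan_scores(model, seq)
  v <- c(sc$fwd, sc$rev)
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(-Inf)
  max(v)
}

#' Empirical ROC curve from positive and negative scores
#'
#' Sweeps all distinct scores as thresholds (descending); at each threshold
#' `t`, TPR is the fraction of positives scoring `>= t` and FPR the fraction
#' of negatives scoring `>= t`. Equal scores move in one step, so ties are
#' handled jointly. The curve starts at (0, 0) and ends at (1, 1).
#'
#' @param pos_scores per-sequence scores of the positive set.
#' @param neg_scores per-sequence scores of the negative set.
#' @return object of class `roc_curve`: data.frame with `fpr`
#'   (non-decreasing) and `tpr`.
#' @export
roc_curve <- function(pos_scores, neg_scores) {
  stopifnot(length(pos_scores) > 0L, length(neg_scores) > 0L)
  thr <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos_scores >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg_scores >= t), numeric(1))
  out <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (out$fpr[nrow(out)] != 1 || out$tpr[nrow(out)] != 1) {
    out <- rbind(out, data.frame(fpr = 1, tpr = 1))
  }
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Partial area under a ROC curve
#'
#' Trapezoidal area of TPR over FPR on `[0, fpr_max]`, with a point
#' linearly interpolated exactly at `fpr_max`. Reported raw (not
#' normalised), so a perfect classifier attains `fpr_max` and a random one
#' `fpr_max^2 / 2`.
#'
#' @param roc a [roc_curve()].
#' @param fpr_max integration bound (default 0.001).
#' @return list of class `pauc_result`: `pauc`, `fpr_max`.
#' @export
partial_auc <- function(roc, fpr_max = 0.001) {
  stopifnot(fpr_max > 0, fpr_max <= 1)
  x <- roc$fpr
  y <- roc$tpr
  # interpolate TPR at fpr_max and truncate
  if (!any(x == fpr_max)) {
    i <- which(x > fpr_max)[1L]
    if (!is.na(i)) {
      x0 <- x[i - 1L]; x1 <- x[i]
      y0 <- y[i - 1L]; y1 <- y[i]
      yi <- if (x1 == x0) y0 else y0 + (y1 - y0) * (fpr_max - x0) / (x1 - x0)
      x <- c(x[seq_len(i - 1L)], fpr_max)
      y <- c(y[seq_len(i - 1L)], yi)
    }
  } else {
    keep <- x <= fpr_max
    x <- x[keep]; y <- y[keep]
  }
  pauc <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  structure(list(pauc = pauc, fpr_max = fpr_max), class = "pauc_result")
}

#' Cross-validate a training procedure against shuffled negatives
#'
#' Repeats a 90/10 split: train on 90 per cent of the peaks, score the
#' held-out 10 per cent (positives) and one mononucleotide-shuffled copy of
#' each held-out peak (negatives) by best window score over positions and
#' strands, and record the partial AUC.
#'
#' @param seqs peak sequences (>= 20).
#' @param trainer function(train_seqs, seed) returning a trained model (see
#'   [pwm_trainer()]).
#' @param repeats number of random splits.
#' @param seed RNG seed; results are bit-reproducible for a fixed seed.
#' @param fpr_max pAUC bound.
#' @param train_fraction fraction of peaks used for training.
#' @return list of `pauc_result`, one per surviving repeat (each also
#'   carries its `roc`).
#' @export
cross_validate <- function(seqs, trainer, repeats = 10L, seed = 1L,
                           fpr_max = 0.001, train_fraction = 0.9) {
  stopifnot(length(seqs) >= 20L)
  if (is.null(names(seqs))) names(seqs) <- paste0("peak_", seq_along(seqs))
  out <- list()
  n <- length(seqs)
  n_train <- max(1L, floor(train_fraction * n))
  for (r in seq_len(repeats)) {
    rep_seed <- derive_seed(seed, r)
    rng <- local_rng(rep_seed)
    idx <- sample(n, n_train)
    rng()
    train <- seqs[idx]
    ctrl <- seqs[-idx]
    model <- tryCatch(trainer(train, rep_seed), error = function(e) {
      warning("repeat ", r, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(model)) next
    pos <- vapply(ctrl, function(s) best_sequence_score(model, s), numeric(1))
    neg <- vapply(seq_along(ctrl), function(i) {
      best_sequence_score(model,
                          shuffle_sequence(ctrl[[i]],
                                           derive_seed(rep_seed, 100000L + i)))
    }, numeric(1))
    roc <- roc_curve(pos, neg)
    pa <- partial_auc(roc, fpr_max)
    pa$roc <- roc
    out[[length(out) + 1L]] <- pa
  }
  if (length(out) < repeats / 2) {
    stop("fewer than half the cross-validation repeats survived")
  }
  out
}

#' Cross-dataset model transfer matrix
#'
#' Cell (i, j) holds the pAUC of the model trained on dataset i evaluated on
#' dataset j. Diagonal cells use the 90/10 cross-validation protocol (mean
#' pAUC); off-diagonal cells train on the full dataset i and evaluate on the
#' full dataset j against shuffled negatives — no split is needed because no
#' peak is shared between training and evaluation.
#'
#' @param datasets named list of peak-sequence sets.
#' @param trainer function(train_seqs, seed) -> model.
#' @param repeats diagonal cross-validation repeats.
#' @param seed RNG seed.
#' @param fpr_max pAUC bound.
#' @return numeric matrix (train x eval) with dataset names; failed cells
#'   are `NA`.
#' @export
transfer_matrix <- function(datasets, trainer, repeats = 5L, seed = 1L,
                            fpr_max = 0.001) {
  nd <- length(datasets)
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("dataset_", seq_len(nd))
  }
  M <- matrix(NA_real_, nd, nd,
              dimnames = list(train = names(datasets),
                              eval = names(datasets)))
  full_models <- vector("list", nd)
  for (i in seq_len(nd)) {
    full_models[[i]] <- tryCatch(
      trainer(datasets[[i]], derive_seed(seed, 500L + i)),
      error = function(e) NULL)
  }
  for (i in seq_len(nd)) {
    for (j in seq_len(nd)) {
      if (i == j) {
        pa <- tryCatch(
          cross_validate(datasets[[i]], trainer, repeats = repeats,
                         seed = derive_seed(seed, i), fpr_max = fpr_max),
          error = function(e) NULL)
        if (!is.null(pa)) {
          M[i, j] <- mean(vapply(pa, `[[`, numeric(1), "pauc"))
        }
      } else if (!is.null(full_models[[i]])) {
        model <- full_models[[i]]
        ev <- datasets[[j]]
        pos <- vapply(ev, function(s) best_sequence_score(model, s),
                      numeric(1))
        neg <- vapply(seq_along(ev), function(t) {
          best_sequence_score(model,
                              shuffle_sequence(ev[[t]],
                                               derive_seed(seed,
                                                           i * 1000L + j * 100L + t)))
        }, numeric(1))
        M[i, j] <- partial_auc(roc_curve(pos, neg), fpr_max)$pauc
      }
    }
  }
  M
}

#' Pairwise Mann--Whitney tests with Bonferroni correction
#'
#' Compares every unordered pair of groups of per-dataset fractions with
#' the two-sided Mann--Whitney (Wilcoxon rank-sum) U test and multiplies
#' each raw p-value by the number of pairs (capped at 1). Small tie-free
#' groups are tested exactly; larger or tied groups use the normal
#' approximation with tie correction, following the standard
#' [stats::wilcox.test()] convention.
#'
#' @param groups named list of numeric vectors (each of length >= 3).
#' @return data.frame with `group1`, `group2`, `U`, `p_raw`, `p_adj`.
#' @export
compare_fraction_distributions <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) >= 3L))
  if (is.null(names(groups))) {
    names(groups) <- paste0("group_", seq_along(groups))
  }
  pairs <- utils::combn(names(groups), 2L)
  npairs <- ncol(pairs)
  rows <- lapply(seq_len(npairs), function(k) {
    a <- groups[[pairs[1L, k]]]
    b <- groups[[pairs[2L, k]]]
    wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
    data.frame(group1 = pairs[1L, k], group2 = pairs[2L, k],
               U = unname(wt$statistic), p_raw = wt$p.value,
               p_adj = min(1, wt$p.value * npairs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
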