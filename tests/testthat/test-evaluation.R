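# brute-force ROC oracle: enumerate every distinct threshold directly
roc_oracle <- function(pos, neg) {
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  pts <- data.frame(fpr = 0, tpr = 0)
  for (t in thr) {
    pts <- rbind(pts, data.frame(fpr = mean(neg >= t),
                                 tpr = mean(pos >= t)))
  }
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1) {
    pts <- rbind(pts, data.frame(fpr = 1, tpr = 1))
  }
  pts
}

trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

test_that("roc_curve matches exhaustive threshold enumeration", {
  cases <- list(list(pos = c(2, 3), neg = c(0, 1)),
                list(pos = c(3, 1), neg = c(2, 0)),
                list(pos = c(1, 2, 3), neg = c(1, 2, 3)))
  for (cs in cases) {
    roc <- roc_curve(cs$pos, cs$neg)
    oracle <- roc_oracle(cs$pos, cs$neg)
    expect_equal(roc$fpr, oracle$fpr)
    expect_equal(roc$tpr, oracle$tpr)
  }
  # perfect separation passes through (0, 1)
  roc <- roc_curve(c(2, 3), c(0, 1))
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  # identical distributions give the diagonal at step resolution
  roc <- roc_curve(1:10, 1:10)
  expect_equal(roc$fpr, roc$tpr)
  # random cases, including ties
  set.seed(61)
  for (i in 1:10) {
    pos <- sample(0:5, 7, replace = TRUE)
    neg <- sample(0:5, 9, replace = TRUE)
    roc <- roc_curve(pos, neg)
    oracle <- roc_oracle(pos, neg)
    expect_equal(roc$fpr, oracle$fpr)
    expect_equal(roc$tpr, oracle$tpr)
    expect_true(all(diff(roc$fpr) >= 0))
    expect_true(all(diff(roc$tpr) >= 0))
  }
})

test_that("full trapezoidal AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(62)
  for (i in 1:5) {
    pos <- rnorm(40, 1)
    neg <- rnorm(40, 0)
    roc <- roc_curve(pos, neg)
    ours <- trapezoid(roc$fpr, roc$tpr)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = c(rep(1, 40), rep(0, 40)), predictor = c(pos, neg),
      quiet = TRUE, direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("partial_auc reproduces closed forms and hand integration", {
  # perfect classifier: TPR = 1 over the whole band
  perfect <- roc_curve(c(10, 11), c(0, 1))
  expect_equal(partial_auc(perfect, 0.001)$pauc, 0.001, tolerance = 1e-12)
  # random classifier (exact diagonal): fpr_max^2 / 2
  diagonal <- structure(data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                        class = c("roc_curve", "data.frame"))
  expect_equal(partial_auc(diagonal, 0.001)$pauc, 5e-7, tolerance = 1e-15)
  # stepwise curve, hand-computed trapezoid on [0, 0.5]:
  # points (0,0.5), (0.5,0.5), (0.5,1), (1,1) -> area = 0.5 * 0.5 = 0.25
  roc <- roc_curve(c(3, 1), c(2, 0))
  expect_equal(partial_auc(roc, 0.5)$pauc, 0.25, tolerance = 1e-12)
  # interpolation at fpr_max between curve points
  expect_equal(partial_auc(diagonal, 0.4)$pauc, 0.4^2 / 2,
               tolerance = 1e-12)
  # bounded by fpr_max; invariant under duplicating all scores
  set.seed(63)
  pos <- rnorm(30, 0.5); neg <- rnorm(30)
  p1 <- partial_auc(roc_curve(pos, neg), 0.05)$pauc
  p2 <- partial_auc(roc_curve(rep(pos, 2), rep(neg, 2)), 0.05)$pauc
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_lte(p1, 0.05)
})

test_that("cross-validation separates planted motifs from noise", {
  sim <- std_sim()
  cfg <- discovery_config(length_grid = 10, n_seeds = 2, seed = 71)
  trainer <- pwm_trainer(10, cfg)
  pa <- cross_validate(sim$sequences, trainer, repeats = 3, seed = 71)
  paucs <- vapply(pa, `[[`, numeric(1), "pauc")
  # well above the random-classifier value 5e-7 (criterion: > 100x)
  expect_gt(mean(paucs), 100 * 5e-7)

  # motif-free control: mean pAUC consistent with the finite-sample
  # exchangeable expectation ~ fpr_max / (n_neg + 1), far below the
  # planted-motif value
  bg <- generate_background(100, 301, gc = 0.41, seed = 72)
  neg_pa <- tryCatch(
    cross_validate(bg, trainer, repeats = 3, seed = 72),
    error = function(e) NULL)
  if (!is.null(neg_pa)) {
    neg_mean <- mean(vapply(neg_pa, `[[`, numeric(1), "pauc"))
    n_ctrl <- 10
    expect_lte(neg_mean, 5 * 0.001 / (n_ctrl + 1))
    expect_lt(neg_mean, mean(paucs))
  }

  # single repeat returns a single element; fixed seed is reproducible
  one <- cross_validate(sim$sequences[1:60], trainer, repeats = 1,
                        seed = 73)
  expect_length(one, 1)
  two <- cross_validate(sim$sequences[1:60], trainer, repeats = 1,
                        seed = 73)
  expect_identical(one[[1]]$pauc, two[[1]]$pauc)
  expect_identical(one[[1]]$roc, two[[1]]$roc)
})

test_that("transfer matrix is high within and across shared-motif datasets", {
  # a 12-bp planted word keeps the per-sequence score separation
  # resolvable against 1:1 shuffled negatives at this sample size: a 7-bp
  # word recurs in mononucleotide shuffles often enough that exact copies
  # tie the top negative scores and collapse the pAUC below FPR 0.001
  shared1 <- generate_peaks(synthetic_spec(n_peaks = 100, peak_length = 150,
                                           consensus = "GTAAACACGCTT",
                                           mutation_rate = 0.05, seed = 81))
  shared2 <- generate_peaks(synthetic_spec(n_peaks = 100, peak_length = 150,
                                           consensus = "GTAAACACGCTT",
                                           mutation_rate = 0.05, seed = 82))
  other <- generate_peaks(synthetic_spec(n_peaks = 100, peak_length = 150,
                                         mutation_rate = 0.05,
                                         consensus = "CACGTGAGTTCA",
                                         seed = 83))
  cfg <- discovery_config(length_grid = 12, n_seeds = 2, seed = 84)
  trainer <- pwm_trainer(12, cfg)
  M <- transfer_matrix(list(a = shared1$sequences, b = shared2$sequences,
                            x = other$sequences),
                       trainer, repeats = 2, seed = 84)
  # datasets sharing the planted motif transfer in both directions
  expect_gt(M["a", "b"], 1e-4)
  expect_gt(M["b", "a"], 1e-4)
  expect_gt(M["a", "a"], 1e-4)
  expect_gt(M["b", "b"], 1e-4)
  # an unrelated motif transfers worse than the within-dataset accuracy
  expect_lt(M["a", "x"], M["a", "a"])
  expect_lt(M["b", "x"], M["b", "b"])
})

test_that("a single dataset gives a 1x1 matrix equal to cross-validation", {
  sim <- generate_peaks(synthetic_spec(n_peaks = 60, seed = 85))
  cfg <- discovery_config(length_grid = 9, n_seeds = 2, seed = 86)
  trainer <- pwm_trainer(9, cfg)
  M <- transfer_matrix(list(only = sim$sequences), trainer, repeats = 2,
                       seed = 77)
  pa <- cross_validate(sim$sequences, trainer, repeats = 2,
                       seed = multimotif:::derive_seed(77, 1))
  expect_equal(dim(M), c(1, 1))
  expect_equal(M[1, 1], mean(vapply(pa, `[[`, numeric(1), "pauc")))
})

# exact-enumeration oracle for the rank-sum test on tiny groups
mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  U_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  mu <- length(a) * length(b) / 2
  combs <- combn(length(pooled), n)
  U_all <- apply(combs, 2, function(idx) {
    sum(rank(pooled)[idx]) - n * (n + 1) / 2
  })
  mean(abs(U_all - mu) >= abs(U_obs - mu))
}

test_that("Mann-Whitney comparisons match exact enumeration, Bonferroni", {
  # fully separated tiny groups: U = 0, exact two-sided p = 2/20
  res <- compare_fraction_distributions(list(lo = c(1, 2, 3),
                                             hi = c(10, 11, 12)))
  expect_equal(res$U, 0)
  expect_equal(res$p_raw, mw_exact_p(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(res$p_raw, 0.1)

  # identical groups are not significant after adjustment
  same <- compare_fraction_distributions(list(a = c(1, 2, 3),
                                              b = c(1, 2, 3)))
  expect_equal(same$p_adj, 1)

  # three groups: three pairwise tests, multiplier 3
  three <- compare_fraction_distributions(list(a = c(1, 2, 3),
                                               b = c(2, 3, 4),
                                               c = c(9, 10, 11)))
  expect_equal(nrow(three), 3)
  expect_equal(three$p_adj, pmin(1, three$p_raw * 3))

  # random tie-free groups of size <= 5 agree with the permutation oracle
  set.seed(91)
  for (i in 1:5) {
    a <- sample(seq(0, 100, by = 0.5), 4)
    b <- sample(setdiff(seq(0, 100, by = 0.5), a), 5)
    res <- compare_fraction_distributions(list(a = a, b = b))
    expect_equal(res$p_raw, mw_exact_p(a, b), tolerance = 1e-12)
  }
})
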