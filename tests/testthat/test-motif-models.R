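test_that("train_pwm applies the pseudocount formula and log2-odds scoring", {
  # hand count: 2 sites, both A at position 1, uniform background, c = 1
  pwm <- train_pwm(c("AC", "AC"), background = rep(0.25, 4), pseudocount = 1)
  expect_equal(unname(pwm$freq[1, "A"]), (2 + 0.25) / 3)
  expect_equal(unname(pwm$freq[1, "C"]), 0.25 / 3)
  expect_equal(rowSums(pwm$freq), rep(1, 2), tolerance = 1e-9)

  # column frequencies equal to the background give an all-zero matrix
  sites <- c("AA", "CC", "GG", "TT")
  pwm0 <- train_pwm(sites, background = rep(0.25, 4), pseudocount = 1)
  expect_equal(unname(pwm0$mat), matrix(0, 2, 4), tolerance = 1e-12)
  expect_equal(score_window(pwm0, "GT"), 0)

  # degenerate count: single site, no pseudocount -> unit rows
  pwm1 <- train_pwm("ACGT", pseudocount = 0)
  expect_equal(unname(pwm1$freq[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(pwm1$freq[4, ]), c(0, 0, 0, 1))

  expect_error(train_pwm(character(0)), "empty")
})

test_that("train_dipwm tallies adjacent pairs with 16 categories", {
  di <- train_dipwm(c("ACG", "ACG"), pseudocount = 0)
  expect_equal(unname(di$freq[1, "AC"]), 1)
  expect_equal(unname(di$freq[2, "CG"]), 1)
  expect_equal(rowSums(di$freq), rep(1, 2), tolerance = 1e-9)

  # frequencies equal to a uniform dinucleotide background -> zero log-odds
  sites16 <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                             paste0))
  di0 <- train_dipwm(sites16, background16 = rep(1 / 16, 16),
                     pseudocount = 1)
  expect_equal(unname(di0$mat), matrix(0, 1, 16), tolerance = 1e-12)

  expect_error(train_dipwm(c("A", "C")), "length")
})

# independent oracle: literal recursion on a tiny alignment
test_that("train_markov matches a hand-computed interpolated recursion", {
  sites <- c("AAT", "AAT", "ACT")
  bg <- rep(0.25, 4)
  mk <- train_markov(sites, order = 1L, alphas = 1, background = bg,
                     pseudocount = 1)
  # order-0 base at position 3: counts T = 3
  p0_3 <- (c(0, 0, 0, 3) + 1 * 0.25) / (3 + 1)
  # position 3, context A (prev letter at pos 2): n(A) = 2, n(A,T) = 2
  p_T_given_A <- (2 + 1 * p0_3[4]) / (2 + 1)
  # context C: n(C) = 1, n(C,T) = 1
  p_T_given_C <- (1 + 1 * p0_3[4]) / (1 + 1)
  expect_equal(unname(mk$cond[[3]][[2]]["A", "T"]), p_T_given_A,
               tolerance = 1e-12)
  expect_equal(unname(mk$cond[[3]][[2]]["C", "T"]), p_T_given_C,
               tolerance = 1e-12)
  # unseen context G falls back entirely to the order-0 estimate
  expect_equal(unname(mk$cond[[3]][[2]]["G", "T"]), p0_3[4],
               tolerance = 1e-12)

  # every conditional row sums to 1 at every position and context
  for (j in 1:3) {
    for (m in seq_along(mk$cond[[j]])) {
      expect_equal(unname(rowSums(mk$cond[[j]][[m]])),
                   rep(1, nrow(mk$cond[[j]][[m]])), tolerance = 1e-9)
    }
  }
  expect_error(train_markov(sites, order = 6L), "exceed 5")
})

test_that("order-0 Markov model scores identically to the PWM", {
  sites <- random_sites(40, 8, seed = 101)
  bg <- c(0.3, 0.2, 0.2, 0.3)
  pwm <- train_pwm(sites, bg, pseudocount = 1)
  mk0 <- train_markov(sites, order = 0L, background = bg, pseudocount = 1)
  wins <- random_sites(100, 8, seed = 102)
  for (w in wins) {
    expect_equal(score_window(mk0, w), score_window(pwm, w),
                 tolerance = 1e-9)
  }
})

test_that("huge interpolation strengths collapse order k onto order k-1", {
  sites <- random_sites(60, 6, seed = 103)
  mk <- train_markov(sites, order = 2L, alphas = c(1e9, 1e9))
  for (j in 3:6) {
    pm2 <- mk$cond[[j]][[3]]           # order-2 conditionals
    pm1 <- mk$cond[[j]][[2]]           # order-1 conditionals
    parent <- ((seq_len(16) - 1L) %% 4L) + 1L
    expect_equal(unname(pm2), unname(pm1[parent, , drop = FALSE]),
                 tolerance = 1e-6)
  }
})

test_that("probability rows are normalised for all trained models", {
  sites <- random_sites(50, 9, seed = 104)
  pwm <- train_pwm(sites)
  di <- train_dipwm(sites)
  mk <- train_markov(sites, order = 2L)
  expect_equal(rowSums(pwm$freq), rep(1, 9), tolerance = 1e-9)
  expect_equal(rowSums(di$freq), rep(1, 8), tolerance = 1e-9)
  for (j in 1:9) {
    for (m in seq_along(mk$cond[[j]])) {
      expect_equal(unname(rowSums(mk$cond[[j]][[m]])),
                   rep(1, nrow(mk$cond[[j]][[m]])), tolerance = 1e-9)
    }
  }
  expect_true(all(pwm$freq > 0))
  expect_true(all(di$freq > 0))
})

test_that("adding observations of a letter never lowers its frequency", {
  base <- random_sites(30, 5, seed = 105)
  extra <- c("AAAAA", "AAAAA", "AAAAA")
  f1 <- train_pwm(base)$freq
  f2 <- train_pwm(c(base, extra))$freq
  expect_true(all(f2[, "A"] >= f1[, "A"] - 1e-12))
})

test_that("score_window handles strands, maxima and unscorable windows", {
  # PWM from a single clean site dominates every other 4-mer
  pwm <- train_pwm("ACGT", pseudocount = 0)
  all4 <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 4))[, 4:1],
                1, paste, collapse = "")
  scores <- vapply(all4, function(w) score_window(pwm, w), numeric(1))
  expect_equal(names(which.max(scores)), "ACGT")
  expect_true(all(scores[names(scores) != "ACGT"] < scores[["ACGT"]]))

  # minus strand == plus strand of the reverse complement, for every family
  sites <- random_sites(40, 7, seed = 106)
  models <- list(train_pwm(sites), train_dipwm(sites),
                 train_markov(sites, order = 2L),
                 prune_markov_orders(train_markov(sites, order = 2L), sites))
  wins <- random_sites(25, 7, seed = 107)
  for (m in models) {
    for (w in wins) {
      expect_equal(score_window(m, w, "-"),
                   score_window(m, revcomp(w), "+"), tolerance = 1e-12)
    }
  }
  expect_true(is.na(score_window(models[[1]], "ACGNTAA")))
})

test_that("BIC pruning removes spurious orders and keeps real dependence", {
  # columns drawn i.i.d.: no position should keep order > 0
  set.seed(501)
  probs <- list(c(.7, .1, .1, .1), c(.1, .6, .2, .1), c(.25, .25, .25, .25),
                c(.1, .1, .1, .7), c(.4, .4, .1, .1))
  sites <- replicate(500, paste(vapply(probs, function(p) {
    sample(c("A", "C", "G", "T"), 1, prob = p)
  }, character(1)), collapse = ""))
  mk <- train_markov(sites, order = 2L)
  pruned <- prune_markov_orders(mk, sites)
  expect_equal(pruned$per_position_order, rep(0L, 5))

  # deterministic first-order dependence at position 3: letter copies the
  # previous one
  set.seed(502)
  dep <- replicate(500, {
    a <- sample(c("A", "C", "G", "T"), 1)
    b <- sample(c("A", "C", "G", "T"), 1)
    paste0(a, b, b, sample(c("A", "C", "G", "T"), 1))
  })
  pd <- prune_markov_orders(train_markov(dep, order = 2L), dep)
  expect_gte(pd$per_position_order[3], 1L)

  # order-0 models are unchanged by pruning
  mk0 <- train_markov(dep, order = 0L)
  expect_equal(prune_markov_orders(mk0, dep)$orders, mk0$orders)
})

test_that("frequency matrices and information content follow closed forms", {
  same <- rep("GATTACA", 5)
  fm <- frequency_matrix_from_sites(same)
  expect_equal(information_content(fm), rep(2, 7))
  expect_equal(consensus_string(same), "GATTACA")

  uniform <- c("A", "C", "G", "T")
  expect_equal(information_content(frequency_matrix_from_sites(uniform)), 0)

  half <- matrix(c(0.5, 0.5, 0, 0), 1, 4)
  expect_equal(information_content(half), 1)
})
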