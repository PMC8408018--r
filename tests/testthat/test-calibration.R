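test_that("background_scores counts every scorable position on both strands", {
  sites <- random_sites(30, 12, seed = 301)
  pwm <- train_pwm(sites)
  prom <- generate_background(1, 2000, gc = 0.5, seed = 302)
  bg <- background_scores(pwm, prom)
  expect_equal(bg$n_positions, 2 * (2000 - 12 + 1))
  expect_equal(length(bg$scores), bg$n_positions)

  # short sequences warn and contribute nothing; all-N contributes nothing
  expect_warning(bg2 <- background_scores(pwm, c(prom, short = "ACGT")),
                 "shorter")
  expect_equal(bg2$n_positions, bg$n_positions)
  bg3 <- background_scores(pwm, c(prom, allN = strrep("N", 100)))
  expect_equal(bg3$n_positions, bg$n_positions)
  expect_error(background_scores(pwm, strrep("N", 100)), "no scorable")
})

# brute-force threshold oracle: try every unique score directly
threshold_oracle <- function(scores, target) {
  uniq <- sort(unique(scores))
  for (t in uniq) {
    fpr <- mean(scores >= t)
    if (fpr <= target) return(list(threshold = t, achieved_fpr = fpr))
  }
  NULL
}

test_that("select_threshold picks the smallest score meeting the bound", {
  # 10000 distinct scores at target 1.9e-4: FPR(9999) = 2e-4 exceeds the
  # bound, so the maximum score is chosen with achieved FPR 1e-4
  sel <- select_threshold(1:10000, 1.9e-4)
  expect_equal(sel$threshold, 10000)
  expect_equal(sel$achieved_fpr, 1e-4)

  sel <- select_threshold(c(1, 2, 3, 4), 0.5)
  expect_equal(sel$threshold, 3)
  expect_equal(sel$achieved_fpr, 0.5)

  # degenerate distribution: only FPR 1 is available
  expect_error(select_threshold(rep(2, 10), 0.5), "no threshold")
  sel <- select_threshold(rep(2, 10), 1)
  expect_equal(sel$achieved_fpr, 1)

  # background too small to resolve the target
  expect_error(select_threshold(1:100, 1.9e-4), "too small")

  # random multisets agree with the brute-force oracle
  set.seed(303)
  for (i in 1:10) {
    scores <- sample(seq(-5, 5, by = 0.5), 200, replace = TRUE)
    target <- sample(c(0.01, 0.05, 0.2), 1)
    oracle <- threshold_oracle(scores, target)
    if (is.null(oracle)) {
      expect_error(select_threshold(scores, target), "no threshold")
      next
    }
    sel <- select_threshold(scores, target)
    expect_equal(sel$threshold, oracle$threshold)
    expect_equal(sel$achieved_fpr, oracle$achieved_fpr)
    # achieved FPR equals the re-measured empirical FPR exactly
    expect_identical(sel$achieved_fpr, mean(scores >= sel$threshold))
  }
})

test_that("the calibration curve is non-increasing in the threshold", {
  sites <- random_sites(30, 8, seed = 304)
  pwm <- train_pwm(sites)
  prom <- generate_background(5, 400, gc = 0.5, seed = 305)
  curve <- calibration_curve(pwm, prom)
  expect_true(all(diff(curve$threshold) > 0))
  expect_true(all(diff(curve$fpr) < 0))
  expect_equal(curve$fpr[1], 1)
})

# a small calibrated bundle built from clean planted sites
toy_bundle <- function(seed = 306) {
  sites <- rep(c("GTAAACAGGCTA", "GTAAACAGGCTT", "GTAAACAGGCTC"), 10)
  model_bundle(pwm = train_pwm(sites),
               dipwm = train_dipwm(sites),
               markov = train_markov(sites, order = 2L),
               pruned_markov = prune_markov_orders(
                 train_markov(sites, order = 2L), sites))
}

test_that("scan_peaks emits exactly the above-threshold windows", {
  bundle <- toy_bundle()
  prom <- generate_background(50, 500, gc = 0.5, seed = 307)
  bundle <- calibrate_bundle(bundle, prom, target_fpr = 0.001)
  expect_true(all(bundle$threshold_table$achieved_fpr <= 0.001))

  # a peak with the clean site planted at offset 50 yields a hit there for
  # every model
  set.seed(308)
  peak <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
  substr(peak, 51, 62) <- "GTAAACAGGCTA"
  hits <- scan_peaks(bundle, c(p1 = peak))
  for (nm in names(bundle$models)) {
    h <- hits[hits$model == nm, ]
    expect_true(any(h$start == 50),
                label = paste("model", nm, "hit at offset 50"))
  }
  expect_true(all(hits$end - hits$start == 12))
  for (nm in names(bundle$models)) {
    h <- hits[hits$model == nm, ]
    expect_true(all(h$score >= bundle$thresholds[[nm]]))
  }

  # thresholds above the maximum attainable score yield no hits
  b2 <- bundle
  b2$thresholds[] <- 1e6
  expect_equal(nrow(scan_peaks(b2, c(p1 = peak))), 0)

  # raising a threshold never increases the hit count
  for (nm in names(bundle$models)) {
    b3 <- bundle
    b3$thresholds[[nm]] <- b3$thresholds[[nm]] + 2
    expect_lte(nrow(scan_peaks(b3, c(p1 = peak))), nrow(hits))
  }
})

test_that("palindromic windows hit on both strands with equal coordinates", {
  sites <- rep("ACGTACGT", 20)   # reverse-complement palindrome
  bundle <- model_bundle(pwm = train_pwm(sites),
                         dipwm = train_dipwm(sites),
                         markov = train_markov(sites, order = 1L),
                         pruned_markov = prune_markov_orders(
                           train_markov(sites, order = 1L), sites))
  bundle$thresholds <- setNames(rep(1, 4), names(bundle$models))
  peak <- paste0(strrep("T", 30), "ACGTACGT", strrep("T", 30))
  hits <- scan_peaks(bundle, c(p = peak))
  h <- hits[hits$model == "pwm" & hits$start == 30, ]
  expect_setequal(h$strand, c("-", "+"))
  expect_equal(unique(h$start), 30)
  expect_equal(h$score[1], h$score[2])
})

test_that("scanning the reverse-complemented peaks mirrors the hit set", {
  bundle <- toy_bundle()
  bundle$thresholds <- setNames(rep(3, 4), names(bundle$models))
  set.seed(309)
  peak <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                collapse = "")
  substr(peak, 31, 42) <- "GTAAACAGGCTA"
  h_fwd <- scan_peaks(bundle, c(p = peak))
  h_rev <- scan_peaks(bundle, c(p = revcomp(peak)))
  expect_equal(nrow(h_fwd), nrow(h_rev))
  n <- nchar(peak)
  # mirror map: start' = n - end, strand flipped
  key_fwd <- with(h_fwd, sort(paste(model, start, strand)))
  key_mir <- with(h_rev, sort(paste(model, n - end,
                                    ifelse(strand == "+", "-", "+"))))
  expect_equal(key_fwd, key_mir)
})

test_that("hits_to_bed converts to genome coordinates", {
  hits <- data.frame(peak_id = "p1", model = "pwm", start = 50L, end = 62L,
                     strand = "+", score = 7.5, stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "chr1", start = 1000L, end = 1300L,
                      name = "p1", score = 80)
  bed <- hits_to_bed(hits, peaks)
  expect_equal(bed$chrom, "chr1")
  expect_equal(bed$start, 1050L)
  expect_equal(bed$end, 1062L)
  expect_equal(bed$strand, "+")

  hits0 <- hits; hits0$start <- 0L; hits0$end <- 12L
  expect_equal(hits_to_bed(hits0, peaks)$start, 1000L)

  bad <- hits; bad$peak_id <- "nope"
  expect_error(hits_to_bed(bad, peaks), "unresolvable")

  # empty hit set writes a header-only BED
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(hits_to_bed(hits[0, ], peaks), f)
  lines <- readLines(f)
  expect_length(lines, 1)
  expect_match(lines, "^#")
})
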