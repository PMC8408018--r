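# Shared fixtures, built lazily and cached for the whole test run.
# The "standard" simulation uses the generator defaults (200 peaks of
# 301 bp, occupancy 0.9, 10 % per-letter mutation, GTAAACA consensus).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

std_spec <- function() synthetic_spec(seed = 42L)

std_sim <- function() {
  fixture("std_sim", function() generate_peaks(std_spec()))
}

std_cfg <- function() {
  discovery_config(length_grid = 12L, n_seeds = 3L, seed = 42L)
}

std_bundle <- function() {
  fixture("std_bundle", function() {
    train_all_models(std_sim()$sequences, 12L, std_cfg())
  })
}

# the calibration background: 1000 x 2000 bp motif-free "promoters"
cal_background <- function() {
  fixture("cal_background", function() {
    generate_background(1000L, 2000L, gc = 0.41, seed = 43L)
  })
}

std_calibrated <- function() {
  fixture("std_calibrated", function() {
    calibrate_bundle(std_bundle(), cal_background(), target_fpr = 1.9e-4)
  })
}

std_hits <- function() {
  fixture("std_hits", function() {
    scan_peaks(std_calibrated(), std_sim()$sequences)
  })
}

# random site alignment for property-style model tests
random_sites <- function(n, L, seed) {
  rng_state <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  out <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  if (!is.null(rng_state)) assign(".Random.seed", rng_state,
                                  envir = globalenv())
  out
}

# minimum Hamming distance of `word` to any same-length window of `text`,
# over both orientations
min_hamming_to_window <- function(word, text) {
  k <- nchar(word)
  best <- k
  for (target in c(text, revcomp(text))) {
    n <- nchar(target)
    if (n < k) next
    for (i in 1:(n - k + 1L)) {
      win <- substr(target, i, i + k - 1L)
      d <- sum(strsplit(win, "")[[1L]] != strsplit(word, "")[[1L]])
      best <- min(best, d)
    }
  }
  best
}
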