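#' Discovery configuration
#'
#' Collects the tunable parameters of de novo motif discovery.
#'
#' @param length_grid candidate motif lengths (bp), within 6..30.
#' @param em_max_iter maximum EM iterations.
#' @param em_tol stop when the log-likelihood improves by less than this.
#' @param n_seeds number of top-ranked seed words used as EM restarts.
#' @param seed_k seed word length for [enumerate_seeds()].
#' @param occupancy prior probability that a sequence carries one site
#'   (ZOOPS occurrence model).
#' @param markov_order order of the Markov member models.
#' @param pseudocount pseudocount for all model training.
#' @param seed RNG seed making discovery deterministic.
#' @return a list of class `discovery_config`.
#' @export
discovery_config <- function(length_grid = c(8, 10, 12, 14, 16, 18, 20),
                             em_max_iter = 100L, em_tol = 1e-4,
                             n_seeds = 5L, seed_k = 7L, occupancy = 0.8,
                             markov_order = 2L, pseudocount = 1,
                             seed = 1L) {
  stopifnot(length(length_grid) >= 1L, em_max_iter >= 1L,
            all(length_grid >= 6), all(length_grid <= 30))
  structure(list(length_grid = as.integer(length_grid),
                 em_max_iter = as.integer(em_max_iter), em_tol = em_tol,
                 n_seeds = as.integer(n_seeds), seed_k = as.integer(seed_k),
                 occupancy = occupancy,
                 markov_order = as.integer(markov_order),
                 pseudocount = pseudocount, seed = as.integer(seed)),
            class = "discovery_config")
}

#' Rank candidate seed words by shuffled-background enrichment
#'
#' Counts every k-mer in the peak set, collapsing a word and its reverse
#' complement onto one canonical form, and compares the observed count with
#' counts in per-sequence mononucleotide-shuffled copies of the peaks. The
#' z-score `(observed - mean_shuffled) / max(sd_shuffled, 1)` ranks words;
#' planted motifs stand far above the shuffled background.
#'
#' @param seqs peak sequences.
#' @param k word length.
#' @param n_seeds number of top words to return.
#' @param n_shuffles shuffled replicates of the peak set used for the null.
#' @param seed RNG seed.
#' @return data.frame with `kmer` (canonical form), `count`, `z`, ranked by
#'   decreasing z.
#' @export
enumerate_seeds <- function(seqs, k = 7L, n_seeds = 5L, n_shuffles = 5L,
                            seed = 1L) {
  stopifnot(k >= 3L, all(nchar(seqs) >= k))
  count_kmers <- function(ss) {
    words <- unlist(lapply(ss, function(s) {
      n <- nchar(s)
      substring(s, 1:(n - k + 1L), k:n)
    }), use.names = FALSE)
    words <- words[!grepl("[^ACGT]", words)]
    tab <- table(words)
    # canonicalise on the unique words only
    u <- names(tab)
    canon <- pmin(u, revcomp(u))
    tapply(as.numeric(tab), canon, sum)
  }
  obs <- count_kmers(toupper(seqs))
  null_counts <- matrix(0, n_shuffles, length(obs),
                        dimnames = list(NULL, names(obs)))
  for (r in seq_len(n_shuffles)) {
    shuf <- vapply(seq_along(seqs), function(i) {
      shuffle_sequence(seqs[[i]], derive_seed(seed, r * 10007L + i))
    }, character(1))
    nc <- count_kmers(shuf)
    common <- intersect(names(nc), names(obs))
    null_counts[r, common] <- nc[common]
  }
  mu <- colMeans(null_counts)
  sdev <- apply(null_counts, 2L, sd)
  z <- (as.numeric(obs) - mu) / pmax(sdev, 1)
  out <- data.frame(kmer = names(obs), count = as.numeric(obs), z = z,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$z, -out$count, out$kmer), ]
  rownames(out) <- NULL
  head(out, n_seeds)
}

# initial PWM for EM: seed word centred in an L-bp window, seed letters get
# weight `conf`, flanks get the background
seed_pwm <- function(seed_word, L, background, conf = 0.7) {
  w <- nchar(seed_word)
  stopifnot(L >= w)
  offset <- (L - w) %/% 2L
  freq <- matrix(rep(background, each = L), L, 4L,
                 dimnames = list(NULL, DNA_LETTERS))
  codes <- encode_dna(seed_word)
  for (t in seq_len(w)) {
    row <- rep((1 - conf) / 3, 4L)
    row[codes[t]] <- conf
    freq[offset + t, ] <- row
  }
  structure(list(L = L, freq = freq,
                 background = setNames(background, DNA_LETTERS),
                 pseudocount = 0,
                 mat = log2(sweep(freq, 2L, background, "/")),
                 nsites = 0L),
            class = c("pwm_model", "motif_model"))
}

#' Refine a seed word into a site alignment by ZOOPS EM
#'
#' Expectation--maximisation over a PWM under the zero-or-one-occurrence-
#' per-sequence model. The E-step computes, per sequence, a posterior over
#' every window position and strand plus a no-occurrence option (prior
#' occupancy `cfg$occupancy`); the M-step re-estimates the PWM from
#' posterior-weighted letter counts. Iteration stops when the observed-data
#' log-likelihood improves by less than `cfg$em_tol` or after
#' `cfg$em_max_iter` iterations; the log-likelihood is non-decreasing
#' throughout. The returned alignment holds the maximum-posterior window of
#' every sequence whose occurrence posterior is at least 0.5.
#'
#' @param seqs peak sequences.
#' @param seed_word initial k-mer (from [enumerate_seeds()]).
#' @param L motif length (>= `nchar(seed_word)`).
#' @param cfg a [discovery_config()].
#' @param background mononucleotide background; estimated from `seqs` when
#'   `NULL`.
#' @return list of class `em_result`: `sites` (character alignment),
#'   `peak_id`, `start` (0-based offset), `strand`, `posterior`, `pwm`
#'   (final model), `loglik_trace`, `n_iter`.
#' @export
em_refine <- function(seqs, seed_word, L, cfg = discovery_config(),
                      background = NULL) {
  stopifnot(L >= nchar(seed_word))
  if (is.null(names(seqs))) names(seqs) <- paste0("peak_", seq_along(seqs))
  seqs <- toupper(seqs)
  usable <- nchar(seqs) >= L
  if (!all(usable)) {
    warning(sum(!usable), " sequence(s) shorter than L dropped")
    seqs <- seqs[usable]
  }
  if (length(seqs) == 0L) stop("motif not found: no usable sequences")
  if (is.null(background)) background <- estimate_background(seqs)
  gamma <- cfg$occupancy
  n_seq <- length(seqs)
  lens <- nchar(seqs)
  # one concatenated code vector (sequences separated by NA) lets every EM
  # iteration score all windows of all sequences in two vectorised passes;
  # windows crossing a separator contain NA and drop out automatically
  offsets <- cumsum(c(1L, head(lens, -1L) + 1L))   # start of each sequence
  big <- rep(NA_integer_, sum(lens) + n_seq - 1L)
  for (i in seq_len(n_seq)) {
    big[offsets[i]:(offsets[i] + lens[i] - 1L)] <- encode_dna(seqs[[i]])
  }
  NW <- length(big) - L + 1L
  # window p (global, 1-based) belongs to sequence i iff
  # offsets[i] <= p <= offsets[i] + lens[i] - L; other windows span a
  # separator and are invalid
  win_seq <- rep(NA_integer_, NW)
  win_per_seq <- integer(n_seq)
  for (i in seq_len(n_seq)) {
    nw_i <- lens[i] - L + 1L
    win_per_seq[i] <- nw_i
    win_seq[offsets[i]:(offsets[i] + nw_i - 1L)] <- i
  }
  valid <- !is.na(win_seq)
  win_seq_f <- factor(win_seq[valid], levels = seq_len(n_seq))
  # (window, motif-position) letter codes for the weighted count step:
  # forward-strand letter at position j is big[p+j-1]; the reverse-strand
  # window over the same bases carries the complement of big[p+L-j]
  vp <- which(valid)
  idx_f <- vector("list", L)
  idx_r <- vector("list", L)
  for (j in seq_len(L)) {
    lf <- big[vp + j - 1L]
    lr <- 5L - big[vp + L - j]
    idx_f[[j]] <- lapply(1:4, function(b) which(lf == b))
    idx_r[[j]] <- lapply(1:4, function(b) which(lr == b))
  }
  pwm <- seed_pwm(seed_word, L, background)
  rc_mat <- function(mat) mat[L:1, 4:1, drop = FALSE]
  loglik_trace <- numeric(0)
  prev_ll <- -Inf
  posterior_pass <- function(pwm, gamma) {
    sf <- score_all_windows.pwm_model(pwm, big)
    # scoring the reverse complement of each window == scoring the window
    # under the reverse-complemented matrix
    pwm_rc <- pwm
    pwm_rc$mat <- rc_mat(pwm$mat)
    sr <- score_all_windows.pwm_model(pwm_rc, big)
    lrf <- 2^sf[vp]; lrf[is.na(lrf)] <- 0
    lrr <- 2^sr[vp]; lrr[is.na(lrr)] <- 0
    tot <- tapply(lrf + lrr, win_seq_f, sum)
    prior <- gamma / (2 * win_per_seq)
    Z <- (1 - gamma) + prior * as.numeric(tot)
    list(lrf = lrf, lrr = lrr, Z = Z, ll = sum(log(Z)),
         prior = prior, q = prior * as.numeric(tot) / Z)
  }
  for (iter in seq_len(cfg$em_max_iter)) {
    ep <- posterior_pass(pwm, gamma)
    loglik_trace <- c(loglik_trace, ep$ll)
    scale <- (ep$prior / ep$Z)[as.integer(win_seq_f)]
    rf <- ep$lrf * scale                  # posterior per (window, strand)
    rr <- ep$lrr * scale
    counts <- matrix(0, L, 4L)
    for (j in seq_len(L)) {
      for (b in 1:4) {
        counts[j, b] <- sum(rf[idx_f[[j]][[b]]]) + sum(rr[idx_r[[j]][[b]]])
      }
    }
    tot <- rowSums(counts)
    freq <- (counts + cfg$pseudocount * rep(background, each = L)) /
      (tot + cfg$pseudocount)
    dimnames(freq) <- list(NULL, DNA_LETTERS)
    pwm$freq <- freq
    pwm$mat <- log2(sweep(freq, 2L, background, "/"))
    if (is.finite(prev_ll) && ep$ll - prev_ll < cfg$em_tol) break
    prev_ll <- ep$ll
  }
  # site extraction at the final parameters
  ep <- posterior_pass(pwm, gamma)
  ids <- character(0); starts <- integer(0); strands <- character(0)
  posts <- numeric(0); sites <- character(0)
  seq_of_win <- as.integer(win_seq_f)
  for (i in seq_len(n_seq)) {
    if (ep$q[i] < 0.5) next
    wi <- which(seq_of_win == i)
    lr_i <- c(ep$lrf[wi], ep$lrr[wi])
    best <- which.max(lr_i)
    nw_i <- length(wi)
    strand <- if (best <= nw_i) "+" else "-"
    p_local <- if (best <= nw_i) best else best - nw_i
    gstart <- vp[wi[p_local]]
    win <- big[gstart:(gstart + L - 1L)]
    if (anyNA(win)) next
    if (strand == "-") win <- revcomp_codes(win)
    ids <- c(ids, names(seqs)[i])
    starts <- c(starts, gstart - offsets[i])
    strands <- c(strands, strand); posts <- c(posts, ep$q[i])
    sites <- c(sites, decode_dna(win))
  }
  if (length(sites) == 0L) stop("motif not found: no sequence passed the ",
                                "occurrence posterior cutoff")
  pwm$nsites <- length(sites)
  structure(list(sites = sites, peak_id = ids, start = starts,
                 strand = strands, posterior = posts, pwm = pwm,
                 loglik_trace = loglik_trace,
                 n_iter = length(loglik_trace)),
            class = "em_result")
}

# full discovery at one length: seed enumeration + multi-start EM,
# best final log-likelihood kept
discover_alignment <- function(seqs, L, cfg = discovery_config(),
                               background = NULL) {
  if (is.null(background)) background <- estimate_background(seqs)
  seeds <- enumerate_seeds(seqs, k = min(cfg$seed_k, L), n_seeds = cfg$n_seeds,
                           seed = cfg$seed)
  best <- NULL
  for (s in seeds$kmer) {
    res <- tryCatch(em_refine(seqs, s, L, cfg, background),
                    error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) ||
        max(res$loglik_trace) > max(best$loglik_trace)) best <- res
  }
  if (is.null(best)) stop("motif not found at length ", L)
  best
}

#' Select the optimal motif length by cross-validated pAUC
#'
#' For each candidate length, a PWM is discovered de novo on each training
#' split and evaluated on the held-out split against shuffled negatives;
#' the length with the highest mean partial AUC wins (ties go to the
#' smaller length). The same length is then used for every model family.
#'
#' @param seqs peak sequences.
#' @param cfg a [discovery_config()]; `cfg$length_grid` is the candidate
#'   set.
#' @param repeats cross-validation repeats per length.
#' @param fpr_max pAUC integration bound.
#' @return list with `L` (chosen length) and `table` (data.frame: length,
#'   mean_pauc, sd_pauc, n_repeats).
#' @export
select_optimal_length <- function(seqs, cfg = discovery_config(),
                                  repeats = 5L, fpr_max = 0.001) {
  grid <- sort(unique(cfg$length_grid))
  if (length(grid) == 1L) {
    return(list(L = grid, table = data.frame(length = grid,
                                             mean_pauc = NA_real_,
                                             sd_pauc = NA_real_,
                                             n_repeats = 0L)))
  }
  rows <- list()
  for (L in grid) {
    trainer <- pwm_trainer(L, cfg)
    pa <- tryCatch(
      cross_validate(seqs, trainer, repeats = repeats,
                     seed = derive_seed(cfg$seed, L), fpr_max = fpr_max),
      error = function(e) NULL)
    if (is.null(pa)) next
    v <- vapply(pa, function(p) p$pauc, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      length = L, mean_pauc = mean(v), sd_pauc = sd(v), n_repeats = length(v))
  }
  if (length(rows) == 0L) stop("discovery failed at every candidate length")
  tab <- do.call(rbind, rows)
  best <- tab$length[which.max(tab$mean_pauc)]  # first max = smallest length
  list(L = best, table = tab)
}

#' A PWM training procedure for cross-validation
#'
#' Returns a function mapping training sequences to a discovered PWM at a
#' fixed length — the `trainer` argument of [cross_validate()] and
#' [transfer_matrix()].
#'
#' @param L motif length.
#' @param cfg a [discovery_config()].
#' @return function(train_seqs, seed) -> `pwm_model`.
#' @export
pwm_trainer <- function(L, cfg = discovery_config()) {
  force(L); force(cfg)
  function(train_seqs, seed = cfg$seed) {
    cfg2 <- cfg
    cfg2$seed <- seed
    res <- discover_alignment(train_seqs, L, cfg2)
    train_pwm(res$sites, background = estimate_background(train_seqs),
              pseudocount = cfg$pseudocount)
  }
}

#' Train all four model families from one discovered alignment
#'
#' Runs discovery once at length `L`, then trains the PWM, dinucleotide PWM,
#' order-`cfg$markov_order` Markov model and its BIC-pruned variant from the
#' shared site alignment. Backgrounds (mono- and dinucleotide) are estimated
#' from the full peak set.
#'
#' @param seqs peak sequences.
#' @param L motif length (e.g. from [select_optimal_length()]).
#' @param cfg a [discovery_config()].
#' @return a `model_bundle` (see [model_bundle()]) without thresholds; its
#'   `alignment` element holds the shared `em_result`.
#' @export
train_all_models <- function(seqs, L, cfg = discovery_config()) {
  if (length(seqs) == 0L) stop("empty peak set")
  bg <- estimate_background(seqs)
  bg16 <- estimate_background_di(seqs)
  res <- discover_alignment(seqs, L, cfg, background = bg)
  sites <- res$sites
  pwm <- train_pwm(sites, bg, cfg$pseudocount)
  dipwm <- train_dipwm(sites, bg16, cfg$pseudocount)
  markov <- train_markov(sites, order = cfg$markov_order, background = bg,
                         pseudocount = cfg$pseudocount)
  pruned <- prune_markov_orders(markov, sites)
  model_bundle(pwm = pwm, dipwm = dipwm, markov = markov,
               pruned_markov = pruned, alignment = res)
}

#' Bundle of trained models sharing one motif length
#'
#' @param pwm,dipwm,markov,pruned_markov trained models of identical length.
#' @param alignment optional `em_result` the models were trained from.
#' @return list of class `model_bundle` with `models` (named list),
#'   `alignment`, and `thresholds` (NULL until [calibrate_bundle()]).
#' @export
model_bundle <- function(pwm, dipwm, markov, pruned_markov,
                         alignment = NULL) {
  models <- list(pwm = pwm, dipwm = dipwm, markov = markov,
                 pruned_markov = pruned_markov)
  Ls <- vapply(models, `[[`, numeric(1), "L")
  if (length(unique(Ls)) != 1L) {
    stop("all bundle members must share one motif length")
  }
  structure(list(models = models, alignment = alignment, thresholds = NULL),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> %d models, length %d\n",
              length(x$models), x$models[[1L]]$L))
  if (!is.null(x$thresholds)) {
    cat("  thresholds:",
        paste(sprintf("%s=%.3f", names(x$thresholds), x$thresholds),
              collapse = ", "), "\n")
  }
  invisible(x)
}
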