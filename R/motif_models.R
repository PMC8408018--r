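#' Validate a site alignment
#'
#' A site alignment is a character vector of equal-length DNA strings over
#' A,C,G,T (no N) — the raw material every model family is trained from.
#'
#' @param sites character vector of sites.
#' @param min_length minimum admissible motif length.
#' @return the alignment, uppercased, invisibly checked.
#' @keywords internal
validate_sites <- function(sites, min_length = 4L) {
  if (length(sites) == 0L) stop("empty site alignment")
  sites <- toupper(sites)
  L <- unique(nchar(sites))
  if (length(L) != 1L) stop("sites must all have the same length")
  if (L < min_length) stop("site length ", L, " below minimum ", min_length)
  if (any(grepl("[^ACGT]", sites))) {
    stop("sites must contain only A, C, G, T")
  }
  sites
}

# integer code matrix: one row per site, one column per motif position
site_code_matrix <- function(sites) {
  matrix(unlist(lapply(sites, encode_dna), use.names = FALSE),
         nrow = length(sites), byrow = TRUE)
}

#' Train a position weight matrix
#'
#' Per-position letter frequencies with a background-distributed pseudocount:
#' `freq[j, b] = (count_j(b) + c * background[b]) / (N + c)`. The scoring
#' matrix is the log2 odds `log2(freq / background)`, so a window whose
#' column frequencies equal the background scores 0.
#'
#' @param sites site alignment (equal-length ACGT strings).
#' @param background mononucleotide background, numeric 4-vector summing
#'   to 1 (default uniform).
#' @param pseudocount total pseudocount `c` distributed by the background.
#' @return an object of class `c("pwm_model", "motif_model")` with elements
#'   `L`, `freq` (L x 4), `background`, `pseudocount`, `mat` (log2-odds),
#'   `nsites`.
#' @export
train_pwm <- function(sites, background = rep(0.25, 4), pseudocount = 1) {
  sites <- validate_sites(sites, min_length = 1L)
  stopifnot(length(background) == 4L, abs(sum(background) - 1) < 1e-6)
  codes <- site_code_matrix(sites)
  N <- nrow(codes)
  L <- ncol(codes)
  freq <- matrix(0, L, 4L, dimnames = list(NULL, DNA_LETTERS))
  for (j in seq_len(L)) {
    cnt <- tabulate(codes[, j], nbins = 4L)
    freq[j, ] <- (cnt + pseudocount * background) / (N + pseudocount)
  }
  structure(list(L = L, freq = freq,
                 background = setNames(as.numeric(background), DNA_LETTERS),
                 pseudocount = pseudocount,
                 mat = log2(sweep(freq, 2L, background, "/")),
                 nsites = N),
            class = c("pwm_model", "motif_model"))
}

#' Train a dinucleotide position weight matrix
#'
#' Row `j` holds the 16 frequencies of the adjacent letter pair at positions
#' `(j, j+1)`, pseudocounted against a 16-category dinucleotide background
#' exactly as in [train_pwm()]. Captures nearest-neighbour dependence that a
#' mononucleotide PWM cannot express.
#'
#' @param sites site alignment with length >= 2.
#' @param background16 dinucleotide background, numeric 16-vector in
#'   AA, AC, ..., TT order summing to 1 (default uniform).
#' @param pseudocount total pseudocount distributed by the background.
#' @return class `c("dipwm_model", "motif_model")` with `freq` and log2-odds
#'   `mat` of dimension (L-1) x 16.
#' @export
train_dipwm <- function(sites, background16 = rep(1 / 16, 16),
                        pseudocount = 1) {
  sites <- validate_sites(sites, min_length = 2L)
  stopifnot(length(background16) == 16L, abs(sum(background16) - 1) < 1e-6)
  codes <- site_code_matrix(sites)
  N <- nrow(codes)
  L <- ncol(codes)
  freq <- matrix(0, L - 1L, 16L, dimnames = list(NULL, DINUC_LETTERS))
  for (j in seq_len(L - 1L)) {
    di <- dinuc_index(codes[, j], codes[, j + 1L])
    cnt <- tabulate(di, nbins = 16L)
    freq[j, ] <- (cnt + pseudocount * background16) / (N + pseudocount)
  }
  structure(list(L = L, freq = freq,
                 background16 = setNames(as.numeric(background16),
                                         DINUC_LETTERS),
                 pseudocount = pseudocount,
                 mat = log2(sweep(freq, 2L, background16, "/")),
                 nsites = N),
            class = c("dipwm_model", "motif_model"))
}

#' Train an inhomogeneous Markov motif model
#'
#' Position `j` carries conditional letter probabilities given the preceding
#' `min(j-1, k)` letters. Conditionals are estimated recursively with
#' interpolation toward the next-lower order:
#' `p_j^m(b | ctx) = (n_j(ctx, b) + alpha_m * p_j^{m-1}(b | ctx')) /
#'  (n_j(ctx) + alpha_m)`
#' where `ctx'` drops the most distant context letter. The order-0 base case
#' is the pseudocounted column frequency, identical to the [train_pwm()]
#' estimate, so an order-0 Markov model scores exactly like the PWM.
#'
#' @param sites site alignment.
#' @param order Markov order `k` (0..5).
#' @param alphas interpolation strengths `alpha_1..alpha_k`; default is the
#'   geometric schedule `7 * 3^(m-1)`.
#' @param background mononucleotide background 4-vector.
#' @param pseudocount order-0 pseudocount (as in [train_pwm()]).
#' @return class `c("markov_model", "motif_model")` with `cond[[j]][[m+1]]`:
#'   the order-`m` conditional matrix (4^m contexts x 4 letters) at position
#'   `j`; `orders`: the per-position order used for scoring, `min(j-1, k)`
#'   until pruned by [prune_markov_orders()].
#' @export
train_markov <- function(sites, order = 2L, alphas = NULL,
                         background = rep(0.25, 4), pseudocount = 1) {
  if (order > 5L) stop("Markov order must not exceed 5 (got ", order, ")")
  if (order < 0L) stop("Markov order must be >= 0")
  sites <- validate_sites(sites, min_length = 1L)
  if (is.null(alphas)) alphas <- 7 * 3^(seq_len(order) - 1)
  if (order > 0L && length(alphas) < order) {
    stop("need ", order, " interpolation strengths, got ", length(alphas))
  }
  codes <- site_code_matrix(sites)
  N <- nrow(codes)
  L <- ncol(codes)
  cond <- vector("list", L)
  for (j in seq_len(L)) {
    mj <- min(j - 1L, order)
    per_order <- vector("list", mj + 1L)
    cnt0 <- tabulate(codes[, j], nbins = 4L)
    p0 <- (cnt0 + pseudocount * background) / (N + pseudocount)
    per_order[[1L]] <- matrix(p0, 1L, 4L, dimnames = list(NULL, DNA_LETTERS))
    if (mj > 0L) {
      for (m in seq_len(mj)) {
        # context code: preceding letters, nearest letter = least
        # significant base-4 digit
        ctx <- rep(0L, N)
        for (t in seq_len(m)) {
          ctx <- ctx + (codes[, j - t] - 1L) * 4L^(t - 1L)
        }
        ctx <- ctx + 1L
        ncx <- 4L^m
        nmat <- matrix(0, ncx, 4L)
        for (b in 1:4) {
          nmat[, b] <- tabulate(ctx[codes[, j] == b], nbins = ncx)
        }
        ntot <- rowSums(nmat)
        prev <- per_order[[m]]
        # parent context drops the most distant letter (highest digit)
        parent <- ((seq_len(ncx) - 1L) %% 4L^(m - 1L)) + 1L
        a <- alphas[m]
        pm <- (nmat + a * prev[parent, , drop = FALSE]) / (ntot + a)
        dimnames(pm) <- list(context_labels(m), DNA_LETTERS)
        per_order[[m + 1L]] <- pm
      }
    }
    cond[[j]] <- per_order
  }
  structure(list(L = L, order = as.integer(order),
                 orders = pmin(seq_len(L) - 1L, order),
                 cond = cond, alphas = alphas,
                 background = setNames(as.numeric(background), DNA_LETTERS),
                 pseudocount = pseudocount, nsites = N),
            class = c("markov_model", "motif_model"))
}

# labels for the 4^m contexts of an order-m conditional, written 5'->3'
# (most distant letter first); context index encodes the nearest letter in
# the least significant digit
context_labels <- function(m) {
  if (m == 0L) return(NULL)
  idx <- seq_len(4L^m) - 1L
  vapply(idx, function(i) {
    digits <- integer(m)
    for (t in seq_len(m)) {
      digits[t] <- i %% 4L
      i <- i %/% 4L
    }
    paste(DNA_LETTERS[rev(digits) + 1L], collapse = "")
  }, character(1))
}

#' Prune per-position Markov orders by BIC
#'
#' For every motif position independently, re-scores the training sites under
#' each admissible order `0..min(j-1, k)` and keeps the order minimising the
#' Bayesian information criterion `-2 * loglik + 3 * 4^m * log(N)`; ties go
#' to the lower order. This yields a parsimonious context model in which
#' positions without genuine upstream dependence fall back to order 0.
#'
#' @param model a trained [train_markov()] model.
#' @param sites the alignment the model was trained on.
#' @return the model with `orders` replaced by the selected per-position
#'   orders and `per_position_order` recorded.
#' @export
prune_markov_orders <- function(model, sites) {
  stopifnot(inherits(model, "markov_model"))
  sites <- validate_sites(sites, min_length = 1L)
  codes <- site_code_matrix(sites)
  N <- nrow(codes)
  if (ncol(codes) != model$L) stop("site length does not match model length")
  chosen <- integer(model$L)
  for (j in seq_len(model$L)) {
    mj <- min(j - 1L, model$order)
    bic <- numeric(mj + 1L)
    for (m in 0:mj) {
      pm <- model$cond[[j]][[m + 1L]]
      if (m == 0L) {
        ctx <- rep(1L, N)
      } else {
        ctx <- rep(0L, N)
        for (t in seq_len(m)) {
          ctx <- ctx + (codes[, j - t] - 1L) * 4L^(t - 1L)
        }
        ctx <- ctx + 1L
      }
      ll <- sum(log(pm[cbind(ctx, codes[, j])]))
      bic[m + 1L] <- -2 * ll + 3 * 4^m * log(N)
    }
    chosen[j] <- which.min(bic) - 1L  # which.min takes the first minimum
  }
  model$orders <- chosen
  model$per_position_order <- chosen
  model
}

#' Score one window under a motif model
#'
#' Log2 likelihood ratio of the window under the model versus its
#' background; strand `"-"` scores the reverse complement of the window.
#' Higher scores indicate windows more likely to be functional binding
#' sites. A window containing N returns `NA` (unscorable) rather than
#' raising an error.
#'
#' @param model a trained motif model (PWM, diPWM or Markov).
#' @param window DNA string of length `model$L`.
#' @param strand `"+"` or `"-"`.
#' @return numeric score in log2 units, or `NA` for unscorable windows.
#' @export
score_window <- function(model, window, strand = "+") {
  stopifnot(nchar(window) == model$L, strand %in% c("+", "-"))
  codes <- encode_dna(window)
  if (strand == "-") codes <- revcomp_codes(codes)
  if (anyNA(codes)) return(NA_real_)
  score_codes(model, codes)
}

score_codes <- function(model, codes) UseMethod("score_codes")

#' @export
score_codes.pwm_model <- function(model, codes) {
  sum(model$mat[cbind(seq_len(model$L), codes)])
}

#' @export
score_codes.dipwm_model <- function(model, codes) {
  j <- seq_len(model$L - 1L)
  sum(model$mat[cbind(j, dinuc_index(codes[j], codes[j + 1L]))])
}

#' @export
score_codes.markov_model <- function(model, codes) {
  s <- 0
  for (j in seq_len(model$L)) {
    m <- model$orders[j]
    pm <- model$cond[[j]][[m + 1L]]
    if (m == 0L) {
      ctx <- 1L
    } else {
      ctx <- 1L
      for (t in seq_len(m)) {
        ctx <- ctx + (codes[j - t] - 1L) * 4L^(t - 1L)
      }
    }
    s <- s + log2(pm[ctx, codes[j]]) - log2(model$background[codes[j]])
  }
  unname(s)
}

#' Raw position frequency matrix of a site alignment
#'
#' Column frequencies with no pseudocount — the matrix used for logos and
#' for similarity comparison against reference motifs.
#'
#' @param sites site alignment.
#' @return L x 4 matrix of frequencies, columns A, C, G, T, rows sum to 1.
#' @export
frequency_matrix_from_sites <- function(sites) {
  sites <- validate_sites(sites, min_length = 1L)
  codes <- site_code_matrix(sites)
  L <- ncol(codes)
  freq <- matrix(0, L, 4L, dimnames = list(NULL, DNA_LETTERS))
  for (j in seq_len(L)) {
    cnt <- tabulate(codes[, j], nbins = 4L)
    freq[j, ] <- cnt / sum(cnt)
  }
  freq
}

#' Per-position information content of a frequency matrix
#'
#' `IC_j = 2 + sum_b f_jb * log2(f_jb)` bits, in \[0, 2\]: 0 for a uniform
#' column, 2 for a fully conserved one. Zero frequencies contribute 0.
#'
#' @param freq L x 4 frequency matrix.
#' @return numeric vector of L values in bits.
#' @export
information_content <- function(freq) {
  apply(freq, 1L, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
}

#' Consensus string of a frequency matrix or alignment
#'
#' Per-position most frequent letter (first of A,C,G,T on ties).
#'
#' @param x an L x 4 frequency matrix or a site alignment.
#' @return consensus DNA string.
#' @export
consensus_string <- function(x) {
  if (is.character(x)) x <- frequency_matrix_from_sites(x)
  paste(DNA_LETTERS[apply(x, 1L, which.max)], collapse = "")
}

#' @export
print.motif_model <- function(x, ...) {
  kind <- class(x)[1L]
  cat(sprintf("<%s> length %d, trained on %d sites\n", kind, x$L, x$nsites))
  if (inherits(x, "markov_model")) {
    cat("  per-position orders:", paste(x$orders, collapse = " "), "\n")
  }
  invisible(x)
}
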