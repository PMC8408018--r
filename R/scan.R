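#' Score every window of a sequence under a model
#'
#' Vectorised forward-strand scoring of all `nchar(seq) - L + 1` windows.
#' Windows containing N (or any non-ACGT letter) score `NA`.
#'
#' @param model a trained motif model.
#' @param seq DNA string (or an integer code vector from [encode_dna()]).
#' @return numeric vector of window scores (log2 units), length
#'   `nchar(seq) - L + 1`; `numeric(0)` if the sequence is shorter than L.
#' @export
score_sequence <- function(model, seq) {
  codes <- if (is.character(seq)) encode_dna(seq) else seq
  n <- length(codes)
  if (n < model$L) return(numeric(0))
  score_all_windows(model, codes)
}

score_all_windows <- function(model, codes) UseMethod("score_all_windows")

#' @export
score_all_windows.pwm_model <- function(model, codes) {
  L <- model$L
  nw <- length(codes) - L + 1L
  s <- numeric(nw)
  for (j in seq_len(L)) {
    row <- model$mat[j, ]
    s <- s + row[codes[seq_len(nw) + j - 1L]]
  }
  unname(s)
}

#' @export
score_all_windows.dipwm_model <- function(model, codes) {
  L <- model$L
  nw <- length(codes) - L + 1L
  a <- codes[-length(codes)]
  b <- codes[-1L]
  di <- dinuc_index(a, b)  # NA propagates
  s <- numeric(nw)
  for (j in seq_len(L - 1L)) {
    row <- model$mat[j, ]
    s <- s + row[di[seq_len(nw) + j - 1L]]
  }
  unname(s)
}

#' @export
score_all_windows.markov_model <- function(model, codes) {
  L <- model$L
  nw <- length(codes) - L + 1L
  idx0 <- seq_len(nw)
  logbg <- log2(model$background)
  s <- numeric(nw)
  for (j in seq_len(L)) {
    m <- model$orders[j]
    logpm <- log2(model$cond[[j]][[m + 1L]])
    pos <- idx0 + j - 1L
    letter <- codes[pos]
    if (m == 0L) {
      ctx <- rep(1L, nw)
    } else {
      ctx <- rep(1L, nw)
      for (t in seq_len(m)) {
        ctx <- ctx + (codes[pos - t] - 1L) * 4L^(t - 1L)
      }
    }
    ncx <- nrow(logpm)
    flat <- as.vector(logpm)  # column-major: [ (b-1)*ncx + ctx ]
    s <- s + flat[(letter - 1L) * ncx + ctx] - logbg[letter]
  }
  unname(s)
}

#' Score both strands of a sequence
#'
#' @param model trained motif model.
#' @param seq DNA string.
#' @return list with `fwd` and `rev`, both indexed by the forward-strand
#'   window start: `rev[i]` is the score of the reverse complement of the
#'   window starting at forward position `i`.
#' @export
scan_scores <- function(model, seq) {
  codes <- encode_dna(seq)
  fwd <- score_sequence(model, codes)
  rc <- score_sequence(model, revcomp_codes(codes))
  list(fwd = fwd, rev = rev(rc))
}
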