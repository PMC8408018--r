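#' Similarity between two frequency matrices
#'
#' Slides the query over the reference in both orientations (reverse
#' complement = reversed column order with complemented letter order) and,
#' at every offset with at least `min_overlap` overlapping columns, scores
#' the placement by the sum of per-column Pearson correlations of the two
#' 4-vectors divided by `min(L, M)` — the maximum number of columns any
#' placement can align. Normalising by the shorter matrix length rather
#' than by the overlap size means a short perfect partial overlap can never
#' tie a full-length match, which keeps the permutation null of
#' [comparison_pvalue()] resolvable. The best placement over all offsets
#' and orientations is returned. A column pair where both columns are
#' (numerically) constant correlates 1 if equal and 0 otherwise; a single
#' constant column correlates 0.
#'
#' @param query L x 4 frequency matrix (columns A, C, G, T).
#' @param reference M x 4 frequency matrix.
#' @param min_overlap minimum overlapping columns per admissible offset.
#' @return list of class `comparison_result`: `best_similarity`,
#'   `best_offset` (query start minus reference start, in columns),
#'   `orientation` (`"forward"` or `"revcomp"`).
#' @export
compare_matrices <- function(query, reference, min_overlap = 4L) {
  stopifnot(ncol(query) == 4L, ncol(reference) == 4L)
  L <- nrow(query); M <- nrow(reference)
  if (L < min_overlap || M < min_overlap) {
    stop("matrices too short for the minimum overlap of ", min_overlap)
  }
  zq <- standardize_columns(query)
  zr <- standardize_columns(reference)
  best <- list(best_similarity = -Inf, best_offset = NA_integer_,
               orientation = NA_character_)
  for (orient in c("forward", "revcomp")) {
    q <- if (orient == "forward") zq else revcomp_standardized(zq)
    # offset o: query row i aligns with reference row i + o
    for (o in seq(-(L - min_overlap), M - min_overlap)) {
      qi <- max(1L, 1L - o):min(L, M - o)
      if (length(qi) < min_overlap) next
      ri <- qi + o
      sim <- sum(column_correlations(q, qi, zr, ri)) / min(L, M)
      if (sim > best$best_similarity) {
        best <- list(best_similarity = sim, best_offset = o,
                     orientation = orient)
      }
    }
  }
  structure(best, class = "comparison_result")
}

# per-row standardisation for fast Pearson over 4-vectors; a constant row is
# marked by an attribute and standardised to zeros
standardize_columns <- function(mat) {
  mu <- rowMeans(mat)
  cen <- mat - mu
  ss <- sqrt(rowSums(cen^2))
  const <- ss < 1e-12
  z <- cen / ifelse(const, 1, ss)
  attr(z, "const") <- const
  attr(z, "values") <- mat
  z
}

revcomp_standardized <- function(z) {
  out <- z[rev(seq_len(nrow(z))), 4:1, drop = FALSE]
  attr(out, "const") <- rev(attr(z, "const"))
  attr(out, "values") <- attr(z, "values")[rev(seq_len(nrow(z))), 4:1,
                                           drop = FALSE]
  out
}

column_correlations <- function(zq, qi, zr, ri) {
  r <- rowSums(zq[qi, , drop = FALSE] * zr[ri, , drop = FALSE])
  cq <- attr(zq, "const")[qi]
  cr <- attr(zr, "const")[ri]
  both <- cq & cr
  if (any(both)) {
    eq <- rowSums(abs(attr(zq, "values")[qi, , drop = FALSE] -
                        attr(zr, "values")[ri, , drop = FALSE])) < 1e-9
    r[both] <- ifelse(eq[both], 1, 0)
  }
  r[xor(cq, cr)] <- 0
  r
}

#' Permutation p-value for a matrix comparison
#'
#' Null distribution: the query's columns are permuted `n_perm` times and
#' the comparison is re-run each time; the p-value is the add-one estimate
#' `(1 + #{null >= observed}) / (1 + n_perm)`, never exactly zero. A dataset
#' passes the enrichment filter when `p < 0.001` (strict), so `n_perm` must
#' be at least 999 to make the threshold reachable in principle and at
#' least 9999 in practice.
#'
#' @param query,reference frequency matrices as in [compare_matrices()].
#' @param n_perm number of column permutations (>= 999).
#' @param seed RNG seed.
#' @param min_overlap minimum overlap, passed through.
#' @return `comparison_result` with `p_value` and `passed` added.
#' @export
comparison_pvalue <- function(query, reference, n_perm = 9999L, seed = 1L,
                              min_overlap = 4L) {
  if (n_perm < 999L) {
    stop("n_perm must be >= 999 to resolve the 0.001 threshold")
  }
  obs <- compare_matrices(query, reference, min_overlap)
  rng <- local_rng(seed)
  on.exit(rng())
  L <- nrow(query)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- query[sample(L), , drop = FALSE]
    null <- compare_matrices(perm, reference, min_overlap)
    if (null$best_similarity >= obs$best_similarity) hits <- hits + 1L
  }
  obs$p_value <- (1 + hits) / (1 + n_perm)
  obs$passed <- obs$p_value < 0.001
  obs
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> similarity %.4f at offset %d (%s)",
              x$best_similarity, x$best_offset, x$orientation))
  if (!is.null(x$p_value)) {
    cat(sprintf(", p = %.2g (%s)", x$p_value,
                if (x$passed) "enriched" else "not enriched"))
  }
  cat("\n")
  invisible(x)
}
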