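#' @importFrom stats sd rnorm runif median quantile setNames wilcox.test cor
#' @importFrom utils head write.table read.table combn
NULL

DNA_LETTERS <- c("A", "C", "G", "T")

# ordered so that pair (a, b) sits at index (a-1)*4 + b: AA, AC, AG, AT, CA, ...
DINUC_LETTERS <- paste0(rep(DNA_LETTERS, each = 4L), rep(DNA_LETTERS, 4L))

# byte-indexed lookup: A/C/G/T -> 1..4, everything else (incl. N) -> NA
.dna_code_table <- local({
  v <- rep(NA_integer_, 256L)
  v[utf8ToInt("A")] <- 1L
  v[utf8ToInt("C")] <- 2L
  v[utf8ToInt("G")] <- 3L
  v[utf8ToInt("T")] <- 4L
  v
})

#' Encode a DNA string as integer codes
#'
#' A,C,G,T map to 1..4; any other letter (N, gap) becomes `NA`. Input is
#' uppercased first, so soft-masked genome sequence scores identically to
#' unmasked sequence.
#'
#' @param seq single character string.
#' @return integer vector of length `nchar(seq)`.
#' @keywords internal
encode_dna <- function(seq) {
  .dna_code_table[utf8ToInt(toupper(seq))]
}

#' Decode integer codes back to a DNA string
#' @param codes integer vector over 1..4 (NA becomes "N").
#' @keywords internal
decode_dna <- function(codes) {
  ch <- DNA_LETTERS[codes]
  ch[is.na(ch)] <- "N"
  paste(ch, collapse = "")
}

#' Reverse complement of DNA strings
#'
#' Vectorised over the input; N is self-complementary.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(comp, function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

# complement in code space: 1<->4, 2<->3; NA stays NA
revcomp_codes <- function(codes) {
  rev(5L - codes)
}

#' Mononucleotide composition of sequences
#'
#' Letter frequencies over A,C,G,T pooled across all sequences; N and other
#' letters are ignored. Used as the default scanning background.
#'
#' @param seqs character vector of DNA sequences.
#' @param pseudo small count added per letter so no frequency is zero.
#' @return named numeric 4-vector summing to 1.
#' @export
estimate_background <- function(seqs, pseudo = 1) {
  codes <- unlist(lapply(seqs, encode_dna), use.names = FALSE)
  n <- tabulate(codes, nbins = 4L) + pseudo
  setNames(n / sum(n), DNA_LETTERS)
}

#' Dinucleotide composition of sequences
#'
#' Frequencies of the 16 adjacent letter pairs pooled across sequences;
#' pairs touching an N are skipped.
#'
#' @inheritParams estimate_background
#' @return named numeric 16-vector (AA, AC, AG, AT, CA, ...) summing to 1.
#' @export
estimate_background_di <- function(seqs, pseudo = 1) {
  counts <- numeric(16L)
  for (s in seqs) {
    codes <- encode_dna(s)
    n <- length(codes)
    if (n < 2L) next
    a <- codes[-n]
    b <- codes[-1L]
    ok <- !is.na(a) & !is.na(b)
    di <- (a[ok] - 1L) * 4L + b[ok]
    counts <- counts + tabulate(di, nbins = 16L)
  }
  counts <- counts + pseudo
  setNames(counts / sum(counts), DINUC_LETTERS)
}

# dinucleotide index of a code pair (a, b): (a-1)*4 + b, in 1..16
dinuc_index <- function(a, b) (a - 1L) * 4L + b

# deterministic child seed: keeps derived seeds within 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
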