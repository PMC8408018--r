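#' Read ChIP-seq peaks from a BED file
#'
#' Parses BED3--BED6. Column 5, when present, is interpreted as the peak
#' quality score, -10*log10(p-value) as emitted by MACS-style peak callers.
#' Coordinates follow the BED convention: 0-based, half-open.
#'
#' @param path path to a tab-separated BED file (no header).
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`.
#'   Peaks appear in file order. A missing name column is synthesised as
#'   `peak_<line>`; a missing score column defaults to 0.
#' @details Malformed records (non-integer coordinates, `start >= end`)
#'   raise an error naming the offending line number.
#' @export
read_bed_peaks <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("no peak records in ", path)
    return(empty_peaks())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3L) stop("BED file must have >= 3 tab-separated columns")
  n <- length(fields)
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop("malformed coordinate on line ", lineno[bad[1L]], ": '",
         lines[bad[1L]], "'")
  }
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    stop("start >= end on line ", lineno[bad[1L]], ": '", lines[bad[1L]], "'")
  }
  name <- vapply(seq_len(n), function(i) {
    f <- fields[[i]]
    if (length(f) >= 4L && nzchar(f[[4L]])) f[[4L]] else paste0("peak_", i)
  }, character(1))
  score <- vapply(seq_len(n), function(i) {
    f <- fields[[i]]
    if (length(f) >= 5L) {
      s <- suppressWarnings(as.numeric(f[[5L]]))
      if (is.na(s)) stop("non-numeric score on line ", i, ": '", f[[5L]], "'")
      s
    } else 0
  }, numeric(1))
  data.frame(chrom = chrom, start = start, end = end, name = name,
             score = score, stringsAsFactors = FALSE)
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), stringsAsFactors = FALSE)
}

#' Select the top-scoring peaks
#'
#' Sorts by the quality score in decreasing order (stable: ties keep their
#' input order) and keeps the first `min(n, nrow)` peaks.
#'
#' @param peaks peak data.frame from [read_bed_peaks()].
#' @param n number of peaks to keep (e.g. 4000 for a full dataset).
#' @return the selected peaks, scores non-increasing.
#' @export
select_top_peaks <- function(peaks, n) {
  stopifnot(n >= 1)
  if (nrow(peaks) == 0L) {
    warning("empty peak set")
    return(peaks)
  }
  ord <- order(-peaks$score)  # radix order is stable
  out <- peaks[ord, , drop = FALSE]
  out <- head(out, n)
  rownames(out) <- NULL
  out
}

#' Read a FASTA file as a named character vector
#'
#' Sequences are uppercased on ingestion; N letters are retained.
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Extract peak sequences from a genome
#'
#' Slices each peak's interval (0-based half-open) out of the genome,
#' forward strand, uppercase. Peaks on missing chromosomes or extending
#' past the chromosome end are dropped with a warning.
#'
#' @param genome either a path to a genome FASTA or a named character vector
#'   of chromosome sequences.
#' @param peaks peak data.frame.
#' @return named character vector of peak sequences (names = peak names).
#' @export
extract_sequences <- function(genome, peaks) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  genome <- toupper(genome)
  out <- character(0)
  for (i in seq_len(nrow(peaks))) {
    chrom <- peaks$chrom[i]
    if (!chrom %in% names(genome)) {
      warning("peak ", peaks$name[i], ": chromosome ", chrom,
              " not in genome; dropped")
      next
    }
    len <- nchar(genome[[chrom]])
    if (peaks$end[i] > len || peaks$start[i] < 0L) {
      warning("peak ", peaks$name[i], ": interval [", peaks$start[i], ",",
              peaks$end[i], ") out of bounds for ", chrom,
              " (length ", len, "); dropped")
      next
    }
    out[peaks$name[i]] <- substr(genome[[chrom]], peaks$start[i] + 1L,
                                 peaks$end[i])
  }
  out
}

#' Mononucleotide shuffle of a sequence
#'
#' Seeded Fisher--Yates permutation of the letters; the letter multiset
#' (including N) is preserved exactly. Used to build negative sets for
#' cross-validation.
#'
#' @param seq a DNA string.
#' @param seed integer RNG seed; the same seed always yields the same
#'   permutation.
#' @return the shuffled string.
#' @export
shuffle_sequence <- function(seq, seed) {
  letters <- utf8ToInt(seq)
  rng <- local_rng(seed)
  on.exit(rng())
  intToUtf8(sample(letters))
}

# set the RNG to a seeded state, returning a restorer for on.exit()
local_rng <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}
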