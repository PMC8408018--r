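#' Synthetic dataset specification
#'
#' Parameters of the planted-motif peak-set generator. The defaults emulate
#' a transcription-factor ChIP-seq dataset with a FOXA2-like degenerate
#' consensus: a few hundred ~300-bp peaks, 90 per cent of which carry one
#' mutated copy of GTAAACA near the peak centre, on a random strand, over a
#' 41 per cent GC background.
#'
#' @param n_peaks number of peaks.
#' @param peak_length peak length in bp.
#' @param gc background GC fraction.
#' @param consensus planted word.
#' @param mutation_rate per-letter substitution probability of the planted
#'   copy.
#' @param occupancy fraction of peaks receiving a site.
#' @param position_spread standard deviation (bp) of the site centre around
#'   the peak centre.
#' @param strand_prob probability of minus-strand placement.
#' @param seed RNG seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_peaks = 200L, peak_length = 301L, gc = 0.41,
                           consensus = "GTAAACA", mutation_rate = 0.1,
                           occupancy = 0.9, position_spread = 30,
                           strand_prob = 0.5, seed = 1L) {
  stopifnot(occupancy >= 0, occupancy <= 1, mutation_rate >= 0,
            mutation_rate <= 1, gc >= 0, gc <= 1, strand_prob >= 0,
            strand_prob <= 1, peak_length > nchar(consensus))
  structure(list(n_peaks = as.integer(n_peaks),
                 peak_length = as.integer(peak_length), gc = gc,
                 consensus = toupper(consensus),
                 mutation_rate = mutation_rate, occupancy = occupancy,
                 position_spread = position_spread,
                 strand_prob = strand_prob, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate motif-free background sequences
#'
#' Independent letters with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1-gc)/2`; deterministic for a fixed seed. Stands in for
#' a promoter background set (regions upstream of transcription starts)
#' in self-contained runs.
#'
#' @param n number of sequences.
#' @param length sequence length (bp).
#' @param gc GC fraction.
#' @param seed RNG seed.
#' @return named character vector (`bg_1`, ...).
#' @export
generate_background <- function(n, length, gc = 0.41, seed = 1L) {
  rng <- local_rng(seed)
  on.exit(rng())
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  out <- vapply(seq_len(n), function(i) {
    paste(sample(DNA_LETTERS, length, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  names(out) <- paste0("bg_", seq_len(n))
  out
}

# one mutated copy of the consensus: each letter substituted independently
# with probability `rate` (to a different letter)
mutate_word <- function(word, rate) {
  codes <- encode_dna(word)
  hit <- runif(length(codes)) < rate
  if (any(hit)) {
    for (i in which(hit)) {
      codes[i] <- sample(setdiff(1:4, codes[i]), 1L)
    }
  }
  list(word = decode_dna(codes), n_mut = sum(hit))
}

#' Generate a synthetic peak set with planted motif sites
#'
#' Draws motif-free peak sequences, plants one (possibly mutated) copy of
#' the consensus into an `occupancy` fraction of them at a Gaussian-jittered
#' position around the peak centre (clipped to keep the site inside the
#' peak) on a random strand, and assigns decreasing quality scores so that
#' top-peak selection is exercised. Everything is reproducible from the
#' seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `peaks` (BED-style data.frame: chrom, start, end, name,
#'   score), `sequences` (named character vector), `truth` (data.frame:
#'   peak_id, start, end, strand, n_mutations — 0-based half-open offsets of
#'   the planted sites).
#' @export
generate_peaks <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  w <- nchar(spec$consensus)
  if (w >= spec$peak_length) stop("consensus longer than peak")
  rng <- local_rng(spec$seed)
  on.exit(rng())
  p <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2, (1 - spec$gc) / 2)
  n <- spec$n_peaks
  seqs <- character(n)
  truth <- list()
  has_site <- runif(n) < spec$occupancy
  centre <- (spec$peak_length - w) / 2
  for (i in seq_len(n)) {
    letters <- sample(DNA_LETTERS, spec$peak_length, replace = TRUE,
                      prob = p)
    if (has_site[i]) {
      start <- round(centre + rnorm(1, 0, spec$position_spread))
      start <- max(0L, min(spec$peak_length - w, as.integer(start)))
      mut <- mutate_word(spec$consensus, spec$mutation_rate)
      site <- mut$word
      strand <- if (runif(1) < spec$strand_prob) "-" else "+"
      placed <- if (strand == "-") revcomp(site) else site
      letters[(start + 1L):(start + w)] <- strsplit(placed, "")[[1L]]
      truth[[length(truth) + 1L]] <- data.frame(
        peak_id = paste0("peak_", i), start = start, end = start + w,
        strand = strand, n_mutations = mut$n_mut, stringsAsFactors = FALSE)
    }
    seqs[i] <- paste(letters, collapse = "")
  }
  names(seqs) <- paste0("peak_", seq_len(n))
  # decreasing MACS-like quality scores with jitter, kept non-negative
  score <- sort(runif(n, 10, 200), decreasing = TRUE)
  gap <- 50L
  starts <- (seq_len(n) - 1L) * (spec$peak_length + gap)
  peaks <- data.frame(chrom = "chrSim", start = starts,
                      end = starts + spec$peak_length,
                      name = names(seqs), score = score,
                      stringsAsFactors = FALSE)
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(peak_id = character(), start = integer(), end = integer(),
               strand = character(), n_mutations = integer(),
               stringsAsFactors = FALSE)
  list(peaks = peaks, sequences = seqs, truth = truth)
}

#' Write a complete synthetic dataset directory
#'
#' Emits `peaks.bed`, `peaks.fasta`, `promoters.fasta`, `truth.tsv` and
#' `reference_pfm.txt` (the planted-consensus frequency matrix, usable by
#' the enrichment filter) into `dir` — a ready-to-run pipeline input.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if missing).
#' @param n_background number of background sequences.
#' @param background_length background sequence length (bp).
#' @return `dir`, invisibly.
#' @export
simulate_dataset <- function(spec = synthetic_spec(), dir,
                             n_background = 1000L,
                             background_length = 2000L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_peaks(spec)
  write.table(sim$peaks, file.path(dir, "peaks.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_fasta(sim$sequences, file.path(dir, "peaks.fasta"))
  bg <- generate_background(n_background, background_length, spec$gc,
                            derive_seed(spec$seed, 999L))
  write_fasta(bg, file.path(dir, "promoters.fasta"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ref <- consensus_pfm(spec$consensus)
  write_pfm_meme(ref, file.path(dir, "reference_pfm.txt"),
                 name = spec$consensus)
  invisible(dir)
}

#' Frequency matrix of a consensus word
#'
#' A near-degenerate matrix putting `conf` on the consensus letter of each
#' column — the synthetic stand-in for a curated reference motif.
#'
#' @param word consensus string.
#' @param conf weight of the consensus letter per column.
#' @return L x 4 frequency matrix.
#' @export
consensus_pfm <- function(word, conf = 0.85) {
  codes <- encode_dna(toupper(word))
  L <- length(codes)
  freq <- matrix((1 - conf) / 3, L, 4L, dimnames = list(NULL, DNA_LETTERS))
  freq[cbind(seq_len(L), codes)] <- conf
  freq
}
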