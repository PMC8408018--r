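#' Write a frequency matrix in MEME minimal format
#'
#' @param freq L x 4 frequency matrix (columns A, C, G, T).
#' @param path output path.
#' @param name motif name written in the MOTIF line.
#' @param nsites site count for the header (optional).
#' @export
write_pfm_meme <- function(freq, path, name = "motif", nsites = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", "",
               paste("MOTIF", name),
               sprintf("letter-probability matrix: alength= 4 w= %d%s",
                       nrow(freq),
                       if (is.na(nsites)) "" else
                         sprintf(" nsites= %d", nsites))), con)
  writeLines(apply(freq, 1L, function(r) {
    paste(sprintf("%.6f", r), collapse = "  ")
  }), con)
  invisible(path)
}

#' Read a plain-text position frequency matrix
#'
#' Understands the MEME minimal dialect (`letter-probability matrix` block),
#' the JASPAR dialect (`>name` then four `A [ ... ]` rows), and a bare
#' whitespace-separated L x 4 (or 4 x L) numeric table. Count matrices are
#' normalised to frequencies.
#'
#' @param path path to the matrix file.
#' @return L x 4 frequency matrix, columns A, C, G, T, rows summing to 1.
#' @export
read_pfm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  mat <- NULL
  if (any(grepl("^letter-probability matrix", lines))) {
    i <- which(grepl("^letter-probability matrix", lines))[1L]
    rows <- list()
    for (j in (i + 1L):length(lines)) {
      v <- suppressWarnings(as.numeric(strsplit(lines[j], "\\s+")[[1L]]))
      if (anyNA(v) || length(v) != 4L) break
      rows[[length(rows) + 1L]] <- v
    }
    mat <- do.call(rbind, rows)
  } else if (any(grepl("^[ACGT]\\s*\\[", lines))) {
    rows <- lapply(c("A", "C", "G", "T"), function(b) {
      ln <- lines[grepl(paste0("^", b, "\\s*\\["), lines)][1L]
      nums <- gsub("^[ACGT]\\s*\\[|\\]", "", ln)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1L]])
    })
    mat <- t(do.call(rbind, rows))
  } else {
    numeric_lines <- lines[!startsWith(lines, ">") & !startsWith(lines, "#")]
    vals <- lapply(numeric_lines, function(l) {
      suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1L]]))
    })
    vals <- vals[!vapply(vals, anyNA, logical(1))]
    m <- do.call(rbind, vals)
    mat <- if (ncol(m) == 4L) m else if (nrow(m) == 4L) t(m) else
      stop("cannot interpret matrix layout in ", path)
  }
  if (is.null(mat) || nrow(mat) == 0L) stop("no matrix found in ", path)
  colnames(mat) <- DNA_LETTERS
  sweep(mat, 1L, rowSums(mat), "/")
}

#' Write a frequency matrix as a simple TSV
#'
#' @param freq L x 4 frequency matrix.
#' @param path output path.
#' @export
write_pfm_tsv <- function(freq, path) {
  df <- data.frame(position = seq_len(nrow(freq)), freq)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialise a Markov motif model to a key-value text format
#'
#' One line per (position, context, letter): tab-separated
#' `position  order  context  letter  probability`, preceded by `#`-comment
#' header lines recording length, order, per-position orders and
#' interpolation strengths. Only the per-position conditionals at the
#' scoring order are written.
#'
#' @param model a `markov_model`.
#' @param path output path.
#' @export
write_markov_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# markov motif model: L=%d order=%d", model$L,
                       model$order),
               paste0("# per_position_order\t",
                      paste(model$orders, collapse = ",")),
               paste0("# alphas\t", paste(model$alphas, collapse = ",")),
               paste0("# background\t",
                      paste(sprintf("%.6f", model$background),
                            collapse = ",")),
               "position\torder\tcontext\tletter\tprobability"), con)
  for (j in seq_len(model$L)) {
    m <- model$orders[j]
    pm <- model$cond[[j]][[m + 1L]]
    ctx <- if (m == 0L) "-" else context_labels(m)
    for (ci in seq_len(nrow(pm))) {
      for (b in 1:4) {
        writeLines(sprintf("%d\t%d\t%s\t%s\t%.8g", j, m, ctx[ci],
                           DNA_LETTERS[b], pm[ci, b]), con)
      }
    }
  }
  invisible(path)
}
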