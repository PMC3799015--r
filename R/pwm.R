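#' Construct a position weight matrix from nucleotide counts
#'
#' Counts plus a pseudocount are normalised per column to
#' probabilities, so each column of the resulting matrix sums to 1.
#'
#' @param id matrix identifier.
#' @param counts 4 x L numeric matrix of A, C, G, T counts (rows in
#'   that order, or named).
#' @param pseudocount non-negative count added to every cell before
#'   normalisation.
#' @return An object of class `PWM` with elements `id`, `mat` (4 x L
#'   probability matrix, rownames A/C/G/T) and `pseudocount`.
#' @export
pwm_from_counts <- function(id, counts, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) {
    stop_("PWM '", id, "': count block must have exactly 4 nucleotide rows, got ",
          nrow(counts))
  }
  if (pseudocount < 0) stop_("pseudocount must be >= 0")
  if (is.null(rownames(counts)) || !setequal(rownames(counts), c("A", "C", "G", "T"))) {
    rownames(counts) <- c("A", "C", "G", "T")
  }
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(counts < 0)) stop_("PWM '", id, "': negative count")
  counts <- counts + pseudocount
  cs <- colSums(counts)
  if (any(cs == 0)) {
    stop_("PWM '", id, "': column ", which(cs == 0)[1],
          " has all-zero counts and pseudocount 0")
  }
  mat <- sweep(counts, 2, cs, "/")
  structure(list(id = id, mat = mat, pseudocount = pseudocount), class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cons <- paste(rownames(x$mat)[apply(x$mat, 2, which.max)], collapse = "")
  cat("PWM '", x$id, "': length ", ncol(x$mat), ", consensus ", cons, "\n", sep = "")
  invisible(x)
}

#' Read JASPAR-style PWM count blocks
#'
#' Each block starts with a `>` header (first token = id) followed by
#' exactly four count rows (A, C, G, T), optionally letter-labelled and
#' bracketed, e.g. `A [ 2 0 5 ]`.
#'
#' @param path file of count blocks.
#' @param pseudocount added to every cell before per-column
#'   normalisation (see [pwm_from_counts()]).
#' @return Named list of `PWM` objects.
#' @export
read_pwm_counts <- function(path, pseudocount = 1) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- which(startsWith(lines, ">"))
  if (!length(starts)) stop_("no '>' PWM header found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  pwms <- list()
  for (b in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[b]])
    id <- strsplit(trimws(header), "\\s+")[[1]][1]
    body <- lines[seq(starts[b] + 1L, length.out = ends[b] - starts[b])]
    rows <- lapply(body, function(l) {
      l <- gsub("[][ACGTacgt]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(rows) != 4) {
      stop_("PWM '", id, "': count block must have exactly 4 nucleotide rows, got ",
            length(rows))
    }
    if (length(unique(lengths(rows))) != 1) {
      stop_("PWM '", id, "': ragged count rows")
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    pwms[[id]] <- pwm_from_counts(id, counts, pseudocount)
  }
  pwms
}

#' Write PWMs as JASPAR-style count blocks
#'
#' Probabilities are written scaled by `scale` (default 100) so the
#' file round-trips through [read_pwm_counts()] with pseudocount 0.
#' @param pwms list of `PWM` objects.
#' @param path output path.
#' @param scale multiplier turning probabilities into pseudo-counts.
#' @export
write_pwm_counts <- function(pwms, path, scale = 100) {
  lines <- character()
  for (p in pwms) {
    lines <- c(lines, paste0(">", p$id))
    for (b in c("A", "C", "G", "T")) {
      lines <- c(lines, paste0(b, " [ ",
                               paste(format(p$mat[b, ] * scale, trim = TRUE),
                                     collapse = " "), " ]"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# reverse-complement of a PWM probability matrix
revcomp_pwm_matrix <- function(mat) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- mat[comp[rownames(mat)], rev(seq_len(ncol(mat))), drop = FALSE]
  rownames(out) <- names(comp)
  out
}
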