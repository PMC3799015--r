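#' Construct a promoter set
#'
#' @param seqs named character vector of upper-case A/C/G/T/N
#'   sequences, names = gene symbols.
#' @param upstream,downstream window definition in nt around the TSS
#'   (`NA` when unknown, e.g. for sequences read directly from FASTA).
#' @param clipped logical vector flagging promoters whose window was
#'   clipped at a contig end.
#' @return An object of class `PromoterSet`.
#' @export
promoter_set <- function(seqs, upstream = NA_integer_, downstream = NA_integer_,
                         clipped = rep(FALSE, length(seqs))) {
  seqs <- toupper(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop_("promoter sequences must be named by gene symbol")
  }
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup)) stop_("duplicate promoter name: ", dup[1])
  if (any(!nzchar(seqs))) {
    stop_("empty promoter sequence for ", names(seqs)[!nzchar(seqs)][1])
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop_("promoter '", names(seqs)[bad][1],
                      "' contains characters outside A,C,G,T,N")
  structure(list(seqs = seqs,
                 window = c(upstream = upstream, downstream = downstream),
                 clipped = stats::setNames(clipped, names(seqs))),
            class = "PromoterSet")
}

#' @export
print.PromoterSet <- function(x, ...) {
  cat("PromoterSet:", length(x$seqs), "sequences, lengths",
      min(nchar(x$seqs)), "-", max(nchar(x$seqs)), "nt\n")
  invisible(x)
}

#' Read promoter sequences from FASTA
#'
#' Headers are taken as gene symbols; sequences are upper-cased and
#' restricted to the A,C,G,T,N alphabet.
#' @param path FASTA file.
#' @return A `PromoterSet` (window definition unknown).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nms <- sub("\\s.*$", "", names(ss))
  dup <- nms[duplicated(nms)]
  if (length(dup)) stop_("duplicate FASTA header: ", dup[1])
  promoter_set(stats::setNames(as.character(ss), nms))
}

#' Write sequences to FASTA
#' @param x a `PromoterSet` or named character vector.
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "PromoterSet")) x$seqs else x
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read BED6 intervals
#'
#' 0-based half-open coordinates with a strand column, as in the BED
#' standard.
#' @param path BED file (no header; >= 6 columns).
#' @return data.frame with columns chrom, start, end, name, score,
#'   strand.
#' @export
read_bed_intervals <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 6) stop_("BED file needs >= 6 columns (BED6)")
  tab <- tab[, 1:6]
  names(tab) <- c("chrom", "start", "end", "name", "score", "strand")
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  if (any(is.na(tab$start)) || any(is.na(tab$end))) {
    stop_("non-integer BED coordinates")
  }
  bad <- tab$start >= tab$end
  if (any(bad)) {
    stop_("BED interval '", tab$name[bad][1], "' has start >= end")
  }
  if (any(tab$start < 0)) stop_("negative BED start coordinate")
  if (!all(tab$strand %in% c("+", "-"))) {
    stop_("BED strand column must be '+' or '-'")
  }
  tab
}
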