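#' Construct a gene set
#'
#' @param name set name.
#' @param genes character vector of gene symbols (deduplicated).
#' @param direction `"up"`, `"down"` or `"unsigned"` — whether the set
#'   represents genes induced, repressed, or without an expected sign.
#' @return An object of class `GeneSet`.
#' @export
gene_set <- function(name, genes, direction = "unsigned") {
  direction <- match.arg(direction, c("up", "down", "unsigned"))
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop_("gene set '", name, "' is empty")
  structure(list(name = name, genes = genes, direction = direction),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat("GeneSet '", x$name, "' (", x$direction, "): ", length(x$genes),
      " genes\n", sep = "")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene...`.
#' If the description field is `up`/`down`/`unsigned` it is restored as
#' the set direction (the convention used by [write_gmt()]).
#'
#' @param path GMT file; lines starting with `#` are ignored.
#' @return Named list of `GeneSet` objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  sets <- list()
  for (i in which(keep)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop_("GMT line ", i, " has fewer than 3 tab-separated fields")
    }
    genes <- fields[-(1:2)]
    genes <- unique(genes[nzchar(genes)])
    if (!length(genes)) stop_("GMT line ", i, ": set '", fields[1], "' is empty")
    dir <- if (fields[2] %in% c("up", "down", "unsigned")) fields[2] else "unsigned"
    if (fields[1] %in% names(sets)) stop_("duplicate gene set name: ", fields[1])
    sets[[fields[1]]] <- gene_set(fields[1], genes, dir)
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' The direction is stored in the description field so that
#' [read_gmt()] round-trips it.
#' @param sets list of `GeneSet` objects (or plain character vectors,
#'   taken as unsigned sets named by the list names).
#' @param path output path.
#' @param header_lines optional provenance comment lines.
#' @export
write_gmt <- function(sets, path, header_lines = character()) {
  lines <- character()
  if (length(header_lines)) lines <- paste0("# ", header_lines)
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    if (!inherits(s, "GeneSet")) s <- gene_set(names(sets)[i], s)
    lines <- c(lines, paste(c(s$name, s$direction, s$genes), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a mouse-to-human ortholog table
#'
#' Two-column tab-separated file (`mouse`, `human`), many-to-one
#' allowed. Returned as a named character vector `mouse -> human`.
#' @param path TSV path (header optional; columns named `mouse`/`human`
#'   or taken positionally).
#' @export
read_ortholog_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2) stop_("ortholog table needs two columns (mouse, human)")
  mouse <- as.character(tab[[if ("mouse" %in% names(tab)) "mouse" else 1]])
  human <- as.character(tab[[if ("human" %in% names(tab)) "human" else 2]])
  if (any(is.na(mouse)) || any(is.na(human)) ||
      any(!nzchar(mouse)) || any(!nzchar(human))) {
    stop_("ortholog table contains empty symbols")
  }
  dup <- mouse[duplicated(mouse)]
  if (length(dup)) stop_("duplicate mouse symbol in ortholog table: ", dup[1])
  stats::setNames(human, mouse)
}
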