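#' Map mouse gene symbols to human orthologs
#'
#' Symbols found in the ortholog table are translated; the rest are
#' handled per `fallback`: `"uppercase"` applies the mouse-to-human
#' symbol convention (title-case -> upper-case), `"drop"` removes them
#' (count in attribute `n_dropped`), `"error"` fails naming the first
#' unmapped symbol.
#'
#' @param genes character vector of mouse symbols.
#' @param table named character vector `mouse -> human` (may be `NULL`
#'   or empty).
#' @param fallback `"uppercase"`, `"drop"` or `"error"`.
#' @return Character vector of human symbols.
#' @export
map_orthologs <- function(genes, table = NULL,
                          fallback = c("uppercase", "drop", "error")) {
  fallback <- match.arg(fallback)
  genes <- as.character(genes)
  mapped <- if (length(table)) unname(table[genes]) else rep(NA_character_, length(genes))
  miss <- is.na(mapped)
  if (any(miss)) {
    if (fallback == "error") {
      stop_("no ortholog mapping for symbol: ", genes[miss][1])
    }
    if (fallback == "uppercase") {
      mapped[miss] <- toupper(genes[miss])
    } else {
      mapped <- mapped[!miss]
    }
  }
  out <- unique(mapped)
  attr(out, "n_dropped") <- if (fallback == "drop") sum(miss) else 0L
  out
}

#' Tabulate leading-edge membership frequencies by species
#'
#' From a panel-wide GSEA table (see [pairwise_matrix()]), counts for
#' every (gene, gene set) pair the number of contrasts per species in
#' whose leading edge the gene appears. Mouse leading edges are first
#' translated to human symbol space via [map_orthologs()] so both
#' species are counted in one namespace. By default only
#' direction-concordant enrichments contribute (positive ES for up
#' sets, negative for down sets); discordant runs say nothing about
#' the genes the set was built from.
#'
#' @param results data.frame from [pairwise_matrix()] (needs columns
#'   `species`, `contrast`, `set`, `direction`, `es`, `leading_edge`).
#' @param ortholog_table named mouse-to-human vector (optional).
#' @param require_direction drop rows whose ES sign contradicts the set
#'   direction.
#' @return Object of class `LeadingEdgeTable`: `entries` (one row per
#'   (gene, set, contrast, species) membership), `counts` (per
#'   (gene, set): `mouse_k`, `human_k`), `n_mouse`/`n_human`
#'   (contrast denominators) and `directions` (per set).
#' @export
leading_edge_frequencies <- function(results, ortholog_table = NULL,
                                     require_direction = TRUE) {
  needed <- c("species", "contrast", "set", "direction", "es", "leading_edge")
  missing_cols <- setdiff(needed, names(results))
  if (length(missing_cols)) {
    stop_("results lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(is.na(results$species)) || !all(results$species %in% c("mouse", "human"))) {
    stop_("every contrast must carry a species label (mouse/human)")
  }
  n_mouse <- length(unique(results$contrast[results$species == "mouse"]))
  n_human <- length(unique(results$contrast[results$species == "human"]))
  directions <- tapply(results$direction, results$set, function(d) d[1])

  keep <- rep(TRUE, nrow(results))
  if (require_direction) {
    keep <- (results$direction == "up" & results$es > 0) |
      (results$direction == "down" & results$es < 0) |
      (results$direction == "unsigned")
  }
  entries <- list()
  for (i in which(keep)) {
    genes <- results$leading_edge[[i]]
    if (!length(genes)) next
    if (results$species[i] == "mouse") {
      genes <- map_orthologs(genes, ortholog_table, fallback = "uppercase")
    }
    entries[[length(entries) + 1]] <- data.frame(
      gene = genes, set = results$set[i], contrast = results$contrast[i],
      species = results$species[i], stringsAsFactors = FALSE)
  }
  entries <- if (length(entries)) unique(do.call(rbind, entries)) else
    data.frame(gene = character(), set = character(), contrast = character(),
               species = character(), stringsAsFactors = FALSE)
  rownames(entries) <- NULL

  if (nrow(entries)) {
    agg <- stats::aggregate(contrast ~ gene + set + species, entries, length)
    counts <- merge(
      stats::setNames(agg[agg$species == "mouse", c("gene", "set", "contrast")],
                      c("gene", "set", "mouse_k")),
      stats::setNames(agg[agg$species == "human", c("gene", "set", "contrast")],
                      c("gene", "set", "human_k")),
      by = c("gene", "set"), all = TRUE)
    counts$mouse_k[is.na(counts$mouse_k)] <- 0L
    counts$human_k[is.na(counts$human_k)] <- 0L
  } else {
    counts <- data.frame(gene = character(), set = character(),
                         mouse_k = integer(), human_k = integer(),
                         stringsAsFactors = FALSE)
  }
  counts$direction <- unname(directions[counts$set])
  structure(list(entries = entries, counts = counts,
                 n_mouse = n_mouse, n_human = n_human,
                 directions = directions), class = "LeadingEdgeTable")
}

#' @export
print.LeadingEdgeTable <- function(x, ...) {
  cat("LeadingEdgeTable:", nrow(x$counts), "(gene, set) pairs over",
      x$n_mouse, "mouse +", x$n_human, "human contrasts\n")
  invisible(x)
}

#' Cross-species frequency-threshold core signature
#'
#' A gene enters the UP core if, for at least one up-direction gene
#' set, it appears in at least `mouse_min_frac` of the mouse leading
#' edges AND at least `human_min_frac` of the human leading edges;
#' DOWN is symmetric, and the per-direction lists are the union over
#' qualifying gene sets. Defaults 10/12 and 5/6 encode the ">80% of
#' conditions in both species" rule. A gene qualifying in both
#' directions is a directional conflict: an error by default, or
#' removed from both lists with `resolve = "drop"`.
#'
#' @param freq a `LeadingEdgeTable`.
#' @param mouse_min_frac,human_min_frac frequency thresholds in (0, 1].
#' @param directions which directions to build (default both).
#' @param resolve `"error"` or `"drop"` for directional conflicts.
#' @return Object of class `CoreSignature`: `up`, `down` (sorted gene
#'   vectors), `table` (per gene: best mouse/human frequencies and a
#'   `k/n` bin label), `thresholds`, `dropped`.
#' @export
core_signature <- function(freq, mouse_min_frac = 10 / 12,
                           human_min_frac = 5 / 6,
                           directions = c("up", "down"),
                           resolve = c("error", "drop")) {
  resolve <- match.arg(resolve)
  for (f in c(mouse_min_frac, human_min_frac)) {
    if (f <= 0 || f > 1) stop_("frequency thresholds must be in (0, 1]")
  }
  if (freq$n_mouse < 1 || freq$n_human < 1) {
    stop_("need tested contrasts in both species")
  }
  km <- ceiling(mouse_min_frac * freq$n_mouse - 1e-9)
  kh <- ceiling(human_min_frac * freq$n_human - 1e-9)
  ct <- freq$counts
  lists <- list(up = character(), down = character())
  tab <- list()
  for (dir in directions) {
    sub <- ct[!is.na(ct$direction) & ct$direction == dir &
                ct$mouse_k >= km & ct$human_k >= kh, , drop = FALSE]
    if (!nrow(sub)) next
    best <- do.call(rbind, lapply(split(sub, sub$gene), function(g) {
      data.frame(gene = g$gene[1], direction = dir,
                 mouse_k = max(g$mouse_k), human_k = max(g$human_k),
                 stringsAsFactors = FALSE)
    }))
    lists[[dir]] <- sort(unique(sub$gene))
    tab[[dir]] <- best
  }
  conflict <- intersect(lists$up, lists$down)
  if (length(conflict) && resolve == "error") {
    stop_("gene(s) qualify for both directions: ",
          paste(utils::head(conflict, 5), collapse = ", "),
          "; rerun with resolve = \"drop\"")
  }
  if (length(conflict)) {
    lists$up <- setdiff(lists$up, conflict)
    lists$down <- setdiff(lists$down, conflict)
  }
  table <- if (length(tab)) do.call(rbind, tab) else
    data.frame(gene = character(), direction = character(),
               mouse_k = integer(), human_k = integer(),
               stringsAsFactors = FALSE)
  table <- table[!(table$gene %in% conflict), , drop = FALSE]
  table$n_mouse <- rep(freq$n_mouse, nrow(table))
  table$n_human <- rep(freq$n_human, nrow(table))
  table$bin <- sprintf("%d/%d %d/%d", table$human_k, freq$n_human,
                       table$mouse_k, freq$n_mouse)
  table <- table[order(table$direction, -table$human_k, -table$mouse_k,
                       table$gene), , drop = FALSE]
  rownames(table) <- NULL
  structure(list(up = lists$up, down = lists$down, table = table,
                 thresholds = c(mouse_min_frac = mouse_min_frac,
                                human_min_frac = human_min_frac,
                                mouse_min_k = km, human_min_k = kh),
                 dropped = conflict), class = "CoreSignature")
}

#' @export
print.CoreSignature <- function(x, ...) {
  cat("CoreSignature:", length(x$up), "UP,", length(x$down), "DOWN genes",
      sprintf("(thresholds >=%d mouse, >=%d human leading edges)\n",
              x$thresholds[["mouse_min_k"]], x$thresholds[["human_min_k"]]))
  invisible(x)
}

#' Write a core signature as GMT plus a frequency-bin TSV
#'
#' @param sig a `CoreSignature`.
#' @param gmt_path GMT with `core_up` and `core_down` sets.
#' @param tsv_path per-gene table (gene, direction, human k/n, mouse
#'   k/n).
#' @param header_lines optional provenance comment lines.
#' @export
write_core_signature <- function(sig, gmt_path, tsv_path,
                                 header_lines = character()) {
  sets <- list()
  if (length(sig$up)) sets$core_up <- gene_set("core_up", sig$up, "up")
  if (length(sig$down)) sets$core_down <- gene_set("core_down", sig$down, "down")
  if (!length(sets)) stop_("empty core signature: nothing to write")
  write_gmt(sets, gmt_path, header_lines)
  write_tsv_artifact(sig$table, tsv_path, header_lines)
  invisible(c(gmt_path, tsv_path))
}
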