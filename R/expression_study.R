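#' Expression study container
#'
#' A lightweight container for one multi-sample expression study: a
#' real-valued log2 expression matrix (features x samples) plus a sample
#' annotation table. This is the universal input of the pipeline; the
#' design follows the matrix-plus-targets idiom of limma's `EList`.
#'
#' @param exprs numeric matrix, rows = feature ids (probes or gene
#'   symbols), columns = sample ids, values on the log2 scale.
#' @param samples data.frame with one row per sample and columns
#'   `sample_id`, `subset`, `state` (`"quiescent"`/`"activated"`),
#'   `species` (`"mouse"`/`"human"`), `contrast`, `replicate`.
#'
#' @return An object of class `ExpressionStudy` with elements `exprs`
#'   and `samples` (reordered to match the matrix columns).
#'
#' @details Invariants enforced: unique feature and sample ids, finite
#'   values, annotation/matrix sample agreement, and for every contrast
#'   id a single cell subset with both activation states present.
#' @export
expression_study <- function(exprs, samples) {
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  required <- c("sample_id", "subset", "state", "species", "contrast", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop_("sample annotation lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  samples$sample_id <- as.character(samples$sample_id)

  if (is.null(rownames(exprs))) stop_("expression matrix has no feature ids")
  dup <- rownames(exprs)[duplicated(rownames(exprs))]
  if (length(dup)) stop_("duplicate feature id: ", dup[1])
  dup <- colnames(exprs)[duplicated(colnames(exprs))]
  if (length(dup)) stop_("duplicate sample id: ", dup[1])
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup)) stop_("duplicate sample id in annotation: ", dup[1])

  only_mat <- setdiff(colnames(exprs), samples$sample_id)
  if (length(only_mat)) {
    stop_("sample in matrix but not in annotation: ", only_mat[1])
  }
  only_ann <- setdiff(samples$sample_id, colnames(exprs))
  if (length(only_ann)) {
    stop_("sample in annotation but not in matrix: ", only_ann[1])
  }
  samples <- samples[match(colnames(exprs), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL

  if (any(!is.finite(exprs))) {
    bad <- which(!is.finite(exprs), arr.ind = TRUE)[1, ]
    stop_("non-finite expression value at feature '", rownames(exprs)[bad[1]],
          "', sample '", colnames(exprs)[bad[2]], "'")
  }
  bad_state <- setdiff(unique(samples$state), c("quiescent", "activated"))
  if (length(bad_state)) stop_("unknown activation state: ", bad_state[1])
  bad_sp <- setdiff(unique(samples$species), c("mouse", "human"))
  if (length(bad_sp)) stop_("unknown species: ", bad_sp[1])

  for (cid in unique(samples$contrast)) {
    sub <- samples[samples$contrast == cid, , drop = FALSE]
    if (length(unique(sub$subset)) != 1L) {
      stop_("contrast '", cid, "' maps to more than one cell subset")
    }
    if (!setequal(unique(sub$state), c("quiescent", "activated"))) {
      stop_("contrast '", cid, "' lacks one of the two activation states")
    }
  }

  structure(list(exprs = exprs, samples = samples), class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat("ExpressionStudy:", nrow(x$exprs), "features x", ncol(x$exprs), "samples\n")
  cat("  species:", paste(unique(x$samples$species), collapse = ", "),
      "| contrasts:", length(unique(x$samples$contrast)),
      "| subsets:", paste(unique(x$samples$subset), collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression study from a matrix TSV and an annotation TSV
#'
#' @param matrix_path tab-separated file; first column = feature ids,
#'   remaining columns = samples, header row of sample ids.
#' @param annotation_path tab-separated sample table with one row per
#'   sample (columns as in [expression_study()]).
#' @return An `ExpressionStudy`, with the matrix column order preserved.
#' @export
read_expression_study <- function(matrix_path, annotation_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2) stop_("expression matrix needs a feature column and >= 1 sample")
  ids <- tab[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop_("duplicate feature id: ", dup[1])
  raw <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_("non-numeric expression value '", raw[bad[1, 1], bad[1, 2]],
          "' at feature '", ids[bad[1, 1]], "', sample '",
          colnames(raw)[bad[1, 2]], "'")
  }
  dimnames(num) <- list(ids, colnames(raw))
  ann <- utils::read.delim(annotation_path, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  expression_study(num, ann)
}

#' Write an expression study as a matrix TSV plus an annotation TSV
#'
#' Inverse of [read_expression_study()]; round-trips exactly on valid
#' studies (up to numeric text representation).
#' @param study an `ExpressionStudy`.
#' @param matrix_path,annotation_path output paths.
#' @param header_lines optional provenance comment lines.
#' @export
write_expression_study <- function(study, matrix_path, annotation_path,
                                   header_lines = character()) {
  df <- data.frame(feature_id = rownames(study$exprs), study$exprs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_artifact(df, matrix_path, header_lines)
  write_tsv_artifact(study$samples, annotation_path, header_lines)
  invisible(c(matrix_path, annotation_path))
}

#' Collapse probe-level features to gene symbols
#'
#' Expression platforms often carry several probes per gene; downstream
#' cross-platform and cross-species comparison requires one row per
#' symbol. The max-mean rule keeps, for each gene, the probe with the
#' highest mean expression across samples.
#'
#' @param study an `ExpressionStudy` with probe-level feature ids.
#' @param probe_map data.frame with columns `probe` and `gene`.
#' @param method collapse rule; only `"max_mean"` is implemented.
#' @return An `ExpressionStudy` keyed by gene symbol. Probes absent from
#'   `probe_map` are dropped; the count is in attribute `n_unmapped`.
#' @export
collapse_probes <- function(study, probe_map, method = "max_mean") {
  method <- match.arg(method, "max_mean")
  if (!all(c("probe", "gene") %in% names(probe_map))) {
    stop_("probe_map needs columns 'probe' and 'gene'")
  }
  keep <- rownames(study$exprs) %in% probe_map$probe
  n_unmapped <- sum(!keep)
  ex <- study$exprs[keep, , drop = FALSE]
  if (!nrow(ex)) stop_("no probe of the study is present in probe_map")
  gene <- probe_map$gene[match(rownames(ex), probe_map$probe)]
  mu <- rowMeans(ex)
  ord <- order(gene, -mu)
  pick <- ord[!duplicated(gene[ord])]
  ex <- ex[pick, , drop = FALSE]
  rownames(ex) <- gene[pick]
  out <- expression_study(ex, study$samples)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

# sample ids of one state within one contrast
contrast_samples <- function(study, contrast, state) {
  s <- study$samples
  ids <- s$sample_id[s$contrast == contrast & s$state == state]
  if (!length(ids)) {
    stop_("no '", state, "' samples for contrast '", contrast, "'")
  }
  ids
}
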