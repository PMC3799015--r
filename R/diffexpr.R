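#' Fit the additive-plus-proportional error model
#'
#' Microarray duplicates are too few for per-gene variance estimates,
#' so the model pools information across genes: the per-gene replicate
#' variance is regressed (least squares, non-negative parameters) on
#' `sigma_add^2 + sigma_prop^2 * mean^2`. This is the variance family
#' underlying duplicate-robust tests of the VAMPIRE type.
#'
#' @param study an `ExpressionStudy`.
#' @param state restrict to replicate groups of one activation state
#'   (`"quiescent"`/`"activated"`), or `NULL` to pool both.
#' @return Object of class `ErrorModel`: `sigma_add`, `sigma_prop`,
#'   `n_genes` (replicate groups used) and `loss` (mean squared
#'   residual of the variance fit).
#' @export
fit_error_model <- function(study, state = NULL) {
  s <- study$samples
  if (!is.null(state)) s <- s[s$state == state, , drop = FALSE]
  groups <- split(s$sample_id, paste(s$contrast, s$state))
  groups <- groups[lengths(groups) >= 2]
  if (!length(groups)) stop_("no replicate group with >= 2 replicates")
  m <- unlist(lapply(groups, function(ids) rowMeans(study$exprs[, ids, drop = FALSE])))
  s2 <- unlist(lapply(groups, function(ids) row_variances(study$exprs[, ids, drop = FALSE])))
  if (nrow(study$exprs) < 50) {
    stop_("error-model fit needs >= 50 genes, got ", nrow(study$exprs))
  }
  m2 <- m^2
  fit <- stats::lm(s2 ~ m2)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  if (is.na(b) || b < 0) {
    b <- 0
    a <- mean(s2)
  } else if (a < 0) {
    a <- 0
    b <- max(sum(s2 * m2) / sum(m2^2), 0)
  }
  loss <- mean((s2 - a - b * m2)^2)
  structure(list(sigma_add = sqrt(a), sigma_prop = sqrt(b),
                 n_genes = nrow(study$exprs), n_groups = length(groups),
                 loss = loss, state = state %||% "pooled"),
            class = "ErrorModel")
}

#' @export
print.ErrorModel <- function(x, ...) {
  cat(sprintf("ErrorModel (%s): sigma_add = %.4f, sigma_prop = %.4f (%d genes, %d groups)\n",
              x$state, x$sigma_add, x$sigma_prop, x$n_genes, x$n_groups))
  invisible(x)
}

#' Duplicate-robust differential expression for one contrast
#'
#' Per gene, the z statistic is the log2 fold change divided by the
#' modelled standard deviation of the difference of replicate means,
#' with variances taken from the pooled error model rather than the
#' per-gene duplicates. Two-sided normal p values are adjusted by
#' Benjamini-Hochberg; calls are gated on both the FDR and a fold
#' change threshold applied to the difference of log2 means.
#'
#' @param study an `ExpressionStudy`.
#' @param contrast contrast id present in the study.
#' @param model an `ErrorModel`; fitted on the whole study when `NULL`.
#' @param fdr_max FDR threshold for calls (default 0.05).
#' @param fc_min fold-change threshold on the linear scale (default 2,
#'   i.e. |log2fc| >= 1).
#' @return A data.frame of class `DeResult` with columns `gene`,
#'   `mean_q`, `mean_a`, `log2fc`, `statistic`, `p`, `q`, `call`
#'   (`up`/`down`/`ns`); thresholds and model in attributes.
#' @export
differential_test <- function(study, contrast, model = NULL,
                              fdr_max = 0.05, fc_min = 2) {
  ids_q <- contrast_samples(study, contrast, "quiescent")
  ids_a <- contrast_samples(study, contrast, "activated")
  if (length(ids_q) < 2 || length(ids_a) < 2) {
    stop_("contrast '", contrast, "' needs >= 2 replicates per state")
  }
  if (is.null(model)) model <- fit_error_model(study)
  mq <- rowMeans(study$exprs[, ids_q, drop = FALSE])
  ma <- rowMeans(study$exprs[, ids_a, drop = FALSE])
  vq <- model$sigma_add^2 + model$sigma_prop^2 * mq^2
  va <- model$sigma_add^2 + model$sigma_prop^2 * ma^2
  var_diff <- vq / length(ids_q) + va / length(ids_a)
  log2fc <- ma - mq
  z <- ifelse(var_diff > 0, log2fc / sqrt(var_diff), 0)
  p <- 2 * stats::pnorm(-abs(z))
  q <- bh_fdr(p)
  lfc_min <- log2(fc_min)
  call <- ifelse(q <= fdr_max & log2fc >= lfc_min, "up",
                 ifelse(q <= fdr_max & log2fc <= -lfc_min, "down", "ns"))
  out <- data.frame(gene = rownames(study$exprs), mean_q = mq, mean_a = ma,
                    log2fc = log2fc, statistic = z, p = p, q = q,
                    call = call, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contrast") <- contrast
  attr(out, "model") <- model
  attr(out, "fdr_max") <- fdr_max
  attr(out, "fc_min") <- fc_min
  class(out) <- c("DeResult", class(out))
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH with monotonicity enforcement, via [stats::p.adjust()].
#' @param pvalues numeric vector in \[0, 1\]; NA/NaN are rejected.
#' @return q values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues))) stop_("NA/NaN p value passed to bh_fdr")
  if (any(pvalues < 0 | pvalues > 1)) stop_("p values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Three-set Venn partition of up- and down-regulated gene lists
#'
#' Partitions the up- and down-regulated lists of three cell subsets
#' into the 7 standard disjoint regions per direction (three privates,
#' three pairwise, one triple intersection). Disjointness and coverage
#' are asserted on every call.
#'
#' @param up_lists,down_lists named lists of exactly three character
#'   vectors each (one per subset); entries within a list must be
#'   unique.
#' @return Object of class `VennPartition`: `up` and `down` are named
#'   lists of 7 regions; `counts` tabulates region sizes.
#' @export
venn_partition <- function(up_lists, down_lists) {
  part_one <- function(lists, dir) {
    if (length(lists) != 3 || is.null(names(lists))) {
      stop_("need exactly three named lists per direction")
    }
    for (nm in names(lists)) {
      dup <- lists[[nm]][duplicated(lists[[nm]])]
      if (length(dup)) {
        stop_("duplicate entry '", dup[1], "' in ", dir, " list '", nm, "'")
      }
    }
    labs <- names(lists)
    all_genes <- unique(unlist(lists, use.names = FALSE))
    member <- vapply(lists, function(l) all_genes %in% l, logical(length(all_genes)))
    if (length(all_genes) == 1) member <- matrix(member, nrow = 1)
    region_names <- c(paste0(labs, "_only"),
                      paste(labs[1], labs[2], sep = "_"),
                      paste(labs[1], labs[3], sep = "_"),
                      paste(labs[2], labs[3], sep = "_"),
                      paste(labs, collapse = "_"))
    masks <- list(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
                  c(FALSE, FALSE, TRUE), c(TRUE, TRUE, FALSE),
                  c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE),
                  c(TRUE, TRUE, TRUE))
    regions <- lapply(masks, function(msk) {
      all_genes[apply(member, 1, function(r) all(r == msk))]
    })
    names(regions) <- region_names
    # partition sanity: disjoint and covering
    if (length(unlist(regions)) != length(all_genes) ||
        !setequal(unlist(regions), all_genes)) {
      stop_("internal error: Venn regions do not partition the input union")
    }
    regions
  }
  up <- part_one(up_lists, "up")
  down <- part_one(down_lists, "down")
  counts <- data.frame(region = c(names(up), names(down)),
                       direction = rep(c("up", "down"), each = 7),
                       n = c(lengths(up), lengths(down)),
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(up = up, down = down, counts = counts),
            class = "VennPartition")
}

#' @export
print.VennPartition <- function(x, ...) {
  cat("VennPartition: 7 up + 7 down regions\n")
  print(x$counts)
  invisible(x)
}

#' Convert Venn regions into directional gene sets
#'
#' The Venn regions are the natural GSEA gene sets for cross-condition
#' validation; each inherits its direction from the side of the
#' partition it came from.
#' @param vp a `VennPartition`.
#' @param min_size drop regions with fewer genes than this.
#' @return Named list of `GeneSet` objects (`<region>.up` /
#'   `<region>.down`).
#' @export
venn_gene_sets <- function(vp, min_size = 1) {
  sets <- list()
  for (dir in c("up", "down")) {
    for (rn in names(vp[[dir]])) {
      genes <- vp[[dir]][[rn]]
      if (length(genes) >= min_size) {
        nm <- paste0(rn, ".", dir)
        sets[[nm]] <- gene_set(nm, genes, dir)
      }
    }
  }
  sets
}

#' Per-gene, per-contrast log2 fold-change table
#'
#' The tabular form of a fold-change heatmap over a gene panel: one row
#' per gene, one column per contrast, entries = activated minus
#' quiescent mean log2 expression. An optional display copy clips
#' values to `[-clip, clip]`, matching the saturation used when such
#' tables are rendered.
#'
#' @param study an `ExpressionStudy`.
#' @param gene_panel genes to report (all must be present).
#' @param contrasts contrast ids (all must be present).
#' @param clip clipping bound for the display copy; `NULL` to skip.
#' @return list with `fc` (gene x contrast matrix) and `display`
#'   (clipped copy, or `NULL`).
#' @export
log2fc_table <- function(study, gene_panel, contrasts, clip = 1) {
  missing_g <- setdiff(gene_panel, rownames(study$exprs))
  if (length(missing_g)) stop_("gene absent from matrix: ", missing_g[1])
  missing_c <- setdiff(contrasts, unique(study$samples$contrast))
  if (length(missing_c)) stop_("contrast absent from study: ", missing_c[1])
  fc <- sapply(contrasts, function(cid) {
    ids_q <- contrast_samples(study, cid, "quiescent")
    ids_a <- contrast_samples(study, cid, "activated")
    rowMeans(study$exprs[gene_panel, ids_a, drop = FALSE]) -
      rowMeans(study$exprs[gene_panel, ids_q, drop = FALSE])
  })
  fc <- matrix(fc, nrow = length(gene_panel),
               dimnames = list(gene_panel, contrasts))
  display <- if (!is.null(clip)) pmin(pmax(fc, -clip), clip) else NULL
  list(fc = fc, display = display)
}
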