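#' @importFrom stats pnorm phyper cor dist hclust prcomp cutree p.adjust
#'   rnorm sd var aggregate coef lm setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ <- function(...) stop(..., call. = FALSE)

# TSV artifacts carry provenance as leading '#' comment lines
write_tsv_artifact <- function(df, path, header_lines = character()) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_artifact <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

# modifyList that recurses into nested lists, used for config overrides
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

row_variances <- function(x) {
  n <- ncol(x)
  if (n < 2) stop_("need >= 2 columns to compute row variances")
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}
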