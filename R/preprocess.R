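#' Preprocessing configuration
#'
#' @param min_mean_fpkm genes are kept when their mean FPKM across samples
#'   is strictly greater than this (default 0.01).
#' @param pseudocount added to every FPKM value before the log transform
#'   (default 0.01); must be positive.
#' @param log_base base of the log transform (default 2).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(min_mean_fpkm = 0.01, pseudocount = 0.01,
                              log_base = 2) {
  if (min_mean_fpkm < 0) stop("`min_mean_fpkm` must be >= 0", call. = FALSE)
  if (pseudocount <= 0) stop("`pseudocount` must be > 0", call. = FALSE)
  if (log_base <= 1) stop("`log_base` must be > 1", call. = FALSE)
  structure(list(min_mean_fpkm = min_mean_fpkm, pseudocount = pseudocount,
                 log_base = log_base),
            class = "preprocess_config")
}

#' Filter genes by mean expression
#'
#' Retains exactly the genes whose arithmetic mean FPKM across all samples
#' is strictly greater than `config$min_mean_fpkm`. The filter is applied
#' on the raw FPKM scale, before any log transform. Sample set and gene
#' order are preserved.
#'
#' @param expr numeric matrix, genes x samples, nonnegative FPKM.
#' @param config a [preprocess_config()].
#' @return the filtered matrix (possibly 0 rows, with a warning).
#' @export
filter_low_expression <- function(expr, config = preprocess_config()) {
  if (!is.matrix(expr) || nrow(expr) == 0 || ncol(expr) == 0) {
    stop("`expr` must be a nonempty genes x samples matrix", call. = FALSE)
  }
  keep <- rowMeans(expr) > config$min_mean_fpkm
  if (!any(keep)) {
    warning("all genes removed by the mean-FPKM filter; returning an empty matrix",
            call. = FALSE)
  }
  expr[keep, , drop = FALSE]
}

#' Log-transform an expression matrix
#'
#' Maps every value `v` to `log(v + pseudocount, base)`; by default
#' `log2(v + 0.01)`, the standard transform for FPKM ahead of linear
#' modelling. Shape and dimnames are preserved.
#'
#' @inheritParams filter_low_expression
#' @return transformed matrix of the same shape.
#' @export
log_transform <- function(expr, config = preprocess_config()) {
  if (any(expr < 0, na.rm = TRUE)) {
    stop("expression values must be nonnegative", call. = FALSE)
  }
  log(expr + config$pseudocount, base = config$log_base)
}
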