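#' Configuration for the selection-frequency procedure
#'
#' Defaults mirror the published analysis: 10% random gene subsets, 10,000
#' trials, eight explanatory variables per trial, and a reporting threshold
#' of 0.01 on the selection frequency.
#'
#' @param subset_fraction fraction of the gene universe drawn per trial,
#'   in (0, 1].
#' @param n_trials number of random-subset trials (>= 1).
#' @param model_size target number of explanatory variables per trial (K).
#' @param frequency_threshold report genes with frequency strictly above
#'   this, in \[0, 1\].
#' @param penalty_rule `"fixed_size"` (pin the active set to `model_size`
#'   via the path) or `"cv"` (5-fold cross-validated penalty; the per-trial
#'   model size then varies).
#' @param seed master seed; each trial gets its own substream.
#' @return a `selection_config` list.
#' @export
selection_config <- function(subset_fraction = 0.10, n_trials = 10000,
                             model_size = 8, frequency_threshold = 0.01,
                             penalty_rule = c("fixed_size", "cv"), seed = 1) {
  penalty_rule <- match.arg(penalty_rule)
  if (subset_fraction <= 0 || subset_fraction > 1) {
    stop("`subset_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  if (model_size < 0) stop("`model_size` must be >= 0", call. = FALSE)
  if (frequency_threshold < 0 || frequency_threshold > 1) {
    stop("`frequency_threshold` must be in [0, 1]", call. = FALSE)
  }
  structure(list(subset_fraction = subset_fraction, n_trials = n_trials,
                 model_size = model_size,
                 frequency_threshold = frequency_threshold,
                 penalty_rule = penalty_rule, seed = seed),
            class = "selection_config")
}

#' Draw a random gene subset
#'
#' Samples `floor(fraction * G)` gene ids uniformly without replacement
#' using the current RNG state (callers seed a per-trial substream).
#'
#' @param gene_ids character vector of the gene universe.
#' @param fraction subset fraction in (0, 1].
#' @return character vector of sampled gene ids.
#' @examples
#' set.seed(1)
#' length(draw_subset(sprintf("g%05d", 1:37043), 0.10)) # 3704
#' @export
draw_subset <- function(gene_ids, fraction) {
  if (!length(gene_ids)) stop("empty gene universe", call. = FALSE)
  size <- floor(fraction * length(gene_ids))
  if (size < 1) {
    stop("subset size floor(fraction * G) is 0; increase `fraction`", call. = FALSE)
  }
  sample(gene_ids, size)
}

## One selection trial: subset -> standardize -> LASSO path -> top-K set.
.selection_trial <- function(expr_log, trait_c, subset, K, rule) {
  X <- t(expr_log[subset, , drop = FALSE])
  n <- nrow(X)
  m <- colMeans(X)
  v <- colMeans(X^2) - m^2
  sds <- sqrt(pmax(v, 0) * n / (n - 1))
  keep <- sds > 0
  n_const <- sum(!keep)
  X <- X[, keep, drop = FALSE]
  if (!ncol(X)) return(list(selected = character(0), n_const = n_const))
  X <- sweep(sweep(X, 2, m[keep]), 2, sds[keep], "/")
  if (rule == "cv") {
    cv <- .cv_lambda_index(X, trait_c)
    b <- cv$path$beta[, cv$k]
    sel <- names(b)[b != 0]
  } else {
    path <- fit_lasso_path(X, trait_c, stop_at_size = K)
    sel <- select_explanatory(path, K)
  }
  list(selected = sel, n_const = n_const)
}

#' Run the random-subset LASSO selection-frequency procedure
#'
#' For each of `n_trials` trials: draw a random subset of the (filtered,
#' log-transformed) gene universe, standardise the subset's expression
#' within the trial, fit a LASSO path of shoot weight on the subset, and
#' designate the trial's explanatory variables (by default the active set
#' pinned to `model_size` genes). A gene's selection frequency is the
#' number of trials in which it was designated explanatory divided by the
#' total number of trials. Each trial runs under its own RNG substream
#' keyed by trial index, so results are independent of execution order.
#'
#' Zero-variance genes within a trial's subset are dropped from that trial
#' (they still count as appearances); the total dropped is reported as the
#' `n_constant_dropped` attribute.
#'
#' @param expr_log numeric matrix, genes x samples, log-transformed
#'   expression (see [log_transform()]).
#' @param trait `trait_vector` or named numeric vector aligned with the
#'   expression samples.
#' @param config a [selection_config()].
#' @return a `selection_frequency_table` data frame with columns
#'   `gene_id`, `appearance_count`, `selected_count`, `frequency`, and
#'   `conditional_frequency` (= selected/appearance, a secondary
#'   diagnostic). Attributes: `n_trials`, `config`, `n_constant_dropped`.
#' @export
run_selection_frequency <- function(expr_log, trait,
                                    config = selection_config()) {
  y <- trait_means(trait)
  if (is.null(colnames(expr_log)) || is.null(names(y))) {
    stop("expression samples and trait must both be named", call. = FALSE)
  }
  if (!all(colnames(expr_log) %in% names(y))) {
    stop("trait values missing for some expression samples", call. = FALSE)
  }
  y <- y[colnames(expr_log)]
  n <- length(y)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (sd(y) == 0) stop("trait is constant", call. = FALSE)

  K <- config$model_size
  if (K > n - 1) {
    warning("model_size capped at n - 1 = ", n - 1, call. = FALSE)
    K <- n - 1
  }
  genes <- rownames(expr_log)
  appearance <- setNames(integer(length(genes)), genes)
  selected <- setNames(integer(length(genes)), genes)
  yc <- y - mean(y)
  n_const <- 0L

  for (t in seq_len(config$n_trials)) {
    res <- withr::with_seed(rng_substream(config$seed, "trial", t), {
      subset <- draw_subset(genes, config$subset_fraction)
      c(.selection_trial(expr_log, yc, subset, K, config$penalty_rule),
        list(subset = subset))
    })
    # appearance counts every subset member; selection only the explanatory
    appearance[res$subset] <- appearance[res$subset] + 1L
    selected[res$selected] <- selected[res$selected] + 1L
    n_const <- n_const + res$n_const
  }

  tab <- data.frame(
    gene_id = genes,
    appearance_count = as.integer(appearance),
    selected_count = as.integer(selected),
    frequency = as.numeric(selected) / config$n_trials,
    conditional_frequency = ifelse(appearance > 0, selected / pmax(appearance, 1), 0),
    stringsAsFactors = FALSE
  )
  attr(tab, "n_trials") <- config$n_trials
  attr(tab, "config") <- config
  attr(tab, "n_constant_dropped") <- n_const
  class(tab) <- c("selection_frequency_table", "data.frame")
  tab
}

#' Report genes above the selection-frequency threshold
#'
#' Lists genes with frequency strictly greater than
#' `config$frequency_threshold`, annotated with the Pearson correlation
#' (and two-sided p-value) of their log expression with the trait, sorted
#' by descending frequency with ties broken by gene id.
#'
#' @param table a `selection_frequency_table`.
#' @param expr_log the log-expression matrix the table was computed on.
#' @param trait the trait used for the selection run.
#' @param config the [selection_config()] (for the threshold).
#' @return data frame with columns `gene_id`, `appearance_count`,
#'   `selected_count`, `frequency`, `pearson_r`, `pearson_p`.
#' @export
report_selected_genes <- function(table, expr_log, trait,
                                  config = selection_config()) {
  y <- trait_means(trait)[colnames(expr_log)]
  hits <- table[table$frequency > config$frequency_threshold, , drop = FALSE]
  if (!nrow(hits)) {
    return(data.frame(gene_id = character(0), appearance_count = integer(0),
                      selected_count = integer(0), frequency = numeric(0),
                      pearson_r = numeric(0), pearson_p = numeric(0)))
  }
  stats <- lapply(hits$gene_id, function(g) {
    x <- expr_log[g, ]
    if (sd(x) == 0 || sd(y) == 0) return(c(NA_real_, NA_real_))
    ct <- pearson_correlation(x, y)
    c(ct$r, ct$p)
  })
  stats <- do.call(rbind, stats)
  out <- data.frame(gene_id = hits$gene_id,
                    appearance_count = hits$appearance_count,
                    selected_count = hits$selected_count,
                    frequency = hits$frequency,
                    pearson_r = stats[, 1], pearson_p = stats[, 2],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
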