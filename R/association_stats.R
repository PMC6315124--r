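#' Pearson correlation with significance
#'
#' Sample product-moment correlation with the two-sided t test
#' (`t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom).
#'
#' @param x,y numeric vectors of equal length `n >= 3`, both non-constant.
#' @return a `correlation_result`: list with `r`, `t`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length", call. = FALSE)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), t = unname(ct$statistic),
                 p = ct$p.value, n = n),
            class = "correlation_result")
}

#' One-way analysis of variance
#'
#' Classic between/within decomposition: `F = MS_between / MS_within` with
#' `k - 1` and `N - k` degrees of freedom.
#'
#' @param values numeric response vector.
#' @param group_labels group membership (coerced to factor); at least two
#'   groups, and at least one group with two or more observations.
#' @return an `anova_result`: list with `groups`, `F`, `p`, `df_between`,
#'   `df_within`.
#' @export
anova_one_way <- function(values, group_labels) {
  if (length(values) != length(group_labels)) {
    stop("`values` and `group_labels` must have equal length", call. = FALSE)
  }
  g <- factor(group_labels)
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  if (length(values) - nlevels(g) < 1) {
    stop("no within-group degrees of freedom", call. = FALSE)
  }
  a <- anova(lm(values ~ g))
  structure(list(groups = levels(g), F = a[["F value"]][1],
                 p = a[["Pr(>F)"]][1],
                 df_between = a[["Df"]][1], df_within = a[["Df"]][2]),
            class = "anova_result")
}

#' Copies per microlitre from concentration and fragment length
#'
#' Absolute copy number of a double-stranded DNA standard:
#' `copies/ul = concentration(g/ul) * N_A / (length_bp * 650 g/mol/bp)`,
#' with Avogadro's number `N_A = 6.02214076e23` and the conventional
#' 650 g/mol per double-stranded base pair.
#'
#' @param concentration_ng_per_ul concentration in ng/ul (>= 0).
#' @param fragment_length_bp fragment length in base pairs (> 0).
#' @param mw_per_bp molecular weight per base pair (g/mol), default 650.
#' @return copies per microlitre.
#' @examples
#' copies_from_mass(1, 1000) # about 9.265e8
#' @export
copies_from_mass <- function(concentration_ng_per_ul, fragment_length_bp,
                             mw_per_bp = 650) {
  if (any(fragment_length_bp <= 0)) stop("fragment length must be > 0", call. = FALSE)
  if (any(concentration_ng_per_ul < 0)) stop("concentration must be >= 0", call. = FALSE)
  concentration_ng_per_ul * 1e-9 * 6.02214076e23 /
    (fragment_length_bp * mw_per_bp)
}

#' Fit a qPCR standard curve
#'
#' Least-squares line of quantification cycle on log10 copy number,
#' `Cq = intercept + slope * log10(copies)`. Amplification efficiency is
#' `10^(-1/slope) - 1` (1.0 for a perfect doubling, slope
#' `-1/log10(2) ~ -3.3219`).
#'
#' @param copies template copy numbers (> 0, >= 3 distinct levels), or a
#'   data frame with columns `copies` and `cq`.
#' @param cq measured quantification cycles (ignored when `copies` is a
#'   data frame).
#' @return a `standard_curve`: list with `slope`, `intercept`,
#'   `efficiency`, `r_squared`.
#' @export
fit_standard_curve <- function(copies, cq = NULL) {
  if (is.data.frame(copies)) {
    cq <- copies$cq
    copies <- copies$copies
  }
  if (any(copies <= 0)) stop("copies must be > 0", call. = FALSE)
  if (length(unique(copies)) < 3) {
    stop("need at least 3 distinct copy levels", call. = FALSE)
  }
  fit <- lm(cq ~ log10(copies))
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    warning("standard curve slope is not negative; efficiency is not meaningful",
            call. = FALSE)
  }
  tss <- sum((cq - mean(cq))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 efficiency = 10^(-1 / slope) - 1,
                 r_squared = r2),
            class = "standard_curve")
}

#' Invert a standard curve
#'
#' @param curve a `standard_curve`.
#' @param cq quantification cycle(s).
#' @return template copies, `10^((cq - intercept) / slope)`.
#' @export
predict_copies <- function(curve, cq) {
  10^((cq - curve$intercept) / curve$slope)
}

#' Absolute quantification of qPCR samples
#'
#' Technical replicates are averaged on the Cq scale, each biological
#' replicate's mean Cq is inverted through the standard curve to copy
#' numbers, copies are log2-transformed, and the per-line expression trait
#' is the mean of the available biological replicates' log2 values — ready
#' to be mapped with [eqtl_scan()]. Missing Cq values drop the technical
#' replicate (warning); a line with no quantifiable replicate is dropped
#' (warning).
#'
#' @param curve a `standard_curve`.
#' @param cq_table data frame with columns `line_id`, `bio_rep`,
#'   `tech_rep`, `cq`.
#' @return a `qpcr_quantification`: list with `replicates` (per biological
#'   replicate: `line_id`, `bio_rep`, `cq_mean`, `copies`, `log2_copies`)
#'   and `line_means` (named numeric, the eQTL-ready trait).
#' @export
quantify_samples <- function(curve, cq_table) {
  need <- c("line_id", "bio_rep", "tech_rep", "cq")
  if (!all(need %in% names(cq_table))) {
    stop("cq_table needs columns line_id, bio_rep, tech_rep, cq", call. = FALSE)
  }
  n_missing <- sum(is.na(cq_table$cq))
  if (n_missing) {
    warning(n_missing, " missing Cq value(s); replicates skipped", call. = FALSE)
  }
  ok <- !is.na(cq_table$cq)
  reps <- stats::aggregate(cq ~ line_id + bio_rep, data = cq_table[ok, , drop = FALSE],
                           FUN = mean)
  names(reps)[names(reps) == "cq"] <- "cq_mean"
  reps <- reps[order(reps$line_id, reps$bio_rep), , drop = FALSE]
  reps$copies <- predict_copies(curve, reps$cq_mean)
  reps$log2_copies <- log2(reps$copies)
  rownames(reps) <- NULL

  all_lines <- unique(cq_table$line_id)
  dropped <- setdiff(all_lines, reps$line_id)
  if (length(dropped)) {
    warning("line(s) with no quantifiable replicate dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  means <- tapply(reps$log2_copies, reps$line_id, mean)
  keep <- intersect(all_lines, names(means))
  structure(list(replicates = reps,
                 line_means = setNames(as.numeric(means[keep]), keep)),
            class = "qpcr_quantification")
}
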