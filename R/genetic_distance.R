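#' Kosambi map function and its inverse
#'
#' Converts a recombination fraction `r` in `[0, 0.5)` to a genetic
#' distance `d = 25 * ln((1 + 2r) / (1 - 2r))` centimorgans, and back via
#' `r = 0.5 * tanh(d / 50)`. The two are exact inverses; `kosambi_cm` is
#' strictly increasing on its domain.
#'
#' @param r recombination fraction(s), `0 <= r < 0.5`.
#' @param d_cm genetic distance(s) in centimorgans, `d >= 0`.
#' @return numeric vector of distances (cM) or recombination fractions.
#' @examples
#' kosambi_cm(0.25)            # 25 * log(3)
#' kosambi_inverse(kosambi_cm(0.1)) # 0.1
#' @export
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) {
    stop("recombination fraction must be in [0, 0.5)", call. = FALSE)
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @export
kosambi_inverse <- function(d_cm) {
  if (any(d_cm < 0)) stop("map distance must be >= 0", call. = FALSE)
  0.5 * tanh(d_cm / 50)
}

#' Estimate the recombination fraction between two markers
#'
#' Counts, over the lines informative at both markers (both calls
#' homozygous and non-missing), the fraction whose homozygous calls differ.
#' Heterozygous or missing calls are excluded as non-informative. The
#' estimate is capped just below 0.5 so a Kosambi conversion stays finite.
#'
#' @param genotypes genotype code matrix (lines x markers).
#' @param marker_a,marker_b marker (column) names.
#' @return a `recombination_estimate`: list with `markers`, `recombinant`,
#'   `informative`, `r`.
#' @export
estimate_recombination_fraction <- function(genotypes, marker_a, marker_b) {
  for (m in c(marker_a, marker_b)) {
    if (!m %in% colnames(genotypes)) stop("unknown marker: ", m, call. = FALSE)
  }
  a <- genotypes[, marker_a]
  b <- genotypes[, marker_b]
  hom <- c("OU", "AR")
  inf <- !is.na(a) & !is.na(b) & a %in% hom & b %in% hom
  n_inf <- sum(inf)
  if (n_inf == 0) {
    stop("recombination fraction undefined: no informative lines for ",
         marker_a, " / ", marker_b, call. = FALSE)
  }
  rec <- sum(a[inf] != b[inf])
  structure(
    list(markers = c(marker_a, marker_b), recombinant = rec,
         informative = n_inf, r = min(rec / n_inf, 0.5 - 1e-9)),
    class = "recombination_estimate"
  )
}
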