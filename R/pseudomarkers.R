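#' Impute expected additive dosages on a pseudomarker grid
#'
#' Lays a grid of test positions over each chromosome (every `step_cm`
#' centimorgans, always including the marker positions themselves) and, for
#' every line, computes the expected additive dosage in `[-1, 1]` at each
#' position conditional on the flanking marker genotypes.
#'
#' Genotypes are modelled as a two-state (recipient/donor) chain along the
#' chromosome whose switch probability over a map distance `d` is the
#' Kosambi inverse `r(d)`; this is the Haley-Knott-style approximation
#' appropriate for mostly homozygous inbred lines. Between two informative
#' flanks with states `sL`, `sR` the conditional donor probability is
#' `P(sL -> Q) P(Q -> sR) / sum over Q`, with `P(s -> s') = 1 - r` when the
#' states agree and `r` otherwise; with a single informative flank the
#' dosage decays as `s * (1 - 2 r)`. Heterozygous and missing calls are
#' non-informative for conditioning (the chain has no heterozygous state);
#' a line with no informative marker on a chromosome gets dosage 0 there.
#' At a genotyped position the observed coding (-1 / 0 / +1) is used
#' directly.
#'
#' @param genotypes genotype code matrix (lines x markers).
#' @param map a `genetic_map`; chromosomes with a single marker fall back
#'   to that marker's observed dosage, with a warning.
#' @param step_cm grid step in centimorgans (> 0).
#' @return a `pseudomarker_grid`: list with `positions` (data frame
#'   `chromosome`, `position_cm`, `marker` — `NA` off-marker) and `dosage`
#'   (lines x positions numeric matrix).
#' @export
impute_pseudomarker_genotypes <- function(genotypes, map, step_cm = 1) {
  if (step_cm <= 0) stop("`step_cm` must be > 0", call. = FALSE)
  if (!all(map$marker %in% colnames(genotypes))) {
    stop("genotypes are missing markers present in the map", call. = FALSE)
  }
  n <- nrow(genotypes)
  dobs <- geno_dosage(genotypes) # NA for missing
  pos_list <- list()
  dos_list <- list()

  for (chr in unique(map$chromosome)) {
    sub <- map[map$chromosome == chr, , drop = FALSE]
    mp <- sub$position_cm
    k <- length(mp)
    if (k < 2) {
      warning("chromosome ", chr,
              " has a single marker; using its observed dosage", call. = FALSE)
      grid <- mp
    } else {
      grid <- sort(unique(c(seq(mp[1], mp[k], by = step_cm), mp)))
    }
    D <- matrix(0, n, length(grid))
    dchr <- dobs[, sub$marker, drop = FALSE]
    # informative = homozygous call: dosage exactly +/-1
    info <- !is.na(dchr) & abs(dchr) == 1

    for (i in seq_len(n)) {
      I <- which(info[i, ])
      if (length(I)) {
        s <- dchr[i, I]
        ip <- mp[I]
        li <- findInterval(grid, ip)
        ri <- li + 1L
        has_l <- li >= 1L
        has_r <- ri <= length(I)
        rl <- kosambi_inverse(pmax(grid - ip[pmax(li, 1L)], 0))
        rr <- kosambi_inverse(pmax(ip[pmin(ri, length(I))] - grid, 0))
        sl <- ifelse(has_l, s[pmax(li, 1L)], NA_real_)
        sr <- ifelse(has_r, s[pmin(ri, length(I))], NA_real_)
        di <- numeric(length(grid))
        both <- has_l & has_r
        if (any(both)) {
          # P(s -> +1) = 1 - r if s == +1 else r
          pl1 <- ifelse(sl[both] > 0, 1 - rl[both], rl[both])
          p1r <- ifelse(sr[both] > 0, 1 - rr[both], rr[both])
          plm <- 1 - pl1
          pmr <- 1 - p1r
          num1 <- pl1 * p1r
          num2 <- plm * pmr
          di[both] <- (num1 - num2) / (num1 + num2)
        }
        onlyl <- has_l & !has_r
        di[onlyl] <- sl[onlyl] * (1 - 2 * rl[onlyl])
        onlyr <- !has_l & has_r
        di[onlyr] <- sr[onlyr] * (1 - 2 * rr[onlyr])
        D[i, ] <- di
      }
      # observed coding (including HET = 0) wins at genotyped positions
      at <- match(mp, grid)
      obs_ok <- !is.na(dchr[i, ])
      D[i, at[obs_ok]] <- dchr[i, obs_ok]
    }
    pos_list[[as.character(chr)]] <- data.frame(
      chromosome = chr, position_cm = grid,
      marker = sub$marker[match(grid, mp)],
      stringsAsFactors = FALSE
    )
    dos_list[[as.character(chr)]] <- D
  }

  positions <- do.call(rbind, pos_list)
  rownames(positions) <- NULL
  dosage <- do.call(cbind, dos_list)
  rownames(dosage) <- rownames(genotypes)
  structure(list(positions = positions, dosage = dosage, step_cm = step_cm),
            class = "pseudomarker_grid")
}
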