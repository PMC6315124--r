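## Regression-based (Haley-Knott style) composite interval mapping.
##
## At each test position the trait is regressed on the imputed additive
## dosage plus background cofactor markers (those within `window_cm` of the
## position on the same chromosome are excluded from the local model), and
##
##   LOD = (n/2) * log10(RSS_reduced / RSS_full)
##
## where the reduced model omits the test dosage. For inbred-line
## populations this is near-identical to mixture-likelihood interval
## mapping and much faster.

.align_trait <- function(trait, lines) {
  y <- trait_means(trait)
  if (!is.null(names(y))) {
    if (!all(lines %in% names(y))) stop("trait values missing for some lines", call. = FALSE)
    y <- y[lines]
  } else if (length(y) != length(lines)) {
    stop("trait length does not match the number of lines", call. = FALSE)
  }
  as.numeric(y)
}

#' Select background cofactor markers by forward-backward regression
#'
#' Stepwise selection on observed marker dosages: repeatedly add the
#' marker with the smallest partial-F p-value if it is `<= entry_p`, then
#' drop any included marker whose partial-F p-value rises above `exit_p`,
#' until a fixed point or `max_cofactors` markers. Ties are broken by map
#' (column) order, so the procedure is deterministic.
#'
#' @param genotypes genotype code matrix (columns in map order).
#' @param trait `trait_vector` or numeric vector aligned with the lines.
#' @param entry_p,exit_p entry and exit p-value thresholds.
#' @param max_cofactors maximum number of cofactors.
#' @return character vector of selected marker names (possibly empty).
#' @export
select_cofactors <- function(genotypes, trait, entry_p = 0.05, exit_p = 0.10,
                             max_cofactors = 5) {
  y <- .align_trait(trait, rownames(genotypes))
  X <- geno_dosage(genotypes, impute_missing = TRUE)
  n <- length(y)
  p <- ncol(X)

  partial_p <- function(model, candidates) {
    # residualise y and candidates on [1, X_model]; F = (df) r^2 / (1 - r^2)
    Z <- cbind(1, X[, model, drop = FALSE])
    q <- qr(Z)
    yr <- qr.resid(q, y)
    df2 <- n - q$rank - 1L
    if (df2 < 1) return(rep(NA_real_, length(candidates)))
    Cr <- qr.resid(q, X[, candidates, drop = FALSE])
    num <- colSums(Cr * yr)
    den <- colSums(Cr^2) * sum(yr^2)
    r2 <- ifelse(den > 1e-300, pmin(num^2 / den, 1), NA_real_)
    f <- df2 * r2 / pmax(1 - r2, 1e-300)
    ifelse(is.na(r2), NA_real_, pf(f, 1, df2, lower.tail = FALSE))
  }

  model <- integer(0)
  for (pass in seq_len(2L * max_cofactors + 2L)) {
    changed <- FALSE
    # forward
    cand <- setdiff(seq_len(p), model)
    if (length(cand) && length(model) < max_cofactors) {
      pv <- partial_p(model, cand)
      if (any(!is.na(pv))) {
        best <- cand[which.min(pv)] # which.min: first minimum = map order
        if (min(pv, na.rm = TRUE) <= entry_p) {
          model <- c(model, best)
          changed <- TRUE
        }
      }
    }
    # backward
    repeat {
      if (length(model) < 1) break
      pv <- vapply(seq_along(model), function(i) {
        partial_p(model[-i], model[i])
      }, numeric(1))
      worst <- which.max(pv)
      if (!length(worst)) break
      if (!is.na(pv[worst]) && pv[worst] > exit_p) {
        model <- model[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  colnames(X)[sort(model)]
}

#' Composite interval mapping scan
#'
#' Computes the LOD profile of a trait over a pseudomarker grid. At each
#' position the full model is `trait ~ intercept + dosage + cofactors`
#' (cofactors within `window_cm` of the position on its chromosome are
#' excluded from the local model) and the reduced model omits the dosage.
#' `RSS_full` is floored at `1e-12 * TSS` so the LOD stays finite. The
#' additive effect is the fitted dosage coefficient (donor allele = +1
#' coding) and `r2_percent = 100 (RSS_reduced - RSS_full) / TSS`.
#'
#' @param genotypes genotype code matrix.
#' @param map a `genetic_map`.
#' @param trait `trait_vector` or named numeric vector.
#' @param cofactors character vector of cofactor marker names (empty for
#'   simple interval mapping).
#' @param window_cm cofactor exclusion window around the test position.
#' @param step_cm scan step; ignored when `grid` is supplied.
#' @param grid optional precomputed [impute_pseudomarker_genotypes()] grid.
#' @param trait_name label stored with the profile.
#' @return a `lod_profile` data frame: `chromosome`, `position_cm`,
#'   `marker`, `lod`, `additive_effect`, `r2_percent`.
#' @export
cim_scan <- function(genotypes, map, trait, cofactors = character(0),
                     window_cm = 10, step_cm = 1, grid = NULL,
                     trait_name = "trait") {
  y <- .align_trait(trait, rownames(genotypes))
  if (is.null(grid)) grid <- impute_pseudomarker_genotypes(genotypes, map, step_cm)
  D <- grid$dosage
  pos <- grid$positions
  n <- length(y)
  TSS <- sum((y - mean(y))^2)
  Xc <- if (length(cofactors)) {
    geno_dosage(genotypes[, cofactors, drop = FALSE], impute_missing = TRUE)
  } else NULL
  cof_chr <- map$chromosome[match(cofactors, map$marker)]
  cof_pos <- map$position_cm[match(cofactors, map$marker)]

  # positions sharing an included-cofactor set share one reduced model
  include <- matrix(TRUE, nrow(pos), length(cofactors))
  if (length(cofactors)) {
    for (j in seq_along(cofactors)) {
      include[, j] <- !(pos$chromosome == cof_chr[j] &
                          abs(pos$position_cm - cof_pos[j]) <= window_cm)
    }
  }
  key <- apply(include, 1, paste, collapse = "")
  lod <- eff <- r2 <- numeric(nrow(pos))
  rank_warned <- FALSE

  for (k in unique(key)) {
    idx <- which(key == k)
    inc <- include[idx[1], ]
    Z <- cbind(rep(1, n), if (any(inc)) Xc[, inc, drop = FALSE])
    q <- qr(Z)
    if (q$rank < ncol(Z) && !rank_warned) {
      warning("rank-deficient cofactor design; dependent columns dropped",
              call. = FALSE)
      rank_warned <- TRUE
    }
    yr <- qr.resid(q, y)
    RSS0 <- sum(yr^2)
    Dr <- qr.resid(q, D[, idx, drop = FALSE])
    num <- colSums(Dr * yr)
    den <- colSums(Dr^2)
    ok <- den > 1e-12 & RSS0 > 1e-12 * max(TSS, 1e-300)
    gain <- ifelse(ok, num^2 / den, 0)
    RSS1 <- pmax(RSS0 - gain, 1e-12 * TSS)
    lod[idx] <- ifelse(ok, pmax((n / 2) * log10(RSS0 / RSS1), 0), 0)
    eff[idx] <- ifelse(ok, num / den, 0)
    r2[idx] <- if (TSS > 0) 100 * (RSS0 - RSS1) / TSS else 0
  }

  out <- data.frame(chromosome = pos$chromosome, position_cm = pos$position_cm,
                    marker = pos$marker, lod = lod, additive_effect = eff,
                    r2_percent = r2, stringsAsFactors = FALSE)
  attr(out, "trait_name") <- trait_name
  attr(out, "cofactors") <- cofactors
  attr(out, "window_cm") <- window_cm
  attr(out, "n") <- n
  class(out) <- c("lod_profile", "data.frame")
  out
}

#' Permutation-derived genome-wide LOD threshold
#'
#' Permutes the trait across lines `n_permutations` times (genotypes
#' fixed), records the genome-wide maximum LOD of each permuted scan, and
#' returns the empirical `1 - alpha` quantile (type-7 interpolation). When
#' a `cofactor_rule` is given, cofactors are re-selected within every
#' permutation replicate so the threshold accounts for model selection;
#' with fixed (or no) cofactors the permuted scans are computed in a single
#' vectorised pass.
#'
#' @inheritParams cim_scan
#' @param n_permutations number of permutations (default 1000; fewer than
#'   20 triggers an instability warning).
#' @param alpha genome-wide significance level in (0, 1), default 0.05.
#' @param seed master seed; each permutation has its own substream.
#' @param cofactor_rule optional list `(entry_p, exit_p, max_cofactors)`;
#'   when given, [select_cofactors()] runs inside every permutation.
#' @return a `permutation_threshold`: list with `threshold`, `max_lods`,
#'   `n_permutations`, `alpha`.
#' @export
permutation_threshold <- function(genotypes, map, trait,
                                  n_permutations = 1000, alpha = 0.05,
                                  seed = 1, cofactors = character(0),
                                  cofactor_rule = NULL, window_cm = 10,
                                  step_cm = 1, grid = NULL) {
  if (n_permutations < 1) stop("`n_permutations` must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (n_permutations < 20) {
    warning("fewer than 20 permutations: the threshold quantile is unstable",
            call. = FALSE)
  }
  y <- .align_trait(trait, rownames(genotypes))
  if (is.null(grid)) grid <- impute_pseudomarker_genotypes(genotypes, map, step_cm)
  n <- length(y)

  perm_y <- vapply(seq_len(n_permutations), function(b) {
    withr::with_seed(rng_substream(seed, "perm", b), sample(y))
  }, numeric(n))

  if (is.null(cofactor_rule) && !length(cofactors)) {
    # no cofactors: LOD = -(n/2) log10(1 - r^2), vectorised over positions
    # and permutations in one cross-product
    D <- grid$dosage
    Dc <- sweep(D, 2, colMeans(D))
    sd_d <- sqrt(colSums(Dc^2))
    Yc <- sweep(perm_y, 2, colMeans(perm_y))
    sd_y <- sqrt(colSums(Yc^2))
    R <- crossprod(Dc, Yc) / outer(sd_d, sd_y)
    R[!is.finite(R)] <- 0
    max_lods <- apply(-(n / 2) * log10(pmax(1 - R^2, 1e-12)), 2, max)
  } else {
    max_lods <- vapply(seq_len(n_permutations), function(b) {
      yp <- perm_y[, b]
      cof <- if (!is.null(cofactor_rule)) {
        do.call(select_cofactors,
                c(list(genotypes = genotypes, trait = setNames(yp, rownames(genotypes))),
                  cofactor_rule))
      } else cofactors
      prof <- cim_scan(genotypes, map, setNames(yp, rownames(genotypes)),
                       cofactors = cof, window_cm = window_cm, grid = grid)
      max(prof$lod)
    }, numeric(1))
  }

  structure(
    list(threshold = quantile(max_lods, 1 - alpha, type = 7, names = FALSE),
         max_lods = max_lods, n_permutations = n_permutations, alpha = alpha),
    class = "permutation_threshold"
  )
}

#' Call QTL from a LOD profile
#'
#' One call per contiguous supra-threshold region per chromosome, reported
#' at the region's LOD peak (ties broken by the smaller position): nearest
#' map marker, additive effect and percent variance explained at the peak.
#'
#' @param profile a `lod_profile` from [cim_scan()].
#' @param map the `genetic_map`.
#' @param threshold numeric LOD threshold or a `permutation_threshold`.
#' @param trait_name label used in the `trait` column and QTL ids
#'   (default: the profile's stored trait name).
#' @return a `qtl_calls` data frame: `trait`, `qtl_id`, `chromosome`,
#'   `position_cm`, `nearest_marker`, `lod`, `additive_effect`,
#'   `r2_percent`. Zero rows when nothing exceeds the threshold.
#' @export
call_qtl <- function(profile, map, threshold, trait_name = NULL) {
  if (inherits(threshold, "permutation_threshold")) threshold <- threshold$threshold
  if (is.null(trait_name)) trait_name <- attr(profile, "trait_name") %||% "trait"
  calls <- list()
  for (chr in unique(profile$chromosome)) {
    sub <- profile[profile$chromosome == chr, , drop = FALSE]
    above <- sub$lod >= threshold
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (i in which(runs$values)) {
      seg <- sub[starts[i]:ends[i], , drop = FALSE]
      peak <- seg[which.max(seg$lod), , drop = FALSE] # first max: smaller cM
      on_chr <- map[map$chromosome == chr, , drop = FALSE]
      nearest <- on_chr$marker[which.min(abs(on_chr$position_cm - peak$position_cm))]
      calls[[length(calls) + 1L]] <- data.frame(
        trait = trait_name, chromosome = chr, position_cm = peak$position_cm,
        nearest_marker = nearest, lod = peak$lod,
        additive_effect = peak$additive_effect, r2_percent = peak$r2_percent,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(calls)) {
    out <- data.frame(trait = character(0), qtl_id = character(0),
                      chromosome = numeric(0), position_cm = numeric(0),
                      nearest_marker = character(0), lod = numeric(0),
                      additive_effect = numeric(0), r2_percent = numeric(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("qtl_calls", "data.frame")
    return(out)
  }
  out <- do.call(rbind, calls)
  id <- sprintf("q%s-%s", trait_name, out$chromosome)
  dup <- ave(seq_along(id), id, FUN = seq_along)
  out$qtl_id <- ifelse(dup > 1, paste0(id, ".", dup), id)
  out <- out[, c("trait", "qtl_id", "chromosome", "position_cm",
                 "nearest_marker", "lod", "additive_effect", "r2_percent")]
  rownames(out) <- NULL
  class(out) <- c("qtl_calls", "data.frame")
  out
}

#' Expression QTL scan
#'
#' Maps a per-line expression trait (e.g. the mean of three biological
#' replicates of log2 qPCR copy number) with exactly the machinery used
#' for phenotypic traits: cofactor selection (optional), permutation
#' threshold, CIM scan, QTL calls. A negative additive effect means the
#' donor (AR) allele decreases expression.
#'
#' @inheritParams permutation_threshold
#' @param expression_trait named numeric vector (or `trait_vector`) of
#'   per-line expression values.
#' @param gene label for the expression trait (used in reports).
#' @return list with `profile` (`lod_profile`), `threshold`
#'   (`permutation_threshold`) and `calls` (`qtl_calls`).
#' @export
eqtl_scan <- function(genotypes, map, expression_trait, gene = "expression",
                      n_permutations = 1000, alpha = 0.05, seed = 1,
                      cofactor_rule = NULL, window_cm = 10, step_cm = 1,
                      grid = NULL) {
  if (is.null(grid)) grid <- impute_pseudomarker_genotypes(genotypes, map, step_cm)
  cof <- if (!is.null(cofactor_rule)) {
    do.call(select_cofactors,
            c(list(genotypes = genotypes, trait = expression_trait), cofactor_rule))
  } else character(0)
  thr <- permutation_threshold(genotypes, map, expression_trait,
                               n_permutations = n_permutations, alpha = alpha,
                               seed = seed, cofactor_rule = cofactor_rule,
                               window_cm = window_cm, grid = grid)
  prof <- cim_scan(genotypes, map, expression_trait, cofactors = cof,
                   window_cm = window_cm, grid = grid, trait_name = gene)
  list(profile = prof, threshold = thr, calls = call_qtl(prof, map, thr, gene))
}

#' Null calibration of the permutation LOD threshold
#'
#' Simulates `n_datasets` BIL populations whose trait is independent of
#' genotype, computes each dataset's permutation threshold (simple interval
#' mapping), and reports the fraction of datasets whose genome-wide maximum
#' LOD exceeds their own threshold — the realised genome-wide type-I error,
#' which should match `alpha`.
#'
#' @param n_datasets number of null datasets.
#' @param n_permutations permutations per dataset.
#' @param alpha genome-wide significance level.
#' @param n_lines BIL population size.
#' @param step_cm scan step.
#' @param seed master seed.
#' @param ... passed to [simulate_genetic_map()].
#' @return list with `rate` (exceedance fraction), `exceeded` (logical),
#'   `max_lod`, `threshold` per dataset, and `n_datasets`.
#' @export
null_threshold_calibration <- function(n_datasets = 100, n_permutations = 100,
                                       alpha = 0.05, n_lines = 104,
                                       step_cm = 1, seed = 1, ...) {
  map <- simulate_genetic_map(seed = rng_substream(seed, "map"), ...)
  exceeded <- logical(n_datasets)
  max_lod <- thr <- numeric(n_datasets)
  for (i in seq_len(n_datasets)) {
    geno <- simulate_bil_genotypes(map, n_lines = n_lines,
                                   seed = rng_substream(seed, "null-geno", i))
    y <- withr::with_seed(rng_substream(seed, "null-trait", i),
                          setNames(rnorm(n_lines), rownames(geno)))
    grid <- impute_pseudomarker_genotypes(geno, map, step_cm)
    prof <- cim_scan(geno, map, y, grid = grid)
    pt <- permutation_threshold(geno, map, y, n_permutations = n_permutations,
                                alpha = alpha, grid = grid,
                                seed = rng_substream(seed, "null-perm", i))
    max_lod[i] <- max(prof$lod)
    thr[i] <- pt$threshold
    exceeded[i] <- max_lod[i] > thr[i]
  }
  list(rate = mean(exceeded), exceeded = exceeded, max_lod = max_lod,
       threshold = thr, n_datasets = n_datasets)
}
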