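#' Simulate a genetic map
#'
#' Builds an ordered marker map over `n_chromosomes` chromosomes. The first
#' and last marker of each chromosome sit at 0 cM and at the chromosome
#' length; interior markers are placed uniformly at random and sorted. The
#' defaults emulate a rice BIL map: 12 chromosomes carrying 124 simple
#' sequence repeat markers over roughly 1530 cM.
#'
#' @param n_chromosomes number of chromosomes (>= 1).
#' @param markers_per_chromosome integer vector (recycled) of marker counts,
#'   each >= 2. Default: 11 markers on the first four chromosomes and 10 on
#'   the remaining eight (124 in total for 12 chromosomes).
#' @param chromosome_lengths_cm numeric vector (recycled) of chromosome
#'   lengths in centimorgans, all > 0.
#' @param seed integer seed; the map is deterministic given the seed.
#' @return a `genetic_map`: a data frame with columns `marker`,
#'   `chromosome`, `position_cm`, ordered by chromosome then position.
#' @examples
#' map <- simulate_genetic_map(seed = 1)
#' nrow(map) # 124
#' @export
simulate_genetic_map <- function(n_chromosomes = 12,
                                 markers_per_chromosome = NULL,
                                 chromosome_lengths_cm = NULL,
                                 seed = 1) {
  if (n_chromosomes < 1) stop("`n_chromosomes` must be >= 1", call. = FALSE)
  if (is.null(markers_per_chromosome)) {
    markers_per_chromosome <- if (n_chromosomes == 12) {
      rep(c(11L, 10L), c(4L, 8L))
    } else {
      rep(10L, n_chromosomes)
    }
  }
  if (is.null(chromosome_lengths_cm)) {
    chromosome_lengths_cm <- if (n_chromosomes == 12) {
      c(180, 170, 160, 130, 120, 125, 120, 120, 95, 85, 115, 110)
    } else {
      rep(120, n_chromosomes)
    }
  }
  m <- rep_len(as.integer(markers_per_chromosome), n_chromosomes)
  len <- rep_len(as.numeric(chromosome_lengths_cm), n_chromosomes)
  if (any(m < 2)) stop("each chromosome needs at least 2 markers", call. = FALSE)
  if (any(len <= 0)) stop("chromosome lengths must be positive", call. = FALSE)

  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_chromosomes), function(chr) {
      pos <- if (m[chr] == 2) {
        c(0, len[chr])
      } else {
        c(0, sort(runif(m[chr] - 2L, 0, len[chr])), len[chr])
      }
      data.frame(
        marker = sprintf("M%02d_%02d", chr, seq_len(m[chr])),
        chromosome = chr,
        position_cm = pos,
        stringsAsFactors = FALSE
      )
    })
    map <- do.call(rbind, rows)
    rownames(map) <- NULL
    class(map) <- c("genetic_map", "data.frame")
    validate_genetic_map(map)
    map
  })
}

#' Validate a genetic map
#'
#' Checks the `genetic_map` invariants: required columns, unique marker
#' names genome-wide, >= 2 markers per chromosome, and nondecreasing
#' positions within each chromosome.
#'
#' @param map a data frame with columns `marker`, `chromosome`,
#'   `position_cm`.
#' @return the map, invisibly, with class `genetic_map`.
#' @export
validate_genetic_map <- function(map) {
  need <- c("marker", "chromosome", "position_cm")
  if (!all(need %in% names(map))) {
    stop("map must have columns marker, chromosome, position_cm", call. = FALSE)
  }
  if (anyDuplicated(map$marker)) {
    stop("marker names must be unique genome-wide", call. = FALSE)
  }
  for (chr in unique(map$chromosome)) {
    pos <- map$position_cm[map$chromosome == chr]
    if (length(pos) < 2) stop("chromosome ", chr, " has fewer than 2 markers", call. = FALSE)
    if (is.unsorted(pos)) stop("positions on chromosome ", chr, " are not nondecreasing", call. = FALSE)
  }
  if (!inherits(map, "genetic_map")) class(map) <- c("genetic_map", class(map))
  invisible(map)
}

## One meiosis for all lines at once. H1/H2 are logical matrices
## (lines x markers, TRUE = donor allele); switch_p[j] is the probability of
## switching homologs between marker j and j+1 (0.5 across chromosome
## boundaries, so chromosomes assort independently).
.gamete <- function(H1, H2, switch_p) {
  n <- nrow(H1)
  m <- ncol(H1)
  chooser <- matrix(FALSE, n, m)
  chooser[, 1] <- runif(n) < 0.5
  if (m > 1) {
    for (j in 2:m) {
      chooser[, j] <- xor(chooser[, j - 1], runif(n) < switch_p[j - 1])
    }
  }
  g <- H2
  g[chooser] <- H1[chooser]
  g
}

#' Simulate backcross inbred line genotypes
#'
#' Simulates a BIL population: an F1 between a recipient (code `OU`) and a
#' donor (`AR`) is backcrossed to the recipient `n_backcrosses` times, then
#' selfed for `n_selfing_generations` generations by single-seed descent.
#' Crossovers between adjacent markers are independent Bernoulli events with
#' probability equal to the Kosambi inverse of the map distance; chromosomes
#' assort independently. After one backcross the expected donor-allele
#' dosage is 0.25 and the expected heterozygous fraction after t selfing
#' generations is `0.5 * (1/2)^t`, leaving realistic residual
#' heterozygosity at the default t = 5.
#'
#' @param map a `genetic_map`.
#' @param n_lines number of lines.
#' @param n_backcrosses number of backcrosses to the recipient (>= 1).
#' @param n_selfing_generations number of selfing generations (>= 0).
#' @param missing_rate per-call probability of a missing genotype.
#' @param seed integer seed.
#' @return character matrix (lines x markers) of codes `"OU"`, `"AR"`,
#'   `"HET"`, or `NA` for missing, with line ids as row names and marker
#'   names as column names.
#' @export
simulate_bil_genotypes <- function(map, n_lines = 104, n_backcrosses = 1,
                                   n_selfing_generations = 5,
                                   missing_rate = 0, seed = 1) {
  validate_genetic_map(map)
  if (n_lines < 1) stop("`n_lines` must be >= 1", call. = FALSE)
  if (n_backcrosses < 1) stop("`n_backcrosses` must be >= 1", call. = FALSE)
  if (n_selfing_generations < 0) stop("`n_selfing_generations` must be >= 0", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) stop("`missing_rate` must be in [0, 1)", call. = FALSE)

  m <- nrow(map)
  d <- diff(map$position_cm)
  same_chr <- diff(map$chromosome) == 0
  switch_p <- ifelse(same_chr, kosambi_inverse(pmax(d, 0)), 0.5)

  withr::with_seed(seed, {
    # F1: one donor homolog, one recipient homolog
    H1 <- matrix(TRUE, n_lines, m)
    H2 <- matrix(FALSE, n_lines, m)
    for (b in seq_len(n_backcrosses)) {
      H1 <- .gamete(H1, H2, switch_p)
      H2 <- matrix(FALSE, n_lines, m)
    }
    for (s in seq_len(n_selfing_generations)) {
      g1 <- .gamete(H1, H2, switch_p)
      g2 <- .gamete(H1, H2, switch_p)
      H1 <- g1
      H2 <- g2
    }
    codes <- matrix("HET", n_lines, m)
    codes[H1 & H2] <- "AR"
    codes[!H1 & !H2] <- "OU"
    if (missing_rate > 0) {
      codes[runif(n_lines * m) < missing_rate] <- NA_character_
    }
    dimnames(codes) <- list(sprintf("BIL%03d", seq_len(n_lines)), map$marker)
    codes
  })
}

#' Convert genotype codes to additive dosages
#'
#' Coding: `OU` (recipient homozygote) = -1, `HET` = 0, `AR` (donor
#' homozygote) = +1, so a positive additive effect means the donor allele
#' increases the trait. Missing calls map to `NA` unless `impute_missing`
#' replaces them with 0 (the population-neutral value).
#'
#' @param genotypes character code matrix as from [simulate_bil_genotypes()].
#' @param impute_missing replace `NA` with 0?
#' @return numeric matrix of the same shape.
#' @export
geno_dosage <- function(genotypes, impute_missing = FALSE) {
  bad <- !(genotypes %in% c("OU", "AR", "HET") | is.na(genotypes))
  if (any(bad)) {
    stop("illegal genotype code(s): ",
         paste(unique(genotypes[bad]), collapse = ", "), call. = FALSE)
  }
  d <- matrix(NA_real_, nrow(genotypes), ncol(genotypes),
              dimnames = dimnames(genotypes))
  d[genotypes == "OU"] <- -1
  d[genotypes == "HET"] <- 0
  d[genotypes == "AR"] <- 1
  if (impute_missing) d[is.na(d)] <- 0
  d
}

## Additive dosage at a map position, taken from the nearest marker on that
## chromosome (ground-truth plumbing; interval imputation lives in
## impute_pseudomarker_genotypes()).
.dosage_at <- function(genotypes, map, chromosome, position_cm) {
  on_chr <- which(map$chromosome == chromosome)
  if (!length(on_chr)) stop("no markers on chromosome ", chromosome, call. = FALSE)
  nearest <- on_chr[which.min(abs(map$position_cm[on_chr] - position_cm))]
  geno_dosage(genotypes, impute_missing = TRUE)[, map$marker[nearest]]
}

#' Default planted ground truth for a synthetic BIL study
#'
#' Encodes the study conditions the rest of the package is calibrated
#' against: four additive shoot-weight QTL on chromosomes 3, 6, 7 and 10
#' (effects 0.21, -0.28, 0.21 and 0.20 mg per allele substitution), a
#' polygenic background term sized so the recipient and donor parents sit at
#' 2.91 and 5.11 mg, 20 causal genes whose log2 expression is coupled to the
#' trait, a focal gene on chromosome 9 with trans-eQTL on chromosomes 1 and
#' 7 (effects -0.17 and -0.25 log2 units), and 10% near-zero-expression
#' genes to exercise the FPKM filter.
#'
#' @param map a `genetic_map` on which QTL positions are placed (middle
#'   marker of each QTL chromosome).
#' @param n_genes number of genes the expression generator will emit.
#' @param n_causal number of trait-coupled genes.
#' @param heritability broad-sense heritability of a single trait replicate,
#'   in (0, 1].
#' @return a `synthetic_truth` list with components `qtl`, `baseline_mg`,
#'   `polygenic_coef`, `heritability`, `parent_means_mg`, `causal_genes`,
#'   `eqtl`, `expr_log2_sd`, `near_zero_fraction`, `qpcr`.
#' @export
default_truth <- function(map, n_genes = 5000, n_causal = 20,
                          heritability = 0.6) {
  validate_genetic_map(map)
  mid_pos <- function(chr) {
    pos <- map$position_cm[map$chromosome == chr]
    pos[ceiling(length(pos) / 2)]
  }
  parent_means <- c(ou = 2.91, ar = 5.11)
  qtl_chr <- intersect(c(3, 6, 7, 10), unique(map$chromosome))
  qtl <- data.frame(
    chromosome = qtl_chr,
    position_cm = vapply(qtl_chr, mid_pos, numeric(1)),
    effect = c(0.21, -0.28, 0.21, 0.20)[seq_along(qtl_chr)]
  )
  # parents differ by 2 * (sum of QTL effects + polygenic coefficient)
  polygenic <- diff(parent_means) / 2 - sum(qtl$effect)
  n_causal <- min(n_causal, n_genes)
  causal <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n_causal)),
    coupling = 1.2 * rep_len(c(1, -1), n_causal)
  )
  eqtl_chr <- intersect(c(1, 7), unique(map$chromosome))
  eqtl <- data.frame(
    gene_id = rep(causal$gene_id[1], length(eqtl_chr)),
    chromosome = eqtl_chr,
    position_cm = vapply(eqtl_chr, mid_pos, numeric(1)),
    effect = c(-0.17, -0.25)[seq_along(eqtl_chr)]
  )
  truth <- list(
    qtl = qtl,
    baseline_mg = unname(mean(parent_means)),
    polygenic_coef = unname(polygenic),
    heritability = heritability,
    parent_means_mg = parent_means,
    causal_genes = causal,
    focal_gene = causal$gene_id[1],
    eqtl = eqtl,
    expr_log2_sd = 0.5,
    near_zero_fraction = 0.10,
    qpcr = list(slope = -3.4, intercept = 38, mu_log2_copies = 14,
                trait_coupling = -0.5, bio_sd_log2 = 0.3, tech_sd_cq = 0.15)
  )
  class(truth) <- "synthetic_truth"
  truth
}

#' Simulate shoot-weight trait values for BILs
#'
#' Trait model per line: `baseline + sum(effect_k * dosage_k) +
#' polygenic_coef * mean(dosage) + noise`, with dosage coding OU = -1,
#' HET = 0, AR = +1. The noise standard deviation is scaled so that the
#' requested single-replicate heritability holds
#' (`sd_noise = sd(genetic) * sqrt((1 - h2)/h2)`); `truth$noise_sd`
#' overrides this (required when the genetic variance is zero, e.g. a null
#' simulation). `n_replicates` biological replicates are drawn per line and
#' their mean is what downstream analyses use.
#'
#' @param genotypes genotype code matrix.
#' @param map the `genetic_map`; all QTL positions must lie within the map.
#' @param truth a `synthetic_truth` (see [default_truth()]).
#' @param n_replicates biological replicates per line.
#' @param seed integer seed.
#' @param include_parents also simulate the two parents (`Ouu365`, all-OU;
#'   `ArrozDaTerra`, all-AR)?
#' @return a `trait_vector`: list with `means` (named numeric, mg),
#'   `replicates` (data frame `line_id`, `replicate`, `value_mg`) and
#'   `n_replicates`.
#' @export
simulate_trait <- function(genotypes, map, truth, n_replicates = 3, seed = 1,
                           include_parents = FALSE) {
  validate_genetic_map(map)
  h2 <- truth$heritability
  if (is.null(truth$noise_sd)) {
    if (is.null(h2) || h2 <= 0 || h2 > 1) {
      stop("heritability must be in (0, 1]", call. = FALSE)
    }
  }
  qtl <- truth$qtl
  if (!is.null(qtl) && nrow(qtl)) {
    for (i in seq_len(nrow(qtl))) {
      pos <- map$position_cm[map$chromosome == qtl$chromosome[i]]
      if (!length(pos) || qtl$position_cm[i] < min(pos) - 1e-9 ||
          qtl$position_cm[i] > max(pos) + 1e-9) {
        stop("QTL position ", qtl$position_cm[i], " cM is off the map on chromosome ",
             qtl$chromosome[i], call. = FALSE)
      }
    }
  }
  dall <- geno_dosage(genotypes, impute_missing = TRUE)
  g <- rep(truth$baseline_mg %||% 0, nrow(genotypes))
  names(g) <- rownames(genotypes)
  if (!is.null(qtl) && nrow(qtl)) {
    for (i in seq_len(nrow(qtl))) {
      g <- g + qtl$effect[i] *
        .dosage_at(genotypes, map, qtl$chromosome[i], qtl$position_cm[i])
    }
  }
  poly <- truth$polygenic_coef %||% 0
  g <- g + poly * rowMeans(dall)

  tot_eff <- sum(qtl$effect %||% 0) + poly
  if (include_parents) {
    g <- c(g,
           Ouu365 = (truth$baseline_mg %||% 0) - tot_eff,
           ArrozDaTerra = (truth$baseline_mg %||% 0) + tot_eff)
  }

  noise_sd <- truth$noise_sd
  if (is.null(noise_sd)) {
    sd_g <- sd(g[rownames(genotypes)]) # heritability refers to the BIL population
    if (sd_g == 0) stop("zero genetic variance: supply truth$noise_sd", call. = FALSE)
    noise_sd <- sd_g * sqrt((1 - h2) / h2)
  }

  withr::with_seed(seed, {
    reps <- data.frame(
      line_id = rep(names(g), each = n_replicates),
      replicate = rep(seq_len(n_replicates), length(g)),
      value_mg = rep(g, each = n_replicates) +
        rnorm(length(g) * n_replicates, 0, noise_sd)
    )
  })
  means <- tapply(reps$value_mg, reps$line_id, mean)
  means <- means[names(g)] # keep line order
  structure(
    list(means = setNames(as.numeric(means), names(g)),
         replicates = reps, n_replicates = n_replicates),
    class = "trait_vector"
  )
}

#' Per-line trait means
#'
#' @param trait a `trait_vector` or a named numeric vector.
#' @return named numeric vector of per-line means.
#' @export
trait_means <- function(trait) {
  if (inherits(trait, "trait_vector")) trait$means else trait
}

#' Simulate an FPKM expression matrix coupled to a trait
#'
#' Log-normal expression model on the log2 scale: for gene g and sample i,
#' `log2(FPKM) = mu_g + a_g * eqtl_dosage_i + c_g * z(trait_i) + eps`, with
#' `eps ~ N(0, expr_log2_sd)` and `z` the standardized trait. Causal genes
#' (from `truth$causal_genes`) have nonzero coupling `c_g`; genes listed in
#' `truth$eqtl` get an additive cis/trans genetic effect `a_g` at the stated
#' map position; all other genes are null. A `truth$near_zero_fraction` of
#' non-causal genes gets a baseline low enough that their mean FPKM is below
#' 0.01, to exercise the expression filter. Baselines `mu_g` are drawn from
#' a wide normal on the log2 scale, giving heavy-tailed nonnegative FPKM.
#'
#' @param genotypes genotype code matrix (parent samples `Ouu365` /
#'   `ArrozDaTerra` need not be rows; they are treated as all-OU / all-AR).
#' @param trait `trait_vector` or named numeric vector of per-line values.
#' @param n_genes number of genes (>= number of causal genes).
#' @param truth a `synthetic_truth`.
#' @param map the `genetic_map` (needed when `truth$eqtl` is nonempty).
#' @param sample_line_ids which lines become expression samples (default:
#'   all lines in `trait`).
#' @param seed integer seed.
#' @return numeric matrix of FPKM values, genes x samples, gene ids
#'   `g00001`, ... as row names.
#' @export
simulate_expression <- function(genotypes, trait, n_genes, truth, map = NULL,
                                sample_line_ids = NULL, seed = 1) {
  if (n_genes < 0) stop("`n_genes` must be nonnegative", call. = FALSE)
  means <- trait_means(trait)
  if (is.null(sample_line_ids)) sample_line_ids <- names(means)
  if (!all(sample_line_ids %in% names(means))) {
    stop("sample line ids missing from trait", call. = FALSE)
  }
  y <- means[sample_line_ids]
  z <- if (sd(y) > 0) (y - mean(y)) / sd(y) else y * 0
  causal <- truth$causal_genes
  if (!is.null(causal) && nrow(causal) > n_genes) {
    stop("`n_genes` is smaller than the number of causal genes", call. = FALSE)
  }
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  n_samp <- length(y)

  withr::with_seed(seed, {
    mu <- rnorm(n_genes, log2(5), 3)
    frac0 <- truth$near_zero_fraction %||% 0
    if (frac0 > 0) {
      eligible <- setdiff(gene_ids, causal$gene_id)
      n0 <- floor(frac0 * n_genes)
      nz <- sample(eligible, min(n0, length(eligible)))
      mu[match(nz, gene_ids)] <- log2(5e-4)
    }
    lg <- matrix(rnorm(n_genes * n_samp, 0, truth$expr_log2_sd %||% 0.5),
                 n_genes, n_samp) + mu
    if (!is.null(causal) && nrow(causal)) {
      idx <- match(causal$gene_id, gene_ids)
      lg[idx, ] <- lg[idx, ] + outer(causal$coupling, z)
    }
    eq <- truth$eqtl
    if (!is.null(eq) && nrow(eq)) {
      if (is.null(map)) stop("`map` is required when truth$eqtl is nonempty", call. = FALSE)
      dos <- function(chr, pos) {
        d <- rep(NA_real_, n_samp)
        names(d) <- sample_line_ids
        in_geno <- sample_line_ids %in% rownames(genotypes)
        if (any(in_geno)) {
          d[in_geno] <- .dosage_at(genotypes[sample_line_ids[in_geno], , drop = FALSE],
                                   map, chr, pos)
        }
        d[sample_line_ids == "Ouu365"] <- -1
        d[sample_line_ids == "ArrozDaTerra"] <- 1
        d[is.na(d)] <- 0
        d
      }
      for (i in seq_len(nrow(eq))) {
        gi <- match(eq$gene_id[i], gene_ids)
        if (is.na(gi)) next
        lg[gi, ] <- lg[gi, ] + eq$effect[i] * dos(eq$chromosome[i], eq$position_cm[i])
      }
    }
    fpkm <- 2^lg
    dimnames(fpkm) <- list(gene_ids, sample_line_ids)
    fpkm
  })
}

#' Simulate a complete synthetic BIL dataset
#'
#' Convenience wrapper tying the generator together: genetic map, BIL
#' genotypes, shoot-weight trait for all lines plus the two parents, a
#' subset of lines chosen for "RNA-Seq" (evenly spread across the trait
#' distribution, plus both parents), and the coupled FPKM matrix. All
#' components draw their seeds from `seed` via [rng_substream()].
#'
#' @param n_lines number of BILs (default 104).
#' @param n_genes number of genes in the expression matrix.
#' @param n_rnaseq_lines number of BILs profiled for expression (default 20;
#'   the two parents are always added, giving 22 samples).
#' @param truth optional `synthetic_truth`; defaults to
#'   [default_truth()] on the simulated map.
#' @param n_replicates biological trait replicates per line.
#' @param seed master seed.
#' @param ... passed to [simulate_genetic_map()].
#' @return a `bil_dataset`: list with `map`, `genotypes`, `trait`,
#'   `expression`, `samples` (data frame `sample_id`, `line_id`) and
#'   `truth`.
#' @export
simulate_bil_dataset <- function(n_lines = 104, n_genes = 5000,
                                 n_rnaseq_lines = 20, truth = NULL,
                                 n_replicates = 3, seed = 1, ...) {
  map <- simulate_genetic_map(seed = rng_substream(seed, "map"), ...)
  genotypes <- simulate_bil_genotypes(map, n_lines = n_lines,
                                      seed = rng_substream(seed, "geno"))
  if (is.null(truth)) truth <- default_truth(map, n_genes = n_genes)
  trait <- simulate_trait(genotypes, map, truth, n_replicates = n_replicates,
                          seed = rng_substream(seed, "trait"),
                          include_parents = TRUE)
  bil_means <- trait$means[rownames(genotypes)]
  ord <- names(sort(bil_means))
  pick <- ord[unique(round(seq(1, length(ord), length.out = min(n_rnaseq_lines, length(ord)))))]
  samples <- c(sort(pick), "Ouu365", "ArrozDaTerra")
  expression <- simulate_expression(genotypes, trait, n_genes, truth, map = map,
                                    sample_line_ids = samples,
                                    seed = rng_substream(seed, "expr"))
  structure(
    list(map = map, genotypes = genotypes, trait = trait,
         expression = expression,
         samples = data.frame(sample_id = samples, line_id = samples),
         truth = truth),
    class = "bil_dataset"
  )
}

#' Simulate qPCR measurements for the focal gene
#'
#' Generates per-line template copy numbers for the focal gene from the
#' planted model (`log2 copies = mu + sum(eqtl effects x dosage) +
#' trait_coupling * z(trait) + biological noise`), then converts each
#' biological replicate's copies to quantification cycles through the true
#' standard curve `Cq = intercept + slope * log10(copies)` with technical
#' noise. Also emits a noise-free 10-fold dilution series of standards so
#' [fit_standard_curve()] can recover the curve exactly.
#'
#' @param genotypes genotype code matrix (all lines to be assayed).
#' @param map the `genetic_map`.
#' @param trait `trait_vector` or named numeric vector covering the lines.
#' @param truth a `synthetic_truth` with a `qpcr` component.
#' @param n_bio,n_tech biological / technical replicates per line.
#' @param seed integer seed.
#' @return list with `cq_table` (data frame `line_id`, `bio_rep`,
#'   `tech_rep`, `cq`), `standards` (data frame `copies`, `cq`) and
#'   `true_curve` (list `slope`, `intercept`).
#' @export
simulate_qpcr <- function(genotypes, map, trait, truth, n_bio = 3, n_tech = 3,
                          seed = 1) {
  qp <- truth$qpcr
  if (is.null(qp)) stop("truth has no qpcr component", call. = FALSE)
  lines <- rownames(genotypes)
  y <- trait_means(trait)[lines]
  z <- if (sd(y) > 0) (y - mean(y)) / sd(y) else y * 0
  lc <- rep(qp$mu_log2_copies, length(lines)) + qp$trait_coupling * z
  eq <- truth$eqtl
  if (!is.null(eq) && nrow(eq)) {
    for (i in seq_len(nrow(eq))) {
      lc <- lc + eq$effect[i] *
        .dosage_at(genotypes, map, eq$chromosome[i], eq$position_cm[i])
    }
  }
  withr::with_seed(seed, {
    rows <- expand.grid(tech_rep = seq_len(n_tech), bio_rep = seq_len(n_bio),
                        line_id = lines, stringsAsFactors = FALSE)[, 3:1]
    bio_noise <- rnorm(length(lines) * n_bio, 0, qp$bio_sd_log2)
    bio_lc <- rep(lc, each = n_bio) + bio_noise # per (line, bio_rep)
    copies <- 2^bio_lc
    cq_bio <- qp$intercept + qp$slope * log10(copies)
    rows$cq <- rep(cq_bio, each = n_tech) +
      rnorm(nrow(rows), 0, qp$tech_sd_cq)
    std_copies <- 10^(3:8)
    standards <- data.frame(copies = std_copies,
                            cq = qp$intercept + qp$slope * log10(std_copies))
    list(cq_table = rows, standards = standards,
         true_curve = list(slope = qp$slope, intercept = qp$intercept))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bil_dataset <- function(x, ...) {
  cat("Synthetic BIL dataset\n")
  cat("  lines:   ", nrow(x$genotypes), " BILs, ", ncol(x$genotypes),
      " markers on ", length(unique(x$map$chromosome)), " chromosomes\n", sep = "")
  cat("  samples: ", ncol(x$expression), " expression samples, ",
      nrow(x$expression), " genes\n", sep = "")
  cat("  trait:   shoot weight, ", x$trait$n_replicates,
      " replicates per line\n", sep = "")
  invisible(x)
}
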