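test_that("default map has 124 markers on 12 chromosomes with sorted positions", {
  map <- simulate_genetic_map(seed = 1)
  expect_equal(nrow(map), 124)
  expect_equal(length(unique(map$chromosome)), 12)
  for (chr in unique(map$chromosome)) {
    expect_false(is.unsorted(map$position_cm[map$chromosome == chr]))
  }
  expect_false(anyDuplicated(map$marker) > 0)
})

test_that("two-marker chromosome puts markers at the endpoints", {
  map <- simulate_genetic_map(n_chromosomes = 1, markers_per_chromosome = 2,
                              chromosome_lengths_cm = 100, seed = 3)
  expect_equal(map$position_cm, c(0, 100))
})

test_that("map simulation is deterministic given the seed and validates inputs", {
  expect_identical(simulate_genetic_map(seed = 42), simulate_genetic_map(seed = 42))
  expect_error(simulate_genetic_map(chromosome_lengths_cm = -5), "positive")
  expect_error(simulate_genetic_map(markers_per_chromosome = 1), "at least 2")
})

test_that("BIL genotypes match backcross/selfing expectations at large n", {
  map <- simulate_genetic_map(seed = 1)
  # one backcross, no selfing: donor allele frequency 0.25
  g0 <- simulate_bil_genotypes(map, n_lines = 10000, n_backcrosses = 1,
                               n_selfing_generations = 0, seed = 11)
  donor_frac <- rowMeans(g0 == "AR") + 0.5 * rowMeans(g0 == "HET")
  se <- sd(donor_frac) / sqrt(length(donor_frac))
  expect_lt(abs(mean(donor_frac) - 0.25), 3 * se)

  # five selfing generations: heterozygous fraction 0.5 / 2^5
  g5 <- simulate_bil_genotypes(map, n_lines = 10000, n_backcrosses = 1,
                               n_selfing_generations = 5, seed = 12)
  het_frac <- rowMeans(g5 == "HET")
  se <- sd(het_frac) / sqrt(length(het_frac))
  expect_lt(abs(mean(het_frac) - 0.5 / 32), 3 * se)
})

test_that("recombinant fraction between adjacent markers follows the Kosambi inverse", {
  map <- data.frame(marker = c("a", "b", "c"), chromosome = 1,
                    position_cm = c(0, 20, 20))
  g <- simulate_bil_genotypes(validate_genetic_map(map), n_lines = 8000,
                              n_selfing_generations = 0, seed = 5)
  # after BC1 with no selfing each line carries a single F1 gamete over a
  # recipient background: donor presence (HET) flips between adjacent
  # markers exactly when that gamete recombined
  rec <- mean((g[, "a"] == "HET") != (g[, "b"] == "HET"))
  r_expect <- kosambi_inverse(20)
  se <- sqrt(r_expect * (1 - r_expect) / nrow(g))
  expect_lt(abs(rec - r_expect), 4 * se)
  # zero map distance: identical genotype columns
  expect_identical(g[, "b"], g[, "c"])
})

test_that("trait difference between homozygote classes is twice the additive effect", {
  map <- simulate_genetic_map(n_chromosomes = 2, seed = 2)
  g <- simulate_bil_genotypes(map, n_lines = 60, seed = 3)
  mk <- map$marker[5]
  truth <- list(qtl = data.frame(chromosome = map$chromosome[5],
                                 position_cm = map$position_cm[5],
                                 effect = 0.7),
                baseline_mg = 4, polygenic_coef = 0, heritability = 1)
  tr <- simulate_trait(g, map, truth, n_replicates = 1, seed = 4)
  y <- tr$means
  expect_equal(mean(y[g[, mk] == "AR"]) - mean(y[g[, mk] == "OU"]), 2 * 0.7)
})

test_that("default truth reproduces the parental shoot weights in the noise-free limit", {
  map <- simulate_genetic_map(seed = 1)
  g <- simulate_bil_genotypes(map, n_lines = 30, seed = 2)
  truth <- default_truth(map, n_genes = 100, heritability = 1)
  tr <- simulate_trait(g, map, truth, seed = 3, include_parents = TRUE)
  expect_equal(unname(tr$means["Ouu365"]), 2.91, tolerance = 1e-12)
  expect_equal(unname(tr$means["ArrozDaTerra"]), 5.11, tolerance = 1e-12)
})

test_that("trait variance is explained by QTL dosages as heritability approaches one", {
  map <- simulate_genetic_map(seed = 6)
  g <- simulate_bil_genotypes(map, n_lines = 300, seed = 7)
  truth <- default_truth(map, n_genes = 100, heritability = 0.999)
  truth$polygenic_coef <- 0
  tr <- simulate_trait(g, map, truth, n_replicates = 1, seed = 8)
  D <- vapply(seq_len(nrow(truth$qtl)), function(i) {
    m <- map$marker[which.min(abs(map$position_cm - truth$qtl$position_cm[i]) +
                                1e6 * (map$chromosome != truth$qtl$chromosome[i]))]
    geno_dosage(g, impute_missing = TRUE)[, m]
  }, numeric(nrow(g)))
  fit <- lm(tr$means[rownames(g)] ~ D)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("heritability outside (0, 1] is rejected", {
  map <- simulate_genetic_map(n_chromosomes = 1, seed = 1)
  g <- simulate_bil_genotypes(map, n_lines = 10, seed = 1)
  truth <- default_truth(map, n_genes = 10)
  truth$heritability <- 1.5
  expect_error(simulate_trait(g, map, truth), "heritability")
})

test_that("null expression genes are uncorrelated with the trait on average", {
  map <- simulate_genetic_map(n_chromosomes = 2, seed = 1)
  g <- simulate_bil_genotypes(map, n_lines = 22, seed = 2)
  truth <- default_truth(map, n_genes = 1000, n_causal = 0)
  truth$causal_genes <- truth$causal_genes[0, ]
  truth$eqtl <- truth$eqtl[0, ]
  truth$near_zero_fraction <- 0
  tr <- simulate_trait(g, map, truth, seed = 3)
  ex <- simulate_expression(g, tr, 1000, truth, map = map, seed = 4)
  y <- tr$means[colnames(ex)]
  r <- apply(log2(ex), 1, function(x) if (sd(x) > 0) cor(x, y) else 0)
  expect_lt(abs(mean(r)), 0.03)
})

test_that("a strongly coupled planted gene correlates tightly with the trait", {
  map <- simulate_genetic_map(n_chromosomes = 2, seed = 1)
  g <- simulate_bil_genotypes(map, n_lines = 22, seed = 2)
  truth <- default_truth(map, n_genes = 50, n_causal = 1)
  truth$causal_genes$coupling <- 3
  truth$eqtl <- truth$eqtl[0, ]
  truth$expr_log2_sd <- 0.1
  tr <- simulate_trait(g, map, truth, seed = 3)
  ex <- simulate_expression(g, tr, 50, truth, map = map, seed = 4)
  y <- tr$means[colnames(ex)]
  expect_gt(abs(cor(log2(ex["g00001", ]), y)), 0.9)
})

test_that("requested near-zero genes are the ones removed by the mean filter", {
  map <- simulate_genetic_map(n_chromosomes = 2, seed = 1)
  g <- simulate_bil_genotypes(map, n_lines = 22, seed = 2)
  truth <- default_truth(map, n_genes = 4000, n_causal = 0)
  truth$causal_genes <- truth$causal_genes[0, ]
  truth$eqtl <- truth$eqtl[0, ]
  tr <- simulate_trait(g, map, truth, seed = 3)
  ex <- simulate_expression(g, tr, 4000, truth, map = map, seed = 4)
  kept <- filter_low_expression(ex, preprocess_config())
  removed <- nrow(ex) - nrow(kept)
  expect_gte(removed, 400)        # all 10% planted near-zero genes
  expect_lte(removed, 440)        # plus at most a small tail of the baseline
})

test_that("dataset generation is deterministic and exposes coherent samples", {
  d1 <- simulate_bil_dataset(n_lines = 30, n_genes = 100, n_rnaseq_lines = 8,
                             seed = 99)
  d2 <- simulate_bil_dataset(n_lines = 30, n_genes = 100, n_rnaseq_lines = 8,
                             seed = 99)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$genotypes, d2$genotypes)
  expect_equal(ncol(d1$expression), 10) # 8 BILs + 2 parents
  expect_true(all(colnames(d1$expression) %in% names(d1$trait$means)))
  expect_true(all(d1$truth$causal_genes$gene_id %in% rownames(d1$expression)))
})
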