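test_that("Kosambi map function and inverse behave as exact inverses", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.25), 25 * log(3), tolerance = 1e-14)
  r <- c(0.001, 0.05, 0.1, 0.25, 0.4, 0.49)
  expect_equal(kosambi_inverse(kosambi_cm(r)), r, tolerance = 1e-12)
  expect_true(all(diff(kosambi_cm(seq(0, 0.49, by = 0.01))) > 0))
  expect_error(kosambi_cm(0.5), "0.5")
  expect_error(kosambi_inverse(-1), ">= 0")
})

test_that("pairwise recombination estimates count informative lines only", {
  g <- matrix("OU", 100, 2, dimnames = list(sprintf("L%03d", 1:100), c("a", "b")))
  expect_equal(estimate_recombination_fraction(g, "a", "b")$r, 0)
  g[1:12, "b"] <- "AR"   # discordant
  g[13:15, "b"] <- "HET" # excluded
  est <- estimate_recombination_fraction(g, "a", "b")
  expect_equal(est$informative, 97)
  expect_equal(est$r, 12 / 97)
  # fully discordant: capped just below one half
  g2 <- cbind(a = rep("OU", 10), b = rep("AR", 10))
  rownames(g2) <- paste0("L", 1:10)
  expect_equal(estimate_recombination_fraction(g2, "a", "b")$r, 0.5 - 1e-9)
  g3 <- cbind(a = rep("HET", 5), b = rep("OU", 5))
  rownames(g3) <- paste0("L", 1:5)
  expect_error(estimate_recombination_fraction(g3, "a", "b"), "no informative")
})

test_that("pseudomarker dosages honor observed codings and flank conditioning", {
  map <- validate_genetic_map(data.frame(marker = c("m1", "m2"), chromosome = 1,
                                         position_cm = c(0, 20)))
  g <- rbind(L1 = c("AR", "OU"), L2 = c("OU", "OU"), L3 = c("HET", "AR"),
             L4 = c(NA, "AR"))
  colnames(g) <- map$marker
  grid <- impute_pseudomarker_genotypes(g, map, step_cm = 5)
  pos <- grid$positions$position_cm
  D <- grid$dosage

  expect_equal(unname(D["L1", pos == 0]), 1)   # observed AR
  expect_equal(unname(D["L3", pos == 0]), 0)   # observed HET codes 0
  expect_equal(unname(D["L2", pos == 10]), dosage_enum_oracle(-1, -1, 10, 10))
  expect_lt(abs(D["L2", pos == 10] + 1), 0.06) # both flanks OU, 20 cM apart
  # asymmetric interior positions match the enumeration oracle
  expect_equal(unname(D["L1", pos == 5]), dosage_enum_oracle(1, -1, 5, 15),
               tolerance = 1e-12)
  expect_equal(unname(D["L1", pos == 15]), dosage_enum_oracle(1, -1, 15, 5),
               tolerance = 1e-12)
  # missing left flank: single-flank decay from the right marker
  expect_equal(unname(D["L4", pos == 0]), 1 * (1 - 2 * kosambi_inverse(20)),
               tolerance = 1e-12)
  expect_true(all(D >= -1 & D <= 1))
})

test_that("tightly linked identical flanks pin the dosage at the midpoint", {
  map <- validate_genetic_map(data.frame(marker = c("m1", "m2"), chromosome = 1,
                                         position_cm = c(0, 2)))
  g <- rbind(L1 = c("OU", "OU"))
  colnames(g) <- map$marker
  grid <- impute_pseudomarker_genotypes(g, map, step_cm = 1)
  expect_lt(max(grid$dosage + 1), 1e-3)
})

test_that("a single-marker chromosome falls back to the observed dosage", {
  map <- data.frame(marker = c("m1", "m2", "m3"), chromosome = c(1, 1, 2),
                    position_cm = c(0, 10, 0))
  g <- rbind(L1 = c("OU", "AR", "AR"), L2 = c("OU", "OU", "HET"))
  colnames(g) <- map$marker
  expect_warning(grid <- impute_pseudomarker_genotypes(g, map), "single marker")
  last <- ncol(grid$dosage)
  expect_equal(unname(grid$dosage[, last]), c(1, 0))
})

test_that("cofactor selection finds perfect signals and breaks ties by map order", {
  map <- simulate_genetic_map(n_chromosomes = 3, seed = 8)
  g <- simulate_bil_genotypes(map, n_lines = 80, seed = 9)
  d <- geno_dosage(g, impute_missing = TRUE)
  mk <- map$marker[7]
  y <- setNames(d[, mk], rownames(g))
  expect_true(mk %in% select_cofactors(g, y))

  # duplicated marker column: only the earlier one enters
  g2 <- cbind(g[, 1:10], dup = g[, 7])
  y2 <- setNames(d[, 7] + rnorm(80, 0, 0.1), rownames(g))
  sel <- select_cofactors(g2, y2)
  expect_false(all(c(colnames(g)[7], "dup") %in% sel))
  if (colnames(g)[7] %in% sel || "dup" %in% sel) {
    expect_true(colnames(g)[7] %in% sel)
  }

  # pure noise with a stringent entry threshold: nothing (or almost) enters
  y3 <- setNames(rnorm(80), rownames(g))
  expect_lte(length(select_cofactors(g, y3, entry_p = 0.001)), 1)
})

test_that("the CIM scan recovers a planted additive effect at its marker", {
  map <- simulate_genetic_map(seed = 10)
  g <- simulate_bil_genotypes(map, n_lines = 104, seed = 11)
  d <- geno_dosage(g, impute_missing = TRUE)
  mk <- 30 # marker index
  a <- 0.21
  y <- setNames(a * d[, mk] + rnorm(104, 0, 0.01), rownames(g))
  prof <- cim_scan(g, map, y)
  peak <- prof[which.max(prof$lod), ]
  expect_equal(peak$chromosome, map$chromosome[mk])
  expect_lt(abs(peak$position_cm - map$position_cm[mk]), 2)
  expect_equal(peak$additive_effect, a, tolerance = 0.02)
  expect_true(all(prof$lod >= 0))
})

test_that("cofactors within the window are excluded from the local model", {
  map <- simulate_genetic_map(n_chromosomes = 4, seed = 12)
  g <- simulate_bil_genotypes(map, n_lines = 90, seed = 13)
  d <- geno_dosage(g, impute_missing = TRUE)
  mk <- map$marker[5]
  y <- setNames(d[, mk] + rnorm(90, 0, 0.05), rownames(g))
  prof <- cim_scan(g, map, y, cofactors = mk, window_cm = 10)
  at_mk <- prof$marker == mk & !is.na(prof$marker)
  # with the cofactor excluded locally, the signal is visible at its marker
  expect_gt(prof$lod[at_mk], 10)
  # far away the cofactor absorbs the signal: other chromosomes stay flat
  other <- prof$chromosome != map$chromosome[match(mk, map$marker)]
  expect_lt(max(prof$lod[other]), prof$lod[at_mk] / 2)
})

test_that("permutation threshold is an order-statistic of max LODs", {
  map <- simulate_genetic_map(n_chromosomes = 2, seed = 14)
  g <- simulate_bil_genotypes(map, n_lines = 50, seed = 15)
  y <- setNames(rnorm(50), rownames(g))
  pt <- permutation_threshold(g, map, y, n_permutations = 99, seed = 16)
  expect_length(pt$max_lods, 99)
  expect_equal(pt$threshold, quantile_sort_oracle(pt$max_lods, 0.95))
  # invariant to the stored order of the list
  expect_equal(pt$threshold,
               quantile_sort_oracle(sample(pt$max_lods), 0.95))
  # constant trait: every permuted scan is flat
  yc <- setNames(rep(2, 50), rownames(g))
  ptc <- permutation_threshold(g, map, yc, n_permutations = 25, seed = 17)
  expect_equal(ptc$threshold, 0)
  expect_warning(permutation_threshold(g, map, y, n_permutations = 10, seed = 1),
                 "unstable")
})

test_that("fixed-cofactor and reselected-cofactor permutation modes run", {
  map <- simulate_genetic_map(n_chromosomes = 2, seed = 30)
  g <- simulate_bil_genotypes(map, n_lines = 40, seed = 31)
  d <- geno_dosage(g, impute_missing = TRUE)
  y <- setNames(d[, 3] + rnorm(40, 0, 0.5), rownames(g))
  p_fixed <- permutation_threshold(g, map, y, n_permutations = 20, seed = 32,
                                   cofactors = map$marker[3])
  p_rule <- permutation_threshold(g, map, y, n_permutations = 20, seed = 32,
                                  cofactor_rule = list(entry_p = 0.01,
                                                       exit_p = 0.05,
                                                       max_cofactors = 2))
  expect_true(is.finite(p_fixed$threshold) && p_fixed$threshold >= 0)
  expect_true(is.finite(p_rule$threshold) && p_rule$threshold >= 0)
})

test_that("QTL calls report one peak per supra-threshold region", {
  map <- validate_genetic_map(
    data.frame(marker = paste0("m", 1:6),
               chromosome = rep(1:2, each = 3),
               position_cm = rep(c(0, 25, 50), 2))
  )
  prof <- data.frame(
    chromosome = rep(1:2, each = 11),
    position_cm = rep(seq(0, 50, by = 5), 2),
    marker = NA_character_,
    lod = c(c(0, 1, 2, 4, 5, 4, 2, 1, 0, 0, 0),   # chr1 peak at 20
            c(0, 0, 0, 0, 0, 0, 4, 4, 0, 0, 0)),  # chr2 plateau peak at 30
    additive_effect = 0.3, r2_percent = 10
  )
  class(prof) <- c("lod_profile", "data.frame")
  calls <- call_qtl(prof, map, 3, "SW")
  expect_equal(nrow(calls), 2)
  expect_equal(calls$position_cm, c(20, 30)) # tie broken by smaller cM
  expect_equal(calls$nearest_marker, c("m2", "m5"))
  expect_equal(calls$qtl_id, c("qSW-1", "qSW-2"))
  # nothing above threshold: no calls
  expect_equal(nrow(call_qtl(prof, map, 10, "SW")), 0)
})

test_that("two planted QTL on different chromosomes yield two calls", {
  map <- simulate_genetic_map(n_chromosomes = 4, seed = 18)
  g <- simulate_bil_genotypes(map, n_lines = 104, seed = 19)
  d <- geno_dosage(g, impute_missing = TRUE)
  i1 <- 5
  i2 <- 25
  stopifnot(map$chromosome[i1] != map$chromosome[i2])
  y <- setNames(0.5 * d[, i1] - 0.5 * d[, i2] + rnorm(104, 0, 0.3),
                rownames(g))
  grid <- impute_pseudomarker_genotypes(g, map)
  prof <- cim_scan(g, map, y, grid = grid)
  thr <- permutation_threshold(g, map, y, n_permutations = 100, seed = 20,
                               grid = grid)
  calls <- call_qtl(prof, map, thr, "SW")
  expect_setequal(unique(calls$chromosome),
                  map$chromosome[c(i1, i2)])
})

test_that("eQTL scanning is the same machinery with an expression trait", {
  map <- simulate_genetic_map(n_chromosomes = 3, seed = 21)
  g <- simulate_bil_genotypes(map, n_lines = 80, seed = 22)
  d <- geno_dosage(g, impute_missing = TRUE)
  y <- setNames(d[, 8] + rnorm(80, 0, 0.4), rownames(g))
  grid <- impute_pseudomarker_genotypes(g, map)
  res <- eqtl_scan(g, map, y, gene = "gX", n_permutations = 50, seed = 23,
                   grid = grid)
  ref <- cim_scan(g, map, y, grid = grid, trait_name = "gX")
  expect_equal(res$profile$lod, ref$lod)

  # planted trans effect with a negative sign under AR = +1 coding
  trans_chr <- map$chromosome[8]
  own_chr <- setdiff(unique(map$chromosome), trans_chr)[1]
  yn <- setNames(-0.6 * d[, 8] + rnorm(80, 0, 0.3), rownames(g))
  resn <- eqtl_scan(g, map, yn, gene = "gX", n_permutations = 50, seed = 24,
                    grid = grid)
  expect_true(trans_chr %in% resn$calls$chromosome)
  expect_false(own_chr %in% resn$calls$chromosome)
  expect_lt(resn$calls$additive_effect[resn$calls$chromosome == trans_chr][1], 0)
})
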