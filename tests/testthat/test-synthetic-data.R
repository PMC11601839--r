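test_that("the generator is deterministic and validates its inputs", {
  pop <- population_model()
  ped <- pedigree_spec(n_sibpairs = 3, n_trios = 2)
  a <- simulate_genotypes(pop, ped, 30, 200, seed = 131)
  b <- simulate_genotypes(pop, ped, 30, 200, seed = 131)
  expect_identical(a$geno$dosages, b$geno$dosages)
  expect_identical(a$truth$admixture, b$truth$admixture)
  c2 <- simulate_genotypes(pop, ped, 30, 200, seed = 132)
  expect_false(identical(a$geno$dosages, c2$geno$dosages))
  expect_error(population_model(fst = 0), "strictly")
  expect_error(simulate_genotypes(pop, pedigree_spec(n_sibpairs = 20),
                                  30, 100, seed = 1), "n_samples")
})

test_that("population drift vanishes as fst goes to zero", {
  sim <- simulate_genotypes(population_model(n_pops = 2, fst = 1e-6),
                            pedigree_spec(), 10, 2000, seed = 133)
  pf <- sim$truth$pop_freq
  expect_lt(mean(abs(pf[, 1] - pf[, 2])), 0.005)
  sim2 <- simulate_genotypes(population_model(n_pops = 2, fst = 0.3),
                             pedigree_spec(), 10, 2000, seed = 133)
  expect_gt(mean(abs(sim2$truth$pop_freq[, 1] - sim2$truth$pop_freq[, 2])),
            0.05)
})

test_that("gene dropping conserves allele frequencies in expectation", {
  sim <- simulate_genotypes(population_model(n_pops = 1, fst = 0.05),
                            pedigree_spec(n_sibpairs = 150), 300, 400,
                            seed = 134)
  ped <- sim$truth$pedigree
  kids <- ped$id[ped$sampled]
  offspring_af <- mean(sim$geno$dosages) / 2
  expected_af <- mean(sim$truth$pop_freq[, 1])
  expect_equal(offspring_af, expected_af, tolerance = 0.02)
})

test_that("two populations separate on the leading PC", {
  sim <- simulate_genotypes(population_model(n_pops = 2, fst = 0.1,
                                             admixture_alpha = 0.05),
                            pedigree_spec(), 500, 5000, seed = 135)
  std <- suppressWarnings(standardize_genotypes(sim$geno, sample_ids(sim$geno)))
  pc1 <- svd(std$ZU, nu = 1)$u[, 1]
  pop <- max.col(sim$truth$admixture)
  expect_gt(abs(cor(pc1, pop == 1)), 0.9)
})

test_that("heritability shares are exact in-sample by construction", {
  fx <- small_cohort()
  phe <- simulate_phenotype(fx$geno, fx$pcs, h2_ancestry = 0.2,
                            h2_polygenic = 0.35, h2_snp = 0.01,
                            causal_variant = tail(variant_ids(fx$geno), 1),
                            n_polygenic_snps = 300, seed = 136)
  v <- apply(phe$components, 2, var)
  expect_equal(unname(v), c(0.2, 0.35, 0.01, 0.44), tolerance = 1e-10)
  expect_equal(phe$y,
               setNames(rowSums(phe$components), names(phe$y)))
  ## all shares zero: pure standard-normal-scaled noise
  phe0 <- simulate_phenotype(fx$geno, NULL, seed = 137)
  expect_equal(var(phe0$y), 1, tolerance = 1e-10)
  expect_equal(unname(apply(phe0$components[, 1:3], 2, var)), rep(0, 3))
  expect_error(simulate_phenotype(fx$geno, fx$pcs, h2_ancestry = 0.9,
                                  h2_polygenic = 0.2), "sum")
})

test_that("polygenic pool excludes even chromosomes and the causal SNP", {
  fx <- small_cohort()
  phe <- simulate_phenotype(fx$geno, fx$pcs, h2_polygenic = 0.3,
                            n_polygenic_snps = 200, seed = 138)
  chroms <- fx$geno$bim$chrom[match(phe$polygenic_ids, variant_ids(fx$geno))]
  expect_true(all(as.integer(chroms) %% 2 == 1))
  odd_variant <- phe$polygenic_ids[1]
  expect_error(simulate_phenotype(fx$geno, fx$pcs, h2_snp = 0.01,
                                  causal_variant = odd_variant, seed = 1),
               "polygenic pool")
})

test_that("null phenotypes give uniform association p-values", {
  ## homogeneous unrelated subset; candidate SNP has no effect
  sim <- simulate_genotypes(population_model(n_pops = 1, fst = 0.02),
                            pedigree_spec(), 150, 50, seed = 139)
  g <- as.numeric(sim$geno$dosages[, ncol(sim$geno$dosages)])
  set.seed(140)
  pvals <- replicate(300, {
    phe <- simulate_phenotype(sim$geno, NULL)
    summary(lm(phe$y ~ g))$coefficients[2, 4]
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("PC-R2 categorization matches a per-variant regression oracle", {
  fx <- small_cohort()
  idx <- seq(1, ncol(fx$geno$dosages), by = 400)
  cats <- categorize_variants_by_pc_r2(fx$geno, fx$pcs)
  S <- fx$pcs$scores
  for (j in idx) {
    z <- as.numeric(fx$geno$dosages[, j])
    r2 <- summary(lm(z ~ S))$r.squared
    expect_equal(cats$r2[j], r2, tolerance = 1e-10)
  }
  ## exact linear function of PC1 lands in category D with R2 = 1
  Glin <- genotype_matrix(
    cbind(as.integer(S[, 1] > median(S[, 1])) * 2L, 1L),
    fam = fx$geno$fam)
  lin <- categorize_variants_by_pc_r2(
    Glin, cbind(as.numeric(S[, 1] > median(S[, 1]))))
  expect_equal(lin$category[1], "D")
  expect_equal(lin$r2[1], 1, tolerance = 1e-10)
  ## a constant variant is excluded
  expect_equal(lin$category[2], "excluded")
})

test_that("calibration/power evaluation handles nominal and distorted nulls", {
  set.seed(141)
  ## uniform null: type-I error near alpha, threshold untouched
  p_null <- runif(20000)
  ev <- evaluate_calibration_and_power(p_null, rep(FALSE, 20000),
                                       alpha = 0.05)
  expect_lt(abs(ev$type1_error - 0.05), 0.006)
  ## the adjusted threshold stays near alpha and keeps FPR at or below it
  expect_lte(ev$threshold, 0.05)
  expect_gt(ev$threshold, 0.04)
  expect_lte(mean(p_null < ev$threshold), 0.05)
  ## perfect causal separation: power 1
  ev2 <- evaluate_calibration_and_power(c(p_null, rep(0, 50)),
                                        c(rep(FALSE, 20000), rep(TRUE, 50)),
                                        alpha = 0.05)
  expect_equal(ev2$power, 1)
  ## anti-conservative null (square of uniform): FPR(t) = sqrt(t), so the
  ## adjusted threshold approaches alpha^2 and power drops accordingly
  pn <- runif(40000)^2
  pc <- runif(500)^4
  ev3 <- evaluate_calibration_and_power(c(pn, pc),
                                        c(rep(FALSE, 40000), rep(TRUE, 500)),
                                        alpha = 0.05)
  expect_gt(ev3$type1_error, 0.15)
  expect_lt(abs(ev3$threshold - 0.05^2), 0.3 * 0.05^2)
  power_unadjusted <- mean(pc < 0.05)
  expect_lt(ev3$power, power_unadjusted)
  expect_error(evaluate_calibration_and_power(pc, rep(TRUE, 500)),
               "no null tests")
})
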