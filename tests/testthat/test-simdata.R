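test_that("sim_config fills study-condition defaults and validates", {
  cfg <- sim_config()
  expect_equal(cfg$n_calves, 313)
  expect_equal(cfg$n_farms, 36)
  expect_equal(cfg$components$trait, c("BW", "WH"))
  expect_equal(cfg$sigma2_p[["BW"]], 779.945)
  expect_equal(cfg$true_rG["BW", "WH"], 0.78)
  expect_equal(round(cfg$snp_allele_freqs[["LCORL"]], 4), 0.9809)
  expect_error(sim_config(true_rG = matrix(c(1, 2, 2, 1), 2),
                          traits = c("BW", "WH")), "semidefinite")
  expect_error(sim_config(n_calves = 0), "n_calves")
})

test_that("simulated pedigrees are reproducible and structured", {
  cfg <- sim_config(n_sires = 2, n_dams = 10, n_calves = 20, seed = 5)
  ped1 <- simulate_pedigree(cfg)
  ped2 <- simulate_pedigree(cfg)
  expect_identical(ped1, ped2)
  expect_equal(nrow(ped1), 32)
  calves <- attr(ped1, "calves")
  expect_equal(length(calves), 20)
  expect_true(all(!is.na(ped1$sire[match(calves, ped1$animal)])))

  # paternal half sibs average additive relationship 0.25
  cfg2 <- sim_config(n_sires = 1, n_dams = 40, n_calves = 40, seed = 6)
  ped <- simulate_pedigree(cfg2)
  A <- relationship_matrix(ped)
  calves <- attr(ped, "calves")
  Ac <- A[calves, calves]
  dam_of <- ped$dam[match(calves, ped$animal)]
  same_dam <- outer(dam_of, dam_of, "==")
  off <- Ac[upper.tri(Ac)][!same_dam[upper.tri(same_dam)]]
  expect_equal(mean(off), 0.25, tolerance = 1e-12)
})

test_that("simulated phenotypes carry the configured covariance structure", {
  # all variances zero, no fixed effects: phenotype equals the mean exactly
  cfg0 <- sim_config(n_sires = 3, n_dams = 10, n_calves = 30, traits = "BW",
                     components = data.frame(trait = "BW", sigma2_a = 0,
                                             sigma2_m = 0, sigma2_e = 0),
                     mu = c(BW = 50), sex_effect = 0, season_effect = 0,
                     farm_sd = 0, seed = 2)
  sim0 <- simulate_phenotypes(simulate_pedigree(cfg0), cfg0)
  expect_equal(sim0$pheno$BW, rep(50, 30), tolerance = 1e-9)

  # phenotypic variance near the configured total at n = 1500
  cfg <- sim_config(n_sires = 50, n_dams = 450, n_calves = 1500,
                    traits = "WH", sex_effect = 0, season_effect = 0,
                    farm_sd = 0, seed = 3)
  sim <- simulate_phenotypes(simulate_pedigree(cfg), cfg)
  expect_lt(abs(var(sim$pheno$WH) / 21.534 - 1), 0.10)

  # cross-trait correlation of true breeding values tracks true_rG
  cfg2 <- sim_config(n_sires = 40, n_dams = 400, n_calves = 1500,
                     traits = c("BW", "WH"), seed = 4,
                     sex_effect = 0, season_effect = 0, farm_sd = 0)
  sim2 <- simulate_phenotypes(simulate_pedigree(cfg2), cfg2)
  expect_lt(abs(cor(sim2$truth$bv[, "BW"], sim2$truth$bv[, "WH"]) - 0.78),
            0.05)

  # founder breeding-value variance near sigma2_a
  founders <- rownames(sim2$truth$bv)[grepl("^(S|D)", rownames(sim2$truth$bv))]
  expect_lt(abs(var(sim2$truth$bv[founders, "BW"]) / 260.172 - 1), 0.2)
})

test_that("measurement series round-trip through age standardization", {
  cfg <- sim_config(n_sires = 3, n_dams = 20, n_calves = 50,
                    traits = c("BW", "WH"), measurement_noise_sd = 0,
                    measurement_ages = c(305, 425), seed = 8)
  sim <- simulate_phenotypes(simulate_pedigree(cfg), cfg)
  meas <- simulate_measurement_series(sim$pheno, cfg)
  expect_equal(nrow(meas), 50 * 2 * 2)
  wide <- standardize_table(meas)
  idx <- match(sim$pheno$animal, wide$animal)
  expect_equal(wide$BW[idx], sim$pheno$BW, tolerance = 1e-9)
  expect_equal(wide$WH[idx], sim$pheno$WH, tolerance = 1e-9)

  # noisy recovery is unbiased with RMSE near the propagated level
  cfg2 <- sim_config(n_sires = 5, n_dams = 100, n_calves = 1000,
                     traits = "BW", measurement_noise_sd = c(BW = 1),
                     measurement_ages = c(305, 425), seed = 9)
  sim2 <- simulate_phenotypes(simulate_pedigree(cfg2), cfg2)
  meas2 <- simulate_measurement_series(sim2$pheno, cfg2)
  wide2 <- standardize_table(meas2)
  err <- wide2$BW[match(sim2$pheno$animal, wide2$animal)] - sim2$pheno$BW
  # midpoint interpolation of two points with unit noise: SE = sqrt(0.5)
  expect_lt(abs(mean(err)), 3 * sqrt(0.5) / sqrt(1000))
  expect_lt(abs(sd(err) - sqrt(0.5)), 3 * sqrt(0.5) / sqrt(2000))

  # ages entirely below the target are flagged as extrapolated
  cfg3 <- sim_config(n_sires = 2, n_dams = 5, n_calves = 10, traits = "BW",
                     measurement_ages = c(250, 300), seed = 10)
  sim3 <- simulate_phenotypes(simulate_pedigree(cfg3), cfg3)
  qc <- attr(standardize_table(simulate_measurement_series(sim3$pheno, cfg3)),
             "qc")
  expect_true(all(qc$method == "extrapolated"))
})

test_that("gene dropping preserves founder allele frequencies", {
  # fixed allele: monomorphic locus
  cfg <- sim_config(n_sires = 3, n_dams = 20, n_calves = 60,
                    snp_allele_freqs = c(L1 = 1.0), seed = 12)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  expect_true(genotype_summary(g$genotype)$monomorphic)

  # skewed frequency regime: heterozygote count near binomial expectation
  cfg2 <- sim_config(n_sires = 10, n_dams = 118, n_calves = 236,
                     snp_allele_freqs = c(LCORL = 463 / 472), seed = 13)
  ped2 <- simulate_pedigree(cfg2)
  hets <- sapply(1:40, function(k) {
    cfg_k <- sim_config(n_sires = 10, n_dams = 118, n_calves = 236,
                        snp_allele_freqs = c(LCORL = 463 / 472),
                        seed = 1000 + k)
    g <- simulate_genotypes(simulate_pedigree(cfg_k), cfg_k)
    calves <- attr(simulate_pedigree(cfg_k), "calves")
    sum(g$genotype[match(calves, g$animal)] == "CT")
  })
  p <- 463 / 472
  expected <- 2 * p * (1 - p) * 236
  expect_lt(abs(mean(hets) - expected),
            3 * sqrt(expected * (1 - 2 * p * (1 - p))) / sqrt(40) + 0.5)

  # gene-dropped frequency close to the founder frequency
  cfg3 <- sim_config(n_sires = 20, n_dams = 200, n_calves = 600,
                     snp_allele_freqs = c(L = 0.7),
                     snp_alleles = list(L = c("A", "G")), seed = 14)
  ped3 <- simulate_pedigree(cfg3)
  g3 <- simulate_genotypes(ped3, cfg3)
  s3 <- genotype_summary(g3$genotype)
  expect_lt(abs(s3$allele_freq[["A"]] - 0.7), 3 * sqrt(0.7 * 0.3 / (2 * 820)) + 0.02)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(n_sires = 4, n_dams = 20, n_calves = 40, seed = 99)
  ped <- simulate_pedigree(cfg)
  s1 <- simulate_phenotypes(ped, cfg)
  s2 <- simulate_phenotypes(ped, cfg)
  expect_identical(s1, s2)
  m1 <- simulate_measurement_series(s1$pheno, cfg)
  m2 <- simulate_measurement_series(s1$pheno, cfg)
  expect_identical(m1, m2)
  g1 <- simulate_genotypes(ped, cfg)
  g2 <- simulate_genotypes(ped, cfg)
  expect_identical(g1, g2)
})
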