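test_that("the generator is deterministic given the seed", {
  cfg <- sim_config(n_families = 30, n_snps = 3, seed = 99)
  a <- simulate_pedigree_genotypes(cfg)
  b <- simulate_pedigree_genotypes(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$truth$x_pat, b$truth$x_pat)
  expect_identical(simulate_poe_phenotype(cfg, a$truth),
                   simulate_poe_phenotype(cfg, b$truth))
  tcfg <- trio_sim_config(n_trios = 50, seed = 99)
  expect_identical(simulate_ascertained_trios(tcfg)$genotypes$dosage,
                   simulate_ascertained_trios(tcfg)$genotypes$dosage)
})

test_that("a seed is mandatory", {
  expect_error(sim_config(n_families = 5), "seed")
  expect_error(trio_sim_config(n_trios = 5), "seed")
})

test_that("founder allele frequencies match the configured MAF", {
  cfg <- sim_config(n_families = 2000, family_shape = "trio", n_snps = 1,
                    maf = 0.3, genotype_missing_rate = 0, seed = 5)
  sim <- simulate_pedigree_genotypes(cfg)
  expect_lt(abs(mean(sim$genotypes$dosage) / 2 - 0.3), 0.01)
  # maf 0: no minor alleles anywhere
  cfg0 <- sim_config(n_families = 50, n_snps = 1, maf = 0, seed = 5)
  sim0 <- simulate_pedigree_genotypes(cfg0)
  expect_true(all(sim0$genotypes$dosage == 0L, na.rm = TRUE))
})

test_that("truth decomposition is consistent with emitted dosages", {
  cfg <- sim_config(n_families = 100, family_shape = "nuclear", n_snps = 3,
                    seed = 13)
  sim <- simulate_pedigree_genotypes(cfg)
  d <- sim$genotypes$dosage
  tt <- sim$truth$x_pat + sim$truth$x_mat
  expect_equal(unname(d[!is.na(d)]), tt[!is.na(d)])
  # missing rate close to the configured 1.3%
  expect_lt(abs(mean(is.na(d)) - 0.013), 0.012)
})

test_that("the phenotype model is the stated linear predictor on the log scale", {
  # near-zero noise, covariate effects off: ln(bmi) = mu + beta_pat * x_pat
  cfg <- sim_config(n_families = 40, family_shape = "trio", n_snps = 1,
                    maf = 0.5, beta_pat = 0.2, beta_mat = 0, mu = 3,
                    beta_age = 0, beta_sex = 0, beta_t2d = 0, sigma = 1e-9,
                    genotype_missing_rate = 0, seed = 77)
  sim <- simulate_pedigree_genotypes(cfg)
  ph <- simulate_poe_phenotype(cfg, sim$truth)
  expect_equal(log(ph$bmi), 3 + 0.2 * sim$truth$x_pat[, 1], tolerance = 1e-6)
})

test_that("equal parental effects are recovered undiluted by the standard test", {
  cfg <- sim_config(n_families = 1000, family_shape = "trio", n_snps = 1,
                    beta_pat = 0.03, beta_mat = 0.03, sigma = 0.15,
                    genotype_missing_rate = 0, seed = 31)
  sim <- simulate_pedigree_genotypes(cfg)
  ph <- simulate_poe_phenotype(cfg, sim$truth)
  r <- fit_allelic_regression(ln_transform(ph), sim$genotypes$dosage[, 1],
                              ph[, c("age", "sex", "t2d")], mode = "standard")
  expect_lt(abs(r$beta - 0.03), 2 * r$se)
})

test_that("ascertainment with maternal risk excess skews transmissions maternally", {
  signs <- vapply(1:40, function(i) {
    ts <- simulate_ascertained_trios(
      trio_sim_config(n_trios = 705, maf = 0.3, rr_mat = 2, rr_pat = 1,
                      seed = 4e6 + i))
    tab <- pat_table(ts$pedigree, ts$genotypes, allele = "minor")
    tab$n_maternal > tab$n_paternal
  }, TRUE)
  expect_gte(mean(signs), 0.9)
})

test_that("impossible ascertainment fails with a bounded-attempts error", {
  cfg <- trio_sim_config(n_trios = 10, maf = 0.01, baseline_risk = 1e-6,
                         seed = 2, max_batches = 2L)
  expect_error(simulate_ascertained_trios(cfg), "ascertainment failed")
})

test_that("simulator output round-trips through the PED/MAP readers", {
  cfg <- sim_config(n_families = 15, family_shape = "nuclear", n_snps = 2,
                    seed = 61)
  sim <- simulate_pedigree_genotypes(cfg)
  out <- write_genotypes(sim$genotypes, sim$pedigree)
  g2 <- read_genotypes(out$ped, out$map)
  for (v in 1:2) {
    a <- sim$genotypes$dosage[, v]; b <- g2$dosage[, v]
    expect_true(isTRUE(all.equal(unname(a), unname(b))) ||
                isTRUE(all.equal(unname(a), 2L - unname(b))))
  }
  expect_identical(read_pedigree(write_pedigree(sim$pedigree))$iid,
                   sim$pedigree$iid)
})
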