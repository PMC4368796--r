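test_that("the trait transform is the natural log of BMI", {
  expect_equal(ln_transform(exp(2)), 2)
  expect_equal(ln_transform(1), 0)
  expect_equal(ln_transform(26.1), log(26.1), tolerance = 1e-12)
  expect_error(ln_transform(c(25, -1)), "positive")
})

test_that("allelic regression recovers a noise-free linear signal exactly", {
  set.seed(2)
  x <- rbinom(60, 2, 0.4); age <- runif(60, 20, 70)
  y <- 0.5 * x + 0.1 * age
  r <- suppressWarnings(    # lm warns about the essentially perfect fit
    fit_allelic_regression(y, x, data.frame(age = age), mode = "standard",
                           snp_id = "rs1", effect_allele = "A"))
  expect_equal(r$beta, 0.5, tolerance = 1e-8)
  expect_lt(r$p, 1e-12)
  expect_equal(r$n, 60L)
  expect_equal(r$ci95, c(r$beta - 1.959964 * r$se, r$beta + 1.959964 * r$se),
               tolerance = 1e-6)
})

test_that("degenerate predictors are rejected with clear errors", {
  y <- rnorm(30)
  expect_error(fit_allelic_regression(y, rep(0L, 30), mode = "paternal"),
               "monomorphic")
  expect_error(fit_allelic_regression(y[1:2], c(0L, 1L), mode = "paternal"),
               "too few")
  expect_error(fit_allelic_regression(y, rep(2L, 30), mode = "paternal"),
               "outside")
})

test_that("flipping the effect allele negates beta and keeps p, in all modes", {
  set.seed(8)
  n <- 150
  covs <- data.frame(age = runif(n, 20, 70), sex = rbinom(n, 1, 0.5) + 1)
  for (mode in c("standard", "paternal", "maternal")) {
    x <- if (mode == "standard") rbinom(n, 2, 0.3) else rbinom(n, 1, 0.3)
    y <- 0.03 * x + 0.002 * covs$age + rnorm(n, sd = 0.1)
    top <- if (mode == "standard") 2L else 1L
    a <- fit_allelic_regression(y, x, covs, mode = mode)
    b <- fit_allelic_regression(y, top - x, covs, mode = mode)
    expect_equal(b$beta, -a$beta, tolerance = 1e-10)
    expect_equal(b$p, a$p, tolerance = 1e-10)
  }
})

test_that("parental predictors report the doubled-scale beta alongside", {
  set.seed(9)
  x <- rbinom(100, 1, 0.3)
  y <- 0.05 * x + rnorm(100, sd = 0.1)
  r <- fit_allelic_regression(y, x, mode = "paternal")
  expect_equal(r$beta_doubled_scale, r$beta / 2)
  # doubling the predictor halves beta and leaves p unchanged
  r2 <- fit_allelic_regression(y, 2 * x, mode = "standard")
  expect_equal(r2$beta, r$beta / 2, tolerance = 1e-10)
  expect_equal(r2$p, r$p, tolerance = 1e-10)
})

test_that("slope comparison follows the normal-reference Wald form", {
  a <- mock_assoc(0.2, 0.1); b <- mock_assoc(0.2, 0.1)
  eq <- compare_betas(a, b)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  cb <- compare_betas(mock_assoc(0.2, 0.1), mock_assoc(-0.1, 0.1))
  expect_equal(cb$t, 0.3 / sqrt(0.02), tolerance = 1e-6)
  expect_equal(cb$p, 0.0338949, tolerance = 1e-5)
  # finite-df override moves p the right way
  cb_t <- compare_betas(mock_assoc(0.2, 0.1), mock_assoc(-0.1, 0.1), df = 20)
  expect_gt(cb_t$p, cb$p)
  expect_error(compare_betas(mock_assoc(1, 1), mock_assoc(1, 1, snp_id = "rs2")),
               "mismatch")
  expect_error(compare_betas(mock_assoc(1, 1),
                             mock_assoc(1, 1, effect_allele = "G")),
               "orientation")
  expect_error(compare_betas(mock_assoc(1, 0), mock_assoc(1, 1)), "positive")
})

test_that("standard errors reconstruct from 95% confidence intervals", {
  expect_equal(se_from_ci(-0.003, 0.010), 0.0033164, tolerance = 1e-4)
  s <- 0.0123; beta <- 0.4
  expect_equal(se_from_ci(beta - 1.959964 * s, beta + 1.959964 * s, beta), s,
               tolerance = 1e-8)
  expect_error(se_from_ci(0, 0), "exceed")
  expect_error(se_from_ci(0.1, 0.2, beta = 0.5), "outside")
})

test_that("the Bonferroni threshold divides alpha by the test count", {
  expect_equal(bonferroni_threshold(0.05, 1, 1), 0.05)
  expect_equal(bonferroni_threshold(0.06, 2, 3), 0.01)
  expect_equal(bonferroni_threshold(0.05, 22, 3), 0.05 / 66)
})

test_that("a pure-maternal effect is diluted in the standard test and found by the maternal test", {
  set.seed(14)
  n <- 300; b_mat <- 0.05
  res <- t(replicate(200, {
    xp <- rbinom(n, 1, 0.3); xm <- rbinom(n, 1, 0.3)
    y <- b_mat * xm + rnorm(n, sd = 0.15)
    pp <- fit_allelic_regression(y, xp, mode = "paternal")$p
    pm <- fit_allelic_regression(y, xm, mode = "maternal")$p
    bs <- fit_allelic_regression(y, xp + xm, mode = "standard")$beta
    c(pp = pp, pm = pm, bs = bs)
  }))
  expect_lt(median(res[, "pm"]), median(res[, "pp"]))
  # standard-mode slope centers near the parental average b_mat / 2
  expect_lt(abs(mean(res[, "bs"]) - b_mat / 2), 0.005)
})

test_that("the paternal-mode CI covers a simulated paternal effect at nominal rate", {
  set.seed(15)
  hits <- replicate(200, {
    n <- 500
    xp <- rbinom(n, 1, 0.3)
    y <- 0.02 * xp + rnorm(n, sd = 0.1)
    r <- fit_allelic_regression(y, xp, mode = "paternal")
    r$ci95[1] <= 0.02 && 0.02 <= r$ci95[2]
  })
  expect_gte(mean(hits), 0.90)
})
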