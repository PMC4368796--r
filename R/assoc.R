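#' Natural-log transform of BMI
#'
#' @param pheno Phenotype table from [read_phenotypes()], or a numeric
#'   vector of BMI values.
#' @return Numeric vector `log(bmi)`; `NA` passes through.
#' @export
ln_transform <- function(pheno) {
  bmi <- if (is.numeric(pheno)) pheno else pheno$bmi
  if (any(bmi <= 0, na.rm = TRUE)) stop("BMI must be strictly positive")
  log(bmi)
}

#' Per-SNP allelic regression on a quantitative trait
#'
#' Ordinary least squares of the (log-transformed) trait on an allelic
#' predictor with covariate adjustment. In `standard` mode the predictor is
#' the 0-2 minor-allele dosage; in `paternal`/`maternal` mode it is the 0/1
#' allele inherited from that parent. Rows with a missing predictor, trait
#' or covariate are dropped (complete-case; `n` reports the rows used).
#'
#' Some pipelines coerce the haploid parental predictor into diploid input
#' by doubling each allele; that rescaling halves the reported beta and
#' leaves the p-value unchanged, so `beta_doubled_scale = beta / 2` is
#' also reported for parental modes.
#'
#' @param y Numeric trait (e.g. [ln_transform()] of BMI).
#' @param x Allelic predictor, same length as `y`.
#' @param covariates Optional `data.frame` of covariates (e.g. age, sex,
#'   t2d), all columns entering the model linearly.
#' @param mode One of `"standard"`, `"paternal"`, `"maternal"`.
#' @param snp_id,effect_allele Metadata carried into the result.
#' @return An object of class `"assoc_result"`: list with `snp_id`, `mode`,
#'   `effect_allele`, `beta`, `se`, `ci95` (beta +/- 1.96 se), `p`
#'   (two-sided), `n`, and `beta_doubled_scale` for parental modes.
#' @examples
#' set.seed(1)
#' x <- rbinom(200, 1, 0.3)
#' y <- 0.05 * x + rnorm(200, sd = 0.1)
#' fit_allelic_regression(y, x, mode = "paternal", snp_id = "rs1")
#' @export
fit_allelic_regression <- function(y, x, covariates = NULL,
                                   mode = c("standard", "paternal", "maternal"),
                                   snp_id = NA_character_,
                                   effect_allele = NA_character_) {
  mode <- match.arg(mode)
  dat <- data.frame(.y = y, .x = x)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(y))
    dat <- cbind(dat, covariates)
  }
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  npar <- ncol(dat)  # intercept + predictor + covariates = ncol(dat) - 1 + 1
  if (n <= npar)
    stop("too few complete observations (n = ", n, ") for ", npar,
         " parameters")
  rng <- if (mode == "standard") c(0, 2) else c(0, 1)
  if (any(dat$.x < rng[1] | dat$.x > rng[2]))
    stop("predictor outside ", rng[1], "-", rng[2], " for mode '", mode, "'")
  if (length(unique(dat$.x)) < 2L)
    stop("monomorphic/unusable predictor for ",
         if (is.na(snp_id)) "variant" else snp_id)
  fit <- lm(.y ~ ., data = dat)
  sm <- summary(fit)$coefficients
  beta <- sm[".x", "Estimate"]; se <- sm[".x", "Std. Error"]
  p <- sm[".x", "Pr(>|t|)"]
  z <- qnorm(0.975)
  res <- list(snp_id = snp_id, mode = mode, effect_allele = effect_allele,
              beta = beta, se = se, ci95 = c(beta - z * se, beta + z * se),
              p = p, n = n)
  if (mode != "standard") res$beta_doubled_scale <- beta / 2
  structure(res, class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s [%s] %s: beta = %.4g (95%% CI %.4g, %.4g), p = %.3g, n = %d\n",
              x$snp_id, x$effect_allele, x$mode, x$beta, x$ci95[1], x$ci95[2],
              x$p, x$n))
  invisible(x)
}

#' Compare paternal and maternal effect estimates
#'
#' Wald-type comparison of two independent regression slopes:
#' `t = (beta_pat - beta_mat) / sqrt(se_pat^2 + se_mat^2)`, referred by
#' default to the standard normal (equivalently t with large df; a finite
#' `df` override is available).
#'
#' @param a,b `assoc_result` objects for the paternal and maternal tests of
#'   the same SNP, on the same effect allele.
#' @param df Optional degrees of freedom for a t reference instead of the
#'   normal.
#' @return List with `snp_id`, `delta` (beta_pat - beta_mat), `t`, `p`
#'   (two-sided).
#' @export
compare_betas <- function(a, b, df = NULL) {
  if (!identical(a$snp_id, b$snp_id))
    stop("snp mismatch: ", a$snp_id, " vs ", b$snp_id)
  if (!identical(a$effect_allele, b$effect_allele))
    stop("effect-allele orientation mismatch for ", a$snp_id, ": ",
         a$effect_allele, " vs ", b$effect_allele)
  if (a$se <= 0 || b$se <= 0) stop("standard errors must be positive")
  delta <- a$beta - b$beta
  t <- delta / sqrt(a$se^2 + b$se^2)
  p <- if (is.null(df)) 2 * pnorm(-abs(t)) else 2 * pt(-abs(t), df = df)
  list(snp_id = a$snp_id, delta = delta, t = t, p = p)
}

#' Standard error from a 95% confidence interval
#'
#' @param low,high CI bounds (normalized so `low < high`).
#' @param beta Optional point estimate; when given, it must lie inside the
#'   interval.
#' @return `(high - low) / (2 * 1.959964)`.
#' @export
se_from_ci <- function(low, high, beta = NULL) {
  if (any(high <= low)) stop("CI upper bound must exceed lower bound")
  if (!is.null(beta) && any(beta < low | beta > high))
    stop("beta outside its confidence interval")
  (high - low) / (2 * qnorm(0.975))
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise level.
#' @param m_snps Number of variants tested.
#' @param k_tests Number of test modes per variant.
#' @return `alpha / (m_snps * k_tests)`.
#' @examples
#' bonferroni_threshold(0.05, 22, 3)   # 7.58e-4, printed as 7.5e-4
#' @export
bonferroni_threshold <- function(alpha, m_snps, k_tests = 1) {
  stopifnot(alpha > 0, m_snps >= 1, k_tests >= 1)
  alpha / (m_snps * k_tests)
}

#' Run all three association modes across SNPs
#'
#' For every variant, fits the standard dosage regression and, where phased
#' data are supplied, the paternal-only and maternal-only regressions, all
#' adjusted for the given covariates; then compares the paternal and
#' maternal slopes per SNP.
#'
#' @param g A (QC-passed) `genotype_matrix`.
#' @param ph A `phased_genotypes` aligned to `g`'s retained variants (may
#'   be `NULL` to run the standard test only).
#' @param pheno Phenotype table ([read_phenotypes()] format); matched to
#'   samples by `iid`.
#' @param covariate_cols Phenotype columns used as covariates.
#' @param df Optional df override for [compare_betas()].
#' @return `list(assoc = data.frame, comparison = data.frame)`; `assoc` has
#'   one row per (snp, mode) with `snp_id`, `mode`, `effect_allele`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `p`, `n`; `comparison` one row per
#'   snp with `delta`, `t`, `p`.
#' @export
assoc_table <- function(g, ph = NULL, pheno,
                        covariate_cols = c("age", "sex", "t2d"), df = NULL) {
  m <- match(g$samples, pheno$iid)
  y <- rep(NA_real_, length(g$samples))
  y[!is.na(m)] <- ln_transform(pheno$bmi[m[!is.na(m)]])
  covs <- as.data.frame(
    lapply(covariate_cols, function(cc) {
      v <- rep(NA_real_, length(g$samples))
      v[!is.na(m)] <- as.numeric(pheno[[cc]][m[!is.na(m)]])
      v
    }))
  names(covs) <- covariate_cols

  rows <- list(); comps <- list()
  for (v in seq_len(nrow(g$variants))) {
    sid <- g$variants$snp_id[v]
    ea <- g$variants$minor_allele[v]
    fits <- list()
    preds <- list(standard = g$dosage[, v])
    if (!is.null(ph)) {
      pv <- match(sid, ph$variants$snp_id)
      if (!is.na(pv)) {
        preds$paternal <- ph$paternal[match(g$samples, ph$samples), pv]
        preds$maternal <- ph$maternal[match(g$samples, ph$samples), pv]
      }
    }
    for (mode in names(preds)) {
      r <- tryCatch(
        fit_allelic_regression(y, preds[[mode]], covs, mode = mode,
                               snp_id = sid, effect_allele = ea),
        error = function(e) e)
      if (!inherits(r, "error")) fits[[mode]] <- r
      rows[[length(rows) + 1L]] <- if (inherits(r, "error"))
        data.frame(snp_id = sid, mode = mode, effect_allele = ea,
                   beta = NA, se = NA, ci_low = NA, ci_high = NA, p = NA,
                   n = NA, note = conditionMessage(r))
      else
        data.frame(snp_id = sid, mode = mode, effect_allele = ea,
                   beta = r$beta, se = r$se, ci_low = r$ci95[1],
                   ci_high = r$ci95[2], p = r$p, n = r$n, note = "")
    }
    if (!is.null(fits$paternal) && !is.null(fits$maternal)) {
      cb <- compare_betas(fits$paternal, fits$maternal, df = df)
      comps[[length(comps) + 1L]] <-
        data.frame(snp_id = sid, delta = cb$delta, t = cb$t, p = cb$p)
    }
  }
  list(assoc = do.call(rbind, rows),
       comparison = if (length(comps)) do.call(rbind, comps)
                    else data.frame(snp_id = character(), delta = numeric(),
                                    t = numeric(), p = numeric()))
}
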