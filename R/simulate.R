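#' Configuration for the pedigree/phenotype simulator
#'
#' Defaults emulate an adult family cohort of the kind the package's
#' quantitative analyses target: 141 families, 27 candidate SNPs, founder
#' genotypes at Hardy-Weinberg proportions, a log-normal BMI-like trait
#' with separate paternal and maternal per-allele effects, age/sex/T2D
#' covariates, and a per-genotype missing rate of 1.3% (a 98.7% call rate).
#'
#' @param n_families Number of families.
#' @param family_shape `"nuclear"` (two founders + `n_children`),
#'   `"trio"` (one child) or `"three_generation"` (two grandparents, their
#'   child, a founder spouse, and `n_children` grandchildren).
#' @param n_children Children per sibship (ignored for `"trio"`).
#' @param n_snps Number of independent SNPs.
#' @param maf Minor allele frequency per SNP, recycled; in \[0, 0.5\].
#' @param beta_pat,beta_mat Per-allele effects of the paternally/maternally
#'   inherited minor allele on the ln-trait, recycled across SNPs.
#' @param mu Intercept of the ln-trait.
#' @param beta_age,beta_sex,beta_t2d Covariate effects on the ln-trait
#'   (sex enters as an indicator for female).
#' @param sigma Residual SD of the ln-trait; must be positive.
#' @param age_mean,age_sd,age_range Gaussian age distribution, clamped.
#' @param sex_prob_female Probability an individual of unassigned sex is
#'   female.
#' @param t2d_prev T2D prevalence.
#' @param genotype_missing_rate Per-genotype missing probability, applied
#'   after the transmission truth is stored.
#' @param ld_r2 Optional target r2 between SNP 1 and SNP 2 (requires
#'   `n_snps = 2`): founder haplotypes are drawn jointly and transmitted
#'   without recombination.
#' @param seed Mandatory integer seed; every draw is reproducible from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_families = 141, family_shape = c("nuclear", "trio",
                                                          "three_generation"),
                       n_children = 2, n_snps = 27, maf = 0.3,
                       beta_pat = 0, beta_mat = 0, mu = 3.16,
                       beta_age = 0.002, beta_sex = 0.01, beta_t2d = 0.05,
                       sigma = 0.2, age_mean = 45.4, age_sd = 17.2,
                       age_range = c(18, 90), sex_prob_female = 0.59,
                       t2d_prev = 0.09, genotype_missing_rate = 0.013,
                       ld_r2 = NULL, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  family_shape <- match.arg(family_shape)
  maf <- rep_len(maf, n_snps)
  stopifnot(all(maf >= 0), all(maf <= 0.5), sigma > 0,
            genotype_missing_rate >= 0, genotype_missing_rate <= 1,
            t2d_prev >= 0, t2d_prev <= 1)
  if (!is.null(ld_r2) && n_snps != 2L)
    stop("ld_r2 mode requires exactly 2 SNPs")
  structure(list(n_families = n_families, family_shape = family_shape,
                 n_children = n_children, n_snps = n_snps, maf = maf,
                 beta_pat = rep_len(beta_pat, n_snps),
                 beta_mat = rep_len(beta_mat, n_snps),
                 mu = mu, beta_age = beta_age, beta_sex = beta_sex,
                 beta_t2d = beta_t2d, sigma = sigma, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range,
                 sex_prob_female = sex_prob_female, t2d_prev = t2d_prev,
                 genotype_missing_rate = genotype_missing_rate,
                 ld_r2 = ld_r2, seed = as.integer(seed)),
            class = "sim_config")
}

# derived per-module seeds, kept inside 32-bit integer range
.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1000000000) + offset)
}

# draw founder haplotypes: matrix n x n_snps of 0/1
.founder_haps <- function(n, cfg) {
  if (!is.null(cfg$ld_r2)) {
    p1 <- cfg$maf[1]; p2 <- cfg$maf[2]
    D <- sqrt(cfg$ld_r2 * p1 * (1 - p1) * p2 * (1 - p2))
    pAB <- p1 * p2 + D
    probs <- c(pAB, p1 - pAB, p2 - pAB, 1 - p1 - p2 + pAB)  # 11,10,01,00
    if (any(probs < -1e-12)) stop("ld_r2 incompatible with the given MAFs")
    draw <- sample(4L, n, replace = TRUE, prob = pmax(probs, 0))
    cbind(as.integer(draw %in% c(1L, 2L)), as.integer(draw %in% c(1L, 3L)))
  } else {
    matrix(rbinom(n * cfg$n_snps, 1L, rep(cfg$maf, each = n)), n, cfg$n_snps)
  }
}

# transmit one haplotype from a parent with haplotypes (h1, h2)
.transmit <- function(h1, h2, ld) {
  n_snps <- length(h1)
  if (ld) {
    if (runif(1) < 0.5) h1 else h2   # whole haplotype, no recombination
  } else {
    pick <- rbinom(n_snps, 1L, 0.5)
    ifelse(pick == 1L, h1, h2)
  }
}

#' Simulate pedigree genotypes by gene dropping
#'
#' Founders receive haplotypes at Hardy-Weinberg proportions given the
#' configured MAFs; every non-founder receives one uniformly chosen allele
#' from each parent. The true paternally and maternally inherited alleles
#' of every individual (founders' latent origins included) are stored
#' before missingness is applied, so phasing and regression can be checked
#' against the generating truth.
#'
#' @param cfg A [sim_config()].
#' @return `list(pedigree, genotypes, truth)` where `truth` is a
#'   `"sim_truth"` list with matrices `x_pat`, `x_mat` (minor-allele
#'   indicators), `samples`, `sex`, and the generating `config`.
#' @export
simulate_pedigree_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  fids <- sprintf("F%04d", seq_len(cfg$n_families))
  recs <- list()
  for (f in fids) {
    id <- function(role) paste0(f, "_", role)
    kid_sex <- function() sample(c("1", "2"), 1L)
    k <- if (cfg$family_shape == "trio") 1L else cfg$n_children
    kids <- lapply(seq_len(k), function(i)
      c(f, id(paste0("c", i)), NA, NA, kid_sex()))
    if (cfg$family_shape == "three_generation") {
      base <- list(c(f, id("gf"), NA, NA, "1"),
                   c(f, id("gm"), NA, NA, "2"),
                   c(f, id("fa"), id("gf"), id("gm"), "1"),
                   c(f, id("mo"), NA, NA, "2"))
      kids <- lapply(kids, function(r) { r[3] <- id("fa"); r[4] <- id("mo"); r })
    } else {
      base <- list(c(f, id("fa"), NA, NA, "1"),
                   c(f, id("mo"), NA, NA, "2"))
      kids <- lapply(kids, function(r) { r[3] <- id("fa"); r[4] <- id("mo"); r })
    }
    recs <- c(recs, base, kids)
  }
  m <- do.call(rbind, recs)
  ped <- data.frame(fid = m[, 1], iid = m[, 2], father = m[, 3],
                    mother = m[, 4],
                    sex = ifelse(m[, 5] == "1", "male", "female"),
                    affected = NA_integer_, stringsAsFactors = FALSE)
  ped$founder <- is.na(ped$father) & is.na(ped$mother)
  class(ped) <- c("pedigree", "data.frame")

  n <- nrow(ped)
  x_pat <- matrix(0L, n, cfg$n_snps)
  x_mat <- matrix(0L, n, cfg$n_snps)
  fh <- .founder_haps(sum(ped$founder), cfg)
  mh <- .founder_haps(sum(ped$founder), cfg)
  x_pat[ped$founder, ] <- fh      # founders' latent parental origins
  x_mat[ped$founder, ] <- mh
  # parents precede children in construction order within each family
  ord <- seq_len(n)
  fa_i <- match(ped$father, ped$iid)
  mo_i <- match(ped$mother, ped$iid)
  ld <- !is.null(cfg$ld_r2)
  for (i in ord[!ped$founder]) {
    x_pat[i, ] <- .transmit(x_pat[fa_i[i], ], x_mat[fa_i[i], ], ld)
    x_mat[i, ] <- .transmit(x_pat[mo_i[i], ], x_mat[mo_i[i], ], ld)
  }
  dosage <- x_pat + x_mat
  if (cfg$genotype_missing_rate > 0) {
    miss <- matrix(runif(n * cfg$n_snps) < cfg$genotype_missing_rate,
                   n, cfg$n_snps)
    dosage[miss] <- NA_integer_
  }
  variants <- data.frame(snp_id = sprintf("snp%02d", seq_len(cfg$n_snps)),
                         chrom = "16",
                         pos = 53737000L + (seq_len(cfg$n_snps) - 1L) * 40000L,
                         allele1 = "A", allele2 = "G", minor_allele = "A",
                         major_allele = "G", maf_tie = FALSE,
                         stringsAsFactors = FALSE)
  g <- new_genotype_matrix(dosage, variants, ped$iid)
  attr(g, "pedigree") <- ped
  truth <- structure(list(x_pat = x_pat, x_mat = x_mat, samples = ped$iid,
                          sex = ifelse(ped$sex == "female", 2L, 1L),
                          config = cfg),
                     class = "sim_truth")
  list(pedigree = ped, genotypes = g, truth = truth)
}

#' Simulate a quantitative phenotype with origin-specific allelic effects
#'
#' Generates `ln(trait) = mu + sum_s(beta_pat[s] X_pat[s] +
#' beta_mat[s] X_mat[s]) + beta_age age + beta_sex I(female) +
#' beta_t2d t2d + N(0, sigma)` and emits the trait as `bmi = exp(.)`.
#'
#' @param cfg The [sim_config()] used to generate `truth`.
#' @param truth A `"sim_truth"` from [simulate_pedigree_genotypes()].
#' @return Phenotype `data.frame(iid, bmi, age, sex, t2d)` in the
#'   [read_phenotypes()] layout.
#' @export
simulate_poe_phenotype <- function(cfg, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(.derive_seed(cfg$seed, 104729L))
  n <- length(truth$samples)
  age <- pmin(pmax(rnorm(n, cfg$age_mean, cfg$age_sd), cfg$age_range[1]),
              cfg$age_range[2])
  sex <- truth$sex
  t2d <- rbinom(n, 1L, cfg$t2d_prev)
  gen <- as.vector(truth$x_pat %*% cfg$beta_pat + truth$x_mat %*% cfg$beta_mat)
  lnbmi <- cfg$mu + gen + cfg$beta_age * age + cfg$beta_sex * (sex == 2L) +
    cfg$beta_t2d * t2d + rnorm(n, 0, cfg$sigma)
  data.frame(iid = truth$samples, bmi = exp(lnbmi), age = age, sex = sex,
             t2d = t2d, stringsAsFactors = FALSE)
}

#' Configuration for the ascertained-trio simulator
#'
#' @param n_trios Number of affected-offspring trios to retain.
#' @param maf Risk-allele (minor) frequency per SNP, recycled; disease risk
#'   depends on SNP 1.
#' @param n_snps Number of independent SNPs.
#' @param rr_pat,rr_mat Multiplicative risk per paternally/maternally
#'   inherited copy of the risk allele at SNP 1.
#' @param baseline_risk Risk with zero risk alleles.
#' @param link `"multiplicative"` (risk capped at 1) or `"logistic"`
#'   (rr applied to the odds).
#' @param seed Mandatory integer seed.
#' @param max_batches Bound on the number of sampling batches before the
#'   simulator gives up (guards impossible ascertainment settings).
#' @return A list of class `"trio_sim_config"`.
#' @export
trio_sim_config <- function(n_trios = 705, maf = 0.3, n_snps = 1,
                            rr_pat = 1, rr_mat = 1, baseline_risk = 0.05,
                            link = c("multiplicative", "logistic"), seed,
                            max_batches = 1000L) {
  if (missing(seed)) stop("a seed is mandatory")
  link <- match.arg(link)
  maf <- rep_len(maf, n_snps)
  stopifnot(n_trios >= 1, all(maf > 0), all(maf <= 0.5), rr_pat > 0,
            rr_mat > 0, baseline_risk > 0, baseline_risk <= 1)
  structure(list(n_trios = n_trios, maf = maf, n_snps = n_snps,
                 rr_pat = rr_pat, rr_mat = rr_mat,
                 baseline_risk = baseline_risk, link = link,
                 seed = as.integer(seed), max_batches = as.integer(max_batches)),
            class = "trio_sim_config")
}

#' Simulate case-parent trios ascertained on an affected child
#'
#' Parent genotypes are drawn at Hardy-Weinberg proportions, child alleles
#' are gene-dropped, and the child is affected with probability
#' `baseline_risk * rr_pat^X_pat * rr_mat^X_mat` (capped at 1; or through
#' the logistic link on the odds). Only trios with an affected child are
#' retained; sampling continues in batches until `n_trios` are collected.
#'
#' @param cfg A [trio_sim_config()].
#' @return `list(pedigree, genotypes, truth)`; the pedigree marks children
#'   affected, and `truth` stores each child's true paternal/maternal
#'   risk-allele indicators.
#' @export
simulate_ascertained_trios <- function(cfg) {
  stopifnot(inherits(cfg, "trio_sim_config"))
  set.seed(cfg$seed)
  ns <- cfg$n_snps
  keep_f1 <- keep_f2 <- keep_m1 <- keep_m2 <- keep_cp <- keep_cm <-
    matrix(integer(0), 0L, ns)
  got <- 0L
  batch <- max(1000L, cfg$n_trios)
  for (b in seq_len(cfg$max_batches)) {
    hap <- function() matrix(rbinom(batch * ns, 1L, rep(cfg$maf, each = batch)),
                             batch, ns)
    f1 <- hap(); f2 <- hap(); m1 <- hap(); m2 <- hap()
    pickp <- matrix(rbinom(batch * ns, 1L, 0.5), batch, ns)
    pickm <- matrix(rbinom(batch * ns, 1L, 0.5), batch, ns)
    cp <- ifelse(pickp == 1L, f1, f2)
    cm <- ifelse(pickm == 1L, m1, m2)
    risk <- if (cfg$link == "multiplicative") {
      pmin(1, cfg$baseline_risk * cfg$rr_pat^cp[, 1] * cfg$rr_mat^cm[, 1])
    } else {
      odds <- cfg$baseline_risk / (1 - cfg$baseline_risk) *
        cfg$rr_pat^cp[, 1] * cfg$rr_mat^cm[, 1]
      odds / (1 + odds)
    }
    aff <- rbinom(batch, 1L, risk) == 1L
    if (any(aff)) {
      keep_f1 <- rbind(keep_f1, f1[aff, , drop = FALSE])
      keep_f2 <- rbind(keep_f2, f2[aff, , drop = FALSE])
      keep_m1 <- rbind(keep_m1, m1[aff, , drop = FALSE])
      keep_m2 <- rbind(keep_m2, m2[aff, , drop = FALSE])
      keep_cp <- rbind(keep_cp, cp[aff, , drop = FALSE])
      keep_cm <- rbind(keep_cm, cm[aff, , drop = FALSE])
      got <- got + sum(aff)
    }
    if (got >= cfg$n_trios) break
  }
  if (got < cfg$n_trios)
    stop("ascertainment failed: only ", got, " affected trios after ",
         cfg$max_batches, " batches; parameters may make affection ",
         "(nearly) impossible")
  sel <- seq_len(cfg$n_trios)
  keep <- lapply(list(f1 = keep_f1, f2 = keep_f2, m1 = keep_m1, m2 = keep_m2,
                      cp = keep_cp, cm = keep_cm),
                 function(x) x[sel, , drop = FALSE])

  fids <- sprintf("T%04d", sel)
  ped <- data.frame(
    fid = rep(fids, each = 3L),
    iid = as.vector(t(cbind(paste0(fids, "_f"), paste0(fids, "_m"),
                            paste0(fids, "_c")))),
    father = as.vector(t(cbind(NA, NA, paste0(fids, "_f")))),
    mother = as.vector(t(cbind(NA, NA, paste0(fids, "_m")))),
    sex = rep(c("male", "female", "unknown"), cfg$n_trios),
    affected = rep(c(NA_integer_, NA_integer_, 1L), cfg$n_trios),
    stringsAsFactors = FALSE)
  ped$sex[seq(3, nrow(ped), by = 3)] <- sample(c("male", "female"),
                                               cfg$n_trios, replace = TRUE)
  ped$founder <- is.na(ped$father) & is.na(ped$mother)
  class(ped) <- c("pedigree", "data.frame")

  n_ind <- 3L * cfg$n_trios
  dosage <- matrix(NA_integer_, n_ind, ns)
  fi <- seq(1L, n_ind, by = 3L)
  dosage[fi, ] <- keep$f1 + keep$f2
  dosage[fi + 1L, ] <- keep$m1 + keep$m2
  dosage[fi + 2L, ] <- keep$cp + keep$cm
  variants <- data.frame(snp_id = sprintf("snp%02d", seq_len(ns)),
                         chrom = "16",
                         pos = 53737000L + (seq_len(ns) - 1L) * 40000L,
                         allele1 = "A", allele2 = "G", minor_allele = "A",
                         major_allele = "G", maf_tie = FALSE,
                         stringsAsFactors = FALSE)
  g <- new_genotype_matrix(dosage, variants, ped$iid)
  attr(g, "pedigree") <- ped
  x_pat <- matrix(0L, n_ind, ns); x_mat <- matrix(0L, n_ind, ns)
  x_pat[fi, ] <- keep$f1; x_mat[fi, ] <- keep$f2
  x_pat[fi + 1L, ] <- keep$m1; x_mat[fi + 1L, ] <- keep$m2
  x_pat[fi + 2L, ] <- keep$cp; x_mat[fi + 2L, ] <- keep$cm
  truth <- structure(list(x_pat = x_pat, x_mat = x_mat, samples = ped$iid,
                          sex = ifelse(ped$sex == "female", 2L, 1L),
                          config = cfg),
                     class = "sim_truth")
  list(pedigree = ped, genotypes = g, truth = truth)
}
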