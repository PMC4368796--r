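#' SNP quality-control thresholds
#'
#' Defaults are the standard pre-phasing filters for array data: per-SNP
#' missing rate < 5%, exact Hardy-Weinberg P > 1e-4, minor allele frequency
#' > 0.01. All three rules are strict inequalities.
#'
#' @param max_missing Maximum tolerated per-SNP missing fraction (exclusive).
#' @param min_hwe_p Minimum HWE exact p-value (exclusive).
#' @param min_maf Minimum minor allele frequency (exclusive).
#' @return A list of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(max_missing = 0.05, min_hwe_p = 1e-4,
                          min_maf = 0.01) {
  stopifnot(max_missing > 0, max_missing < 1,
            min_hwe_p > 0, min_hwe_p < 1,
            min_maf > 0, min_maf < 1)
  structure(list(max_missing = max_missing, min_hwe_p = min_hwe_p,
                 min_maf = min_maf), class = "qc_thresholds")
}

#' Per-SNP missing rate
#'
#' @param g A `genotype_matrix`.
#' @param v Variant index/indices; default all.
#' @return Fraction of samples with missing dosage, per variant.
#' @export
snp_missing_rate <- function(g, v = seq_len(nrow(g$variants))) {
  if (length(g$samples) == 0L) stop("empty sample set")
  colMeans(is.na(g$dosage[, v, drop = FALSE]))
}

#' Per-SNP minor allele frequency
#'
#' Computed among non-missing chromosomes as `min(p, 1 - p)` where `p` is
#' the frequency of the dosage-counted allele.
#'
#' @inheritParams snp_missing_rate
#' @return MAF per variant.
#' @export
snp_maf <- function(g, v = seq_len(nrow(g$variants))) {
  d <- g$dosage[, v, drop = FALSE]
  nn <- colSums(!is.na(d))
  if (any(nn == 0L))
    stop("all-missing variant: ",
         paste(g$variants$snp_id[v][nn == 0L], collapse = ", "))
  p <- colSums(d, na.rm = TRUE) / (2 * nn)
  pmin(p, 1 - p)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the allele counts, the probability of each
#' possible heterozygote count is computed and the two-sided p-value is the
#' sum of probabilities of all configurations no more probable than the
#' observed one.
#'
#' @param n_aa Count of one homozygote class.
#' @param n_ab Count of heterozygotes.
#' @param n_bb Count of the other homozygote class.
#' @return Exact p-value in (0, 1]. Symmetric in `n_aa` and `n_bb`.
#' @examples
#' hwe_exact_p(25, 50, 25)
#' hwe_exact_p(0, 20, 0)   # maximal heterozygote excess -> small p
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("genotype counts must be >= 0")
  n <- n_aa + n_ab + n_bb
  if (n < 1L) stop("at least one genotyped individual required")
  n_rare <- 2L * min(n_aa, n_bb) + n_ab      # rare-allele count
  # possible het counts share the parity of n_rare
  hets <- seq(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
  # stable recurrence for P(het = h | n, n_rare), unnormalized
  probs <- numeric(length(hets))
  mid0 <- which.min(abs(hets - n_rare * (2 * n - n_rare) / (2 * n)))
  probs[mid0] <- 1
  if (mid0 < length(hets)) {
    for (k in mid0:(length(hets) - 1L)) {
      h <- hets[k]
      # P(h+2)/P(h) = 4 * n_rare_hom * n_common_hom / ((h+2)(h+1))
      rhom <- (n_rare - h) / 2; chom <- n - h - rhom
      probs[k + 1L] <- probs[k] * 4 * rhom * chom / ((h + 2) * (h + 1))
    }
  }
  if (mid0 > 1L) {
    for (k in mid0:2L) {
      h <- hets[k]
      rhom <- (n_rare - h) / 2; chom <- n - h - rhom
      probs[k - 1L] <- probs[k] * h * (h - 1) / (4 * (rhom + 1) * (chom + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_ab, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

#' Combine QC statistics into a pass/fail decision
#'
#' Applies the strict-inequality rules: pass requires
#' `missing_rate < max_missing`, `hwe_p > min_hwe_p` and `maf > min_maf`.
#'
#' @param missing_rate,maf,hwe_p Per-variant statistics (vectorized).
#' @param thresholds A [qc_thresholds()] object.
#' @return `data.frame(pass, fail_reasons)`; `fail_reasons` is a
#'   comma-separated string, empty iff `pass`.
#' @export
qc_pass <- function(missing_rate, maf, hwe_p, thresholds = qc_thresholds()) {
  f_miss <- !(missing_rate < thresholds$max_missing)
  f_hwe <- !(hwe_p > thresholds$min_hwe_p)
  f_maf <- !(maf > thresholds$min_maf)
  reasons <- mapply(function(a, b, c) {
    paste(c(if (a) "missing_rate", if (b) "hwe", if (c) "maf"),
          collapse = ",")
  }, f_miss, f_hwe, f_maf)
  data.frame(pass = !(f_miss | f_hwe | f_maf), fail_reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Apply SNP-level quality control
#'
#' Computes per-variant missing rate, MAF and the exact HWE p-value, applies
#' the strict-inequality rules of [qc_pass()], and drops failing variants.
#'
#' @param g A `genotype_matrix`.
#' @param thresholds A [qc_thresholds()] object.
#' @param founders_only Logical; when `TRUE`, the HWE test is restricted to
#'   pedigree founders (requires `ped`). Default `FALSE`: all genotyped
#'   individuals enter the test.
#' @param ped Pedigree, only needed for `founders_only = TRUE`.
#' @return `list(genotypes = filtered genotype_matrix, report = data.frame)`
#'   with report columns `snp_id`, `missing_rate`, `maf`, `hwe_p`, `pass`,
#'   `fail_reasons`.
#' @export
apply_qc <- function(g, thresholds = qc_thresholds(), founders_only = FALSE,
                     ped = attr(g, "pedigree")) {
  miss <- snp_missing_rate(g)
  nn <- colSums(!is.na(g$dosage))
  maf <- ifelse(nn == 0L, 0, colSums(g$dosage, na.rm = TRUE) / (2 * pmax(nn, 1L)))
  maf <- pmin(maf, 1 - maf)
  hg <- g$dosage
  if (founders_only) {
    if (is.null(ped)) stop("founders_only = TRUE requires a pedigree")
    hg <- hg[g$samples %in% ped$iid[ped$founder], , drop = FALSE]
  }
  hwe_p <- vapply(seq_len(ncol(hg)), function(v) {
    d <- hg[, v]
    n0 <- sum(d == 0L, na.rm = TRUE); n1 <- sum(d == 1L, na.rm = TRUE)
    n2 <- sum(d == 2L, na.rm = TRUE)
    if (n0 + n1 + n2 == 0L) return(1)
    hwe_exact_p(n2, n1, n0)
  }, 0)
  dec <- qc_pass(miss, maf, hwe_p, thresholds)
  report <- data.frame(snp_id = g$variants$snp_id, missing_rate = miss,
                       maf = maf, hwe_p = hwe_p, pass = dec$pass,
                       fail_reasons = dec$fail_reasons,
                       stringsAsFactors = FALSE, row.names = NULL)
  out <- subset_variants(g, dec$pass)
  attr(out, "pedigree") <- ped
  list(genotypes = out, report = report)
}
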