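# Small builders used across test files. Fixtures are constructed in code;
# nothing is read from disk.

# genotype_matrix from a plain dosage matrix (counts of minor allele "A")
make_gmat <- function(dosage, snp_ids = sprintf("s%d", seq_len(ncol(dosage))),
                      samples = sprintf("i%d", seq_len(nrow(dosage)))) {
  variants <- data.frame(snp_id = snp_ids, chrom = "16",
                         pos = seq_len(ncol(dosage)) * 1000L,
                         allele1 = "A", allele2 = "G", minor_allele = "A",
                         major_allele = "G", maf_tie = FALSE,
                         stringsAsFactors = FALSE)
  new_genotype_matrix(dosage, variants, samples)
}

# phased_genotypes from allele matrices; all samples origin-eligible
make_phased <- function(pat, mat, eligible = rep(TRUE, nrow(pat)),
                        samples = sprintf("i%d", seq_len(nrow(pat)))) {
  variants <- data.frame(snp_id = sprintf("s%d", seq_len(ncol(pat))),
                         chrom = "16", pos = seq_len(ncol(pat)) * 1000L,
                         allele1 = "A", allele2 = "G", minor_allele = "A",
                         major_allele = "G", maf_tie = FALSE,
                         stringsAsFactors = FALSE)
  src <- matrix(ifelse(is.na(pat) | is.na(mat), "unresolved", "propagated"),
                nrow(pat), ncol(pat))
  new_phased_genotypes(pat, mat, src, variants, samples, eligible)
}

trio_ped <- function() {
  read_pedigree(c("F1 f 0 0 1", "F1 m 0 0 2", "F1 k f m 1"))
}

# one-variant trio genotypes from allele-pair strings
trio_geno <- function(f, m, k) {
  read_genotypes(c(paste("F1 f 0 0 1 -9", f), paste("F1 m 0 0 2 -9", m),
                   paste("F1 k f m 1 -9", k)), "1 rs1 0 100")
}

# Independent HWE oracle: closed-form conditional probability of each
# heterozygote count via log-factorials (the implementation uses a
# ratio recurrence instead).
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nr <- 2 * min(n_aa, n_bb) + n_ab
  hets <- seq(nr %% 2, min(nr, 2 * n - nr), by = 2)
  logw <- vapply(hets, function(h) {
    rhom <- (nr - h) / 2
    chom <- n - h - rhom
    lfactorial(n) - lfactorial(rhom) - lfactorial(h) - lfactorial(chom) +
      h * log(2)
  }, 0)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  sum(w[w <= w[match(n_ab, hets)] * (1 + 1e-9)])
}

# mock assoc_result for compare_betas tests
mock_assoc <- function(beta, se, snp_id = "rs1", effect_allele = "A",
                       mode = "paternal") {
  structure(list(snp_id = snp_id, mode = mode, effect_allele = effect_allele,
                 beta = beta, se = se,
                 ci95 = c(beta - 1.959964 * se, beta + 1.959964 * se),
                 p = 2 * stats::pnorm(-abs(beta / se)), n = 500L),
            class = "assoc_result")
}
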