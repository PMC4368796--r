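#' Full quantitative-trait POE pipeline
#'
#' Runs SNP quality control, pedigree phasing, the unphased-rate filter,
#' the three association modes (standard, paternal, maternal) adjusted for
#' covariates, the paternal-vs-maternal slope comparison, and the
#' Bonferroni threshold `alpha / (m_snps * 3)`.
#'
#' @param ped Pedigree.
#' @param g `genotype_matrix`.
#' @param pheno Phenotype table ([read_phenotypes()] layout).
#' @param thresholds [qc_thresholds()].
#' @param phase_threshold Unphased-rate exclusion bound (default 0.30).
#' @param alpha Family-wise significance level.
#' @param covariate_cols Phenotype columns entering every regression.
#' @param df Optional df override for [compare_betas()].
#' @param out_dir Optional directory: writes `qc_report.tsv`,
#'   `phasing_report.tsv`, `assoc.tsv`, `beta_compare.tsv`, each with a
#'   provenance header.
#' @param seed Seed recorded in the provenance header (the pipeline itself
#'   is deterministic).
#' @return List with `qc_report`, `phasing_report`, `assoc`, `comparison`,
#'   `bonferroni`, `n_snps_tested`, `mean_phasing_rate`.
#' @export
run_quant_pipeline <- function(ped, g, pheno, thresholds = qc_thresholds(),
                               phase_threshold = 0.30, alpha = 0.05,
                               covariate_cols = c("age", "sex", "t2d"),
                               df = NULL, out_dir = NULL, seed = NA) {
  qc <- apply_qc(g, thresholds, ped = ped)
  if (nrow(qc$genotypes$variants) == 0L)
    stop("no variants remain after QC")
  ph <- phase_pedigree(ped, qc$genotypes)
  fl <- filter_unphased(ph, phase_threshold)
  if (nrow(fl$phased$variants) == 0L)
    stop("no variants remain after the unphased-rate filter")
  g2 <- subset_variants(qc$genotypes,
                        qc$genotypes$variants$snp_id %in%
                          fl$phased$variants$snp_id)
  at <- assoc_table(g2, fl$phased, pheno, covariate_cols, df = df)
  m <- nrow(g2$variants)
  res <- list(qc_report = qc$report, phasing_report = fl$report,
              assoc = at$assoc, comparison = at$comparison,
              bonferroni = bonferroni_threshold(alpha, m, 3),
              n_snps_tested = m,
              mean_phasing_rate = attr(fl$report, "mean_phasing_rate"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- c(sprintf("seed=%s", seed), sprintf("alpha=%g", alpha),
              sprintf("qc: missing<%g hwe_p>%g maf>%g",
                      thresholds$max_missing, thresholds$min_hwe_p,
                      thresholds$min_maf),
              sprintf("phase_threshold=%g", phase_threshold))
    .write_tsv(res$qc_report, file.path(out_dir, "qc_report.tsv"), prov)
    .write_tsv(res$phasing_report, file.path(out_dir, "phasing_report.tsv"),
               prov)
    .write_tsv(res$assoc, file.path(out_dir, "assoc.tsv"), prov)
    .write_tsv(res$comparison, file.path(out_dir, "beta_compare.tsv"), prov)
  }
  res
}

#' Case-parent trio PAT pipeline
#'
#' Checks the pedigree for trio structure (families that are not a single
#' child with two founder parents are skipped with a warning), counts
#' transmissions of the designated allele per SNP and applies the exact
#' binomial parental asymmetry test.
#'
#' @inheritParams run_quant_pipeline
#' @param allele `"major"` or `"minor"`: the allele whose transmissions
#'   are counted.
#' @return The PAT table ([pat_table()] format) with attribute
#'   `"n_families_skipped"`.
#' @export
run_trio_pipeline <- function(ped, g, allele = c("major", "minor"),
                              out_dir = NULL, seed = NA) {
  allele <- match.arg(allele)
  is_trio <- vapply(split(seq_len(nrow(ped)), ped$fid), function(idx) {
    length(idx) == 3L && sum(ped$founder[idx]) == 2L &&
      sum(!ped$founder[idx]) == 1L
  }, TRUE)
  skipped <- sum(!is_trio)
  if (skipped > 0L)
    warning(skipped, " non-trio famil",
            if (skipped == 1L) "y" else "ies", " skipped")
  keep <- ped$fid %in% names(is_trio)[is_trio]
  tab <- pat_table(ped[keep, , drop = FALSE], g, allele = allele)
  attr(tab, "n_families_skipped") <- skipped
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(tab, file.path(out_dir, "pat.tsv"),
               c(sprintf("seed=%s", seed), sprintf("allele=%s", allele),
                 sprintf("n_families_skipped=%d", skipped)))
  }
  tab
}
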