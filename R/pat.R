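#' Count informative parental transmissions in case-parent trios
#'
#' For each trio with a heterozygous (affected) child, determines which
#' parent transmitted the designated allele. With dosages of that allele
#' `gf` (father), `gm` (mother) and a heterozygous child, transmission is
#' paternal when the father can supply the allele and the mother can supply
#' the other (`gf >= 1` and `gm <= 1`) but not vice versa, and maternal in
#' the mirror case. Both parents heterozygous leaves the origin ambiguous
#' and the trio uninformative; Mendelian-impossible combinations are
#' excluded and counted.
#'
#' @param father,mother,child Integer vectors of designated-allele dosages
#'   (0/1/2), one element per trio; trios with any missing value are
#'   skipped.
#' @param snp_id,allele_counted Metadata carried into the result.
#' @return List of class `"transmission_counts"`: `n_paternal`,
#'   `n_maternal`, plus bookkeeping `n_ambiguous`, `n_impossible`,
#'   `n_missing`, `n_child_not_het`.
#' @examples
#' # father AA, mother GG, child AG, counting A: forced paternal
#' count_transmissions(2L, 0L, 1L)
#' @export
count_transmissions <- function(father, mother, child,
                                snp_id = NA_character_,
                                allele_counted = NA_character_) {
  stopifnot(length(father) == length(child), length(mother) == length(child))
  ok <- !(is.na(father) | is.na(mother) | is.na(child))
  n_missing <- sum(!ok)
  gf <- father[ok]; gm <- mother[ok]; gc <- child[ok]
  if (any(!(gf %in% 0:2) | !(gm %in% 0:2) | !(gc %in% 0:2)))
    stop("genotype dosages must be 0, 1 or 2")
  het <- gc == 1L
  n_not_het <- sum(!het)
  gf <- gf[het]; gm <- gm[het]
  pat_possible <- gf >= 1L & gm <= 1L
  mat_possible <- gm >= 1L & gf <= 1L
  paternal <- pat_possible & !mat_possible
  maternal <- mat_possible & !pat_possible
  ambiguous <- pat_possible & mat_possible
  impossible <- !pat_possible & !mat_possible
  structure(list(snp_id = snp_id, allele_counted = allele_counted,
                 n_paternal = sum(paternal), n_maternal = sum(maternal),
                 n_ambiguous = sum(ambiguous), n_impossible = sum(impossible),
                 n_missing = n_missing, n_child_not_het = n_not_het),
            class = "transmission_counts")
}

#' Parental asymmetry test (exact binomial)
#'
#' Tests whether the designated allele is transmitted to heterozygous
#' affected offspring equally often by fathers and mothers. Under the null
#' of no parental asymmetry the paternal count is Binomial(n, 0.5) given
#' n informative transmissions; the two-sided p-value doubles the smaller
#' exact tail, capped at 1.
#'
#' @param n_paternal,n_maternal Informative transmission counts; a
#'   `transmission_counts` object may be given as the first argument.
#' @return List of class `"pat_result"`: `snp_id`, `n_paternal`,
#'   `n_maternal`, `n_informative`, `p`.
#' @examples
#' pat_binomial(111, 152)$p   # maternal excess
#' pat_binomial(129, 128)$p   # balanced: p capped at 1
#' @export
pat_binomial <- function(n_paternal, n_maternal = NULL) {
  snp_id <- NA_character_
  if (inherits(n_paternal, "transmission_counts")) {
    tc <- n_paternal
    snp_id <- tc$snp_id
    n_paternal <- tc$n_paternal; n_maternal <- tc$n_maternal
  }
  stopifnot(n_paternal >= 0, n_maternal >= 0)
  n <- n_paternal + n_maternal
  if (n < 1L) stop("no informative trios")
  k <- min(n_paternal, n_maternal)
  p <- min(1, 2 * pbinom(k, n, 0.5))
  structure(list(snp_id = snp_id, n_paternal = n_paternal,
                 n_maternal = n_maternal, n_informative = n, p = p),
            class = "pat_result")
}

#' @export
print.pat_result <- function(x, ...) {
  cat(sprintf("PAT %s: paternal %d vs maternal %d (n = %d), p = %.4g\n",
              if (is.na(x$snp_id)) "" else x$snp_id,
              x$n_paternal, x$n_maternal, x$n_informative, x$p))
  invisible(x)
}

#' PAT across all SNPs of a trio dataset
#'
#' Identifies case-parent trios in the pedigree (individuals with both
#' parents recorded), restricts to affected offspring (all offspring are
#' assumed affected when no affection status is recorded, the usual
#' situation for trios ascertained on an affected child), counts
#' transmissions of the designated allele per SNP and applies
#' [pat_binomial()].
#'
#' @param ped Pedigree containing the trios.
#' @param g A `genotype_matrix` for parents and children.
#' @param allele `"major"` (default) or `"minor"`: which allele's
#'   transmissions are counted. The p-value is invariant to this choice;
#'   the paternal/maternal counts swap.
#' @return `data.frame` with one row per SNP: `snp_id`, `allele_counted`,
#'   `n_paternal`, `n_maternal`, `n_informative`, `p` (`NA` with zero
#'   informative trios).
#' @export
pat_table <- function(ped, g, allele = c("major", "minor")) {
  allele <- match.arg(allele)
  kids <- ped[!is.na(ped$father) & !is.na(ped$mother), , drop = FALSE]
  if (!is.null(kids$affected)) {
    kids <- kids[is.na(kids$affected) | kids$affected == 1L, , drop = FALSE]
  }
  ci <- match(kids$iid, g$samples)
  fi <- match(kids$father, g$samples)
  mi <- match(kids$mother, g$samples)
  keep <- !is.na(ci) & !is.na(fi) & !is.na(mi)
  ci <- ci[keep]; fi <- fi[keep]; mi <- mi[keep]
  if (length(ci) == 0L) stop("no genotyped case-parent trios found")
  out <- lapply(seq_len(nrow(g$variants)), function(v) {
    d <- g$dosage[, v]
    if (allele == "major") d <- 2L - d     # dosage counts the minor allele
    al <- if (allele == "major") g$variants$major_allele[v]
          else g$variants$minor_allele[v]
    tc <- count_transmissions(d[fi], d[mi], d[ci],
                              snp_id = g$variants$snp_id[v],
                              allele_counted = al)
    n <- tc$n_paternal + tc$n_maternal
    data.frame(snp_id = tc$snp_id, allele_counted = al,
               n_paternal = tc$n_paternal, n_maternal = tc$n_maternal,
               n_informative = n,
               p = if (n >= 1L) pat_binomial(tc)$p else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
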