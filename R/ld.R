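#' Pairwise linkage disequilibrium r-squared from phased haplotypes
#'
#' Because phase is known, r2 is computed by direct haplotype counting:
#' paternal and maternal haplotypes of origin-eligible samples are pooled,
#' haplotypes with either site unresolved are dropped pairwise, and
#' `r2 = D^2 / (pA pa pB pb)` with `D = pAB - pA pB`.
#'
#' @param ph A `phased_genotypes`.
#' @param v1,v2 Variant indices or snp ids.
#' @return r2 in `[0, 1]`, or `NA` (with a warning) when either variant is
#'   monomorphic among the jointly resolved haplotypes.
#' @export
haplotype_r2 <- function(ph, v1, v2) {
  idx <- function(v) {
    if (is.character(v)) v <- match(v, ph$variants$snp_id)
    if (is.na(v)) stop("unknown variant")
    v
  }
  v1 <- idx(v1); v2 <- idx(v2)
  el <- ph$eligible
  h1 <- c(ph$paternal[el, v1], ph$maternal[el, v1])
  h2 <- c(ph$paternal[el, v2], ph$maternal[el, v2])
  ok <- !is.na(h1) & !is.na(h2)
  h1 <- h1[ok]; h2 <- h2[ok]
  if (length(h1) == 0L) {
    warning("no jointly resolved haplotypes")
    return(NA_real_)
  }
  pA <- mean(h1); pB <- mean(h2)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    warning("monomorphic variant among resolved haplotypes; r2 undefined")
    return(NA_real_)
  }
  D <- mean(h1 == 1L & h2 == 1L) - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Full pairwise r-squared matrix
#'
#' @param ph A `phased_genotypes`.
#' @return Symmetric matrix of r2 values with unit diagonal for polymorphic
#'   variants; undefined pairs are `NA`.
#' @export
ld_matrix <- function(ph) {
  nv <- nrow(ph$variants)
  r2 <- matrix(NA_real_, nv, nv,
               dimnames = list(ph$variants$snp_id, ph$variants$snp_id))
  for (i in seq_len(nv)) {
    for (j in i:nv) {
      val <- suppressWarnings(haplotype_r2(ph, i, j))
      r2[i, j] <- r2[j, i] <- val
    }
  }
  r2
}
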