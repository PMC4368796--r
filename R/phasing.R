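#' Construct a phased-genotypes container
#'
#' @param paternal,maternal Samples x variants matrices of alleles in
#'   `{0, 1, NA}` (1 = the variant's dosage-counted allele).
#' @param phase_source Character matrix of per-cell tags: `"homozygote"`,
#'   `"trio-forced"`, `"propagated"`, `"external"` or `"unresolved"`.
#' @param variants Variant table as in [new_genotype_matrix()].
#' @param samples Sample keys.
#' @param eligible Logical per sample: `TRUE` for individuals whose allele
#'   origins can in principle be assigned (non-founders). Founders keep
#'   `NA` alleles and are excluded from phasing-rate denominators.
#' @return Object of class `"phased_genotypes"`.
#' @export
new_phased_genotypes <- function(paternal, maternal, phase_source, variants,
                                 samples, eligible) {
  dimnames(paternal) <- dimnames(maternal) <- dimnames(phase_source) <-
    list(samples, variants$snp_id)
  structure(list(paternal = paternal, maternal = maternal,
                 phase_source = phase_source, variants = variants,
                 samples = as.character(samples),
                 eligible = as.logical(eligible)),
            class = "phased_genotypes")
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat("phased_genotypes:", length(x$samples), "samples (",
      sum(x$eligible), "origin-eligible ) x", nrow(x$variants), "variants\n")
  cat("mean unphased rate among eligible:",
      round(mean(phasing_missing_rate(x)), 3), "\n")
  invisible(x)
}

# Ordered-pair encoding used by the propagation: columns of the possibility
# matrix are (paternal, maternal) = (0,0), (0,1), (1,0), (1,1).
.pair_sum <- c(0L, 1L, 1L, 2L)
.pair_pat <- c(0L, 0L, 1L, 1L)
.pair_mat <- c(0L, 1L, 0L, 1L)

# Alleles an individual can transmit, given its remaining ordered pairs.
.carriage <- function(possrow) {
  c(any(possrow & (.pair_pat == 0L | .pair_mat == 0L)),
    any(possrow & (.pair_pat == 1L | .pair_mat == 1L)))
}

# Fixpoint propagation for one family at one variant.
# d: member dosages (NA = untyped); fa, mo: member indices of parents (NA
# if that parent is unrecorded). Returns list(poss, inconsistent).
.phase_family_variant <- function(d, fa, mo) {
  n <- length(d)
  poss <- matrix(TRUE, n, 4L)
  for (i in seq_len(n)) {
    if (!is.na(d[i])) poss[i, ] <- .pair_sum == d[i]
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      # restrict child by each recorded parent's transmissible alleles
      if (!is.na(fa[i])) {
        tf <- .carriage(poss[fa[i], ])
        keep <- poss[i, ] & tf[.pair_pat + 1L]
        if (!identical(keep, poss[i, ])) { poss[i, ] <- keep; changed <- TRUE }
      }
      if (!is.na(mo[i])) {
        tm <- .carriage(poss[mo[i], ])
        keep <- poss[i, ] & tm[.pair_mat + 1L]
        if (!identical(keep, poss[i, ])) { poss[i, ] <- keep; changed <- TRUE }
      }
      if (!any(poss[i, ])) return(list(poss = poss, inconsistent = TRUE))
      # feed back: each parent must be able to supply one of the child's
      # remaining alleles on the corresponding side
      opts_p <- unique(.pair_pat[poss[i, ]])
      opts_m <- unique(.pair_mat[poss[i, ]])
      if (!is.na(fa[i])) {
        keep <- poss[fa[i], ] &
          ((.pair_pat[] %in% opts_p) | (.pair_mat[] %in% opts_p))
        if (!identical(keep, poss[fa[i], ])) {
          poss[fa[i], ] <- keep; changed <- TRUE
          if (!any(keep)) return(list(poss = poss, inconsistent = TRUE))
        }
      }
      if (!is.na(mo[i])) {
        keep <- poss[mo[i], ] &
          ((.pair_pat[] %in% opts_m) | (.pair_mat[] %in% opts_m))
        if (!identical(keep, poss[mo[i], ])) {
          poss[mo[i], ] <- keep; changed <- TRUE
          if (!any(keep)) return(list(poss = poss, inconsistent = TRUE))
        }
      }
    }
    if (!changed) break
  }
  list(poss = poss, inconsistent = FALSE)
}

#' Assign parental origin to alleles by Mendelian constraint propagation
#'
#' Deterministic single-marker phaser. Per variant and family, each
#' individual's ordered (paternal, maternal) allele pair is restricted to a
#' fixpoint under the Mendelian rules: homozygotes are phased outright; a
#' child's allele is forced when the corresponding parent's transmissible
#' alleles are unique (parent homozygous, or the parent's own genotype
#' inferred through its relatives); a resolved child allele feeds back into
#' the parent's possible genotypes. Sites still ambiguous at the fixpoint
#' (canonically a child-father-mother heterozygous triple with no outside
#' information) remain unresolved — the phaser never guesses, so every
#' assigned allele is implied by the observed genotypes.
#'
#' Ungenotyped pedigree members participate in propagation with unknown
#' genotype, so e.g. homozygous grandparents can determine an untyped
#' parent's transmission. Founders (no recorded parents) have no origin to
#' assign: their cells stay `NA` and they are excluded from phasing-rate
#' denominators, though they constrain their descendants.
#'
#' Mendelian inconsistencies (e.g. child dosage 2 with a dosage-0 parent)
#' are not fatal: the family's cells at that variant are set unresolved and
#' the event is recorded in the `"mendel_errors"` attribute.
#'
#' @param ped A pedigree covering every genotyped sample.
#' @param g A `genotype_matrix`.
#' @return A `phased_genotypes` for `g`'s samples; wherever both alleles
#'   are non-missing they sum to the observed dosage.
#' @examples
#' ped <- read_pedigree(c("F1 f 0 0 1", "F1 m 0 0 2", "F1 k f m 1"))
#' g <- read_genotypes(c("F1 f 0 0 1 -9 A A", "F1 m 0 0 2 -9 G G",
#'                       "F1 k f m 1 -9 A G"), "1 rs1 0 100")
#' ph <- phase_pedigree(ped, g)
#' ph$paternal["k", ]   # minor-allele copy from the father
#' @export
phase_pedigree <- function(ped, g) {
  if (!all(g$samples %in% ped$iid))
    stop("samples absent from pedigree: ",
         paste(setdiff(g$samples, ped$iid), collapse = ", "))
  ns <- length(g$samples); nv <- nrow(g$variants)
  pat <- mat <- matrix(NA_integer_, ns, nv)
  src <- matrix("unresolved", ns, nv)
  mendel <- list()

  for (f in unique(ped$fid)) {
    rows <- which(ped$fid == f)
    ids <- ped$iid[rows]
    fa <- match(ped$father[rows], ids)
    mo <- match(ped$mother[rows], ids)
    gidx <- match(ids, g$samples)            # NA for untyped members
    nonf <- !(is.na(fa) & is.na(mo))
    out <- which(!is.na(gidx) & nonf)        # members receiving output
    if (length(out) == 0L) next
    for (v in seq_len(nv)) {
      d <- rep(NA_integer_, length(ids))
      d[!is.na(gidx)] <- g$dosage[gidx[!is.na(gidx)], v]
      res <- .phase_family_variant(d, fa, mo)
      if (res$inconsistent) {
        mendel[[length(mendel) + 1L]] <-
          data.frame(fid = f, snp_id = g$variants$snp_id[v],
                     stringsAsFactors = FALSE)
        next
      }
      for (i in out) {
        pp <- unique(.pair_pat[res$poss[i, ]])
        mm <- unique(.pair_mat[res$poss[i, ]])
        si <- gidx[i]
        if (length(pp) == 1L) pat[si, v] <- pp
        if (length(mm) == 1L) mat[si, v] <- mm
        if (length(pp) == 1L && length(mm) == 1L) {
          if (!is.na(d[i]) && d[i] %in% c(0L, 2L)) {
            src[si, v] <- "homozygote"
          } else {
            fhom <- !is.na(fa[i]) && !is.na(d[fa[i]]) && d[fa[i]] %in% c(0L, 2L)
            mhom <- !is.na(mo[i]) && !is.na(d[mo[i]]) && d[mo[i]] %in% c(0L, 2L)
            src[si, v] <- if (fhom || mhom) "trio-forced" else "propagated"
          }
        }
      }
    }
  }
  ph <- new_phased_genotypes(pat, mat, src, g$variants, g$samples,
                             eligible = .phase_eligible(ped, g$samples))
  attr(ph, "mendel_errors") <- if (length(mendel)) do.call(rbind, mendel)
    else data.frame(fid = character(), snp_id = character())
  ph
}

.phase_eligible <- function(ped, samples) {
  m <- match(samples, ped$iid)
  !(is.na(ped$father[m]) & is.na(ped$mother[m]))
}

#' Per-variant unphased rate
#'
#' Fraction of origin-eligible (non-founder) samples whose phase at a
#' variant is unresolved (at least one of the two alleles missing).
#'
#' @param ph A `phased_genotypes`.
#' @param v Variant index/indices; default all.
#' @return Numeric vector of unphased fractions.
#' @export
phasing_missing_rate <- function(ph, v = seq_len(nrow(ph$variants))) {
  el <- ph$eligible
  if (!any(el)) stop("no origin-eligible samples")
  un <- is.na(ph$paternal[el, v, drop = FALSE]) |
        is.na(ph$maternal[el, v, drop = FALSE])
  colMeans(un)
}

#' Drop variants with high unphased rate
#'
#' Variants whose unphased rate is greater than or equal to `threshold`
#' (note: inclusive bound) are removed.
#'
#' @param ph A `phased_genotypes`.
#' @param threshold Exclusion bound on the unphased rate (default 0.30).
#' @return `list(phased = filtered phased_genotypes, report = data.frame)`
#'   with report columns `snp_id`, `unphased_rate`, `excluded`, plus an
#'   attribute `"mean_phasing_rate"` (mean per-variant resolution rate over
#'   all input variants).
#' @export
filter_unphased <- function(ph, threshold = 0.30) {
  rate <- phasing_missing_rate(ph)
  excl <- rate >= threshold
  report <- data.frame(snp_id = ph$variants$snp_id, unphased_rate = rate,
                       excluded = excl, stringsAsFactors = FALSE,
                       row.names = NULL)
  attr(report, "mean_phasing_rate") <- mean(1 - rate)
  keep <- !excl
  out <- new_phased_genotypes(ph$paternal[, keep, drop = FALSE],
                              ph$maternal[, keep, drop = FALSE],
                              ph$phase_source[, keep, drop = FALSE],
                              ph$variants[keep, , drop = FALSE],
                              ph$samples, ph$eligible)
  list(phased = out, report = report)
}
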