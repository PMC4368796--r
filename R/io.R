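#' Read a pedigree from FAM-dialect text
#'
#' Parses whitespace-delimited pedigree lines with at least five columns
#' (family id, individual id, father id, mother id, sex), the PLINK FAM
#' dialect. A sixth column, when present, is read as affection status
#' (1 = unaffected, 2 = affected, anything else missing). The missing code
#' for parent ids is `"0"`.
#'
#' @param x File path, a single string with newlines, or a character vector
#'   of lines.
#' @param strict When `TRUE` (default), parent references must resolve to
#'   an individual in the same family; `FALSE` tolerates references to
#'   ungenotyped/unlisted parents, as PED genotype rows may.
#' @return A `data.frame` of class `"pedigree"` with columns `fid`, `iid`,
#'   `father`, `mother` (`NA` where missing), `sex`
#'   (`"male"`/`"female"`/`"unknown"`), `affected` (0/1/`NA`) and `founder`.
#' @details Individual ids must be unique within a family; parent references
#'   must resolve within the same family or be missing; the parent graph must
#'   be acyclic. Violations are errors naming the offending id.
#' @examples
#' ped <- read_pedigree(c("F1 dad 0 0 1", "F1 mom 0 0 2", "F1 kid dad mom 1"))
#' ped$founder
#' @export
read_pedigree <- function(x, strict = TRUE) {
  fields <- .split_ws(.as_lines(x))
  if (length(fields) == 0L) stop("empty pedigree input")
  ncols <- lengths(fields)
  if (any(ncols < 5L))
    stop("pedigree line ", which(ncols < 5L)[1L], " has fewer than 5 columns")
  fid <- vapply(fields, `[`, "", 1L)
  iid <- vapply(fields, `[`, "", 2L)
  father <- vapply(fields, `[`, "", 3L)
  mother <- vapply(fields, `[`, "", 4L)
  sexc <- vapply(fields, `[`, "", 5L)
  affc <- vapply(fields, function(f) if (length(f) >= 6L) f[6L] else NA_character_, "")

  key <- paste(fid, iid)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate individual id in pedigree: ", d)
  }
  father[father == "0"] <- NA_character_
  mother[mother == "0"] <- NA_character_
  sex <- ifelse(sexc == "1", "male", ifelse(sexc == "2", "female", "unknown"))
  affected <- ifelse(is.na(affc), NA, ifelse(affc == "2", 1L,
                     ifelse(affc == "1", 0L, NA)))

  ped <- data.frame(fid = fid, iid = iid, father = father, mother = mother,
                    sex = sex, affected = as.integer(affected),
                    stringsAsFactors = FALSE)
  ped$founder <- is.na(ped$father) & is.na(ped$mother)

  # per-family validation: parent refs resolve, graph acyclic
  for (f in unique(ped$fid)) {
    idx <- which(ped$fid == f)
    ids <- ped$iid[idx]
    if (strict) {
      for (col in c("father", "mother")) {
        ref <- ped[[col]][idx]
        bad <- !is.na(ref) & !(ref %in% ids)
        if (any(bad))
          stop("parent id '", ref[bad][1L], "' referenced in family ", f,
               " but not present")
      }
    }
    # topological elimination; leftover individuals lie on a cycle
    remaining <- ids
    repeat {
      fa <- ped$father[idx][match(remaining, ids)]
      mo <- ped$mother[idx][match(remaining, ids)]
      free <- (is.na(fa) | !(fa %in% remaining)) &
              (is.na(mo) | !(mo %in% remaining))
      if (all(free)) break
      if (!any(free))
        stop("pedigree cycle detected in family ", f, " involving: ",
             paste(remaining, collapse = ", "))
      remaining <- remaining[!free]
      if (length(remaining) == 0L) break
    }
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Write a pedigree as FAM-dialect lines
#'
#' @param ped A pedigree from [read_pedigree()] or the simulator.
#' @return Character vector of FAM lines (missing codes `"0"`, affection
#'   1/2 with `"0"` for unknown).
#' @export
write_pedigree <- function(ped) {
  sexc <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  affc <- ifelse(is.na(ped$affected), "0", ifelse(ped$affected == 1L, "2", "1"))
  paste(ped$fid, ped$iid,
        ifelse(is.na(ped$father), "0", ped$father),
        ifelse(is.na(ped$mother), "0", ped$mother),
        sexc, affc)
}

#' Construct a genotype matrix container
#'
#' @param dosage Integer matrix, samples x variants, entries 0/1/2/`NA`,
#'   counting copies of each variant's minor allele.
#' @param variants `data.frame` with columns `snp_id`, `chrom`, `pos`,
#'   `allele1`, `allele2`, `minor_allele`, `major_allele`.
#' @param samples Character vector of sample keys (row order of `dosage`).
#' @return Object of class `"genotype_matrix"`.
#' @export
new_genotype_matrix <- function(dosage, variants, samples = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(samples)) stop("sample keys required")
  stopifnot(nrow(dosage) == length(samples), ncol(dosage) == nrow(variants))
  ok <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
  if (!all(ok)) stop("dosage entries must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(samples, variants$snp_id)
  structure(list(dosage = dosage, variants = variants,
                 samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$samples), nrow(x$variants))

#' Subset a genotype matrix by variant
#'
#' @param g A `genotype_matrix`.
#' @param keep Logical or integer index over variants.
#' @return A `genotype_matrix` restricted to the kept variants.
#' @export
subset_variants <- function(g, keep) {
  new_genotype_matrix(g$dosage[, keep, drop = FALSE],
                      g$variants[keep, , drop = FALSE], g$samples)
}

#' Read genotypes from PED/MAP-dialect text
#'
#' PED rows carry six leading columns (family, individual, father, mother,
#' sex, phenotype) followed by two allele columns per variant; MAP rows carry
#' chromosome, snp id, optional genetic distance, and 1-based position.
#' The missing allele code is `"0"`. Dosages count the minor allele as
#' determined from the observed allele frequencies; frequency ties are broken
#' by lexicographic order of the allele symbol (recorded in the `maf_tie`
#' variant column).
#'
#' @param ped_text,map_text File path or lines (see [read_pedigree()]).
#' @return A `genotype_matrix`; the six leading PED columns are attached as
#'   a `"pedigree"` attribute parsed with [read_pedigree()].
#' @examples
#' map <- "1 rs1 0 100"
#' ped <- c("F1 a 0 0 1 -9 A A", "F1 b 0 0 2 -9 A G")
#' g <- read_genotypes(ped, map)
#' g$dosage
#' @export
read_genotypes <- function(ped_text, map_text) {
  mfields <- .split_ws(.as_lines(map_text))
  mlen <- lengths(mfields)
  if (any(mlen < 3L | mlen > 4L))
    stop("MAP line ", which(mlen < 3L | mlen > 4L)[1L],
         " must have 3 or 4 columns")
  chrom <- vapply(mfields, `[`, "", 1L)
  snp_id <- vapply(mfields, `[`, "", 2L)
  pos <- as.integer(vapply(mfields, function(f) f[length(f)], ""))
  if (anyNA(pos) || any(pos < 1L)) stop("MAP positions must be integers >= 1")
  nv <- length(snp_id)

  pfields <- .split_ws(.as_lines(ped_text))
  plen <- lengths(pfields)
  bad <- plen != 6L + 2L * nv
  if (any(bad))
    stop("PED row ", which(bad)[1L], " has ", plen[which(bad)[1L]],
         " columns; expected ", 6L + 2L * nv)
  ns <- length(pfields)
  lead <- t(vapply(pfields, `[`, character(6L), 1:6))
  ped <- read_pedigree(apply(lead, 1L, paste, collapse = " "), strict = FALSE)
  samples <- ped$iid
  if (anyDuplicated(samples))
    stop("duplicate individual id across PED rows: ",
         samples[duplicated(samples)][1L])

  a1 <- matrix("", ns, nv); a2 <- matrix("", ns, nv)
  for (i in seq_len(ns)) {
    al <- toupper(pfields[[i]][-(1:6)])
    a1[i, ] <- al[seq(1L, 2L * nv, by = 2L)]
    a2[i, ] <- al[seq(2L, 2L * nv, by = 2L)]
  }
  valid <- c("A", "C", "G", "T", "0")
  badm <- matrix(!(a1 %in% valid), ns, nv) | matrix(!(a2 %in% valid), ns, nv)
  if (any(badm)) {
    bad <- which(badm, arr.ind = TRUE)[1L, ]
    sym <- c(a1[bad[1L], bad[2L]], a2[bad[1L], bad[2L]])
    stop("non-ACGT allele symbol '", sym[!(sym %in% valid)][1L],
         "' at PED row ", bad[1L], ", variant ", bad[2L])
  }

  dosage <- matrix(NA_integer_, ns, nv)
  allele1 <- allele2 <- minor <- major <- rep(NA_character_, nv)
  tie <- logical(nv)
  for (v in seq_len(nv)) {
    av <- c(a1[, v], a2[, v])
    miss <- a1[, v] == "0" | a2[, v] == "0"   # half-calls treated as missing
    obs <- c(a1[!miss, v], a2[!miss, v])
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L)
      stop("variant ", snp_id[v], " has more than two alleles: ",
           paste(alleles, collapse = ","))
    if (length(alleles) >= 1L) allele1[v] <- alleles[1L]
    if (length(alleles) == 2L) allele2[v] <- alleles[2L]
    if (length(alleles) == 2L) {
      n1 <- sum(obs == alleles[1L]); n2 <- sum(obs == alleles[2L])
      tie[v] <- n1 == n2
      minor[v] <- if (n1 <= n2) alleles[1L] else alleles[2L]
      major[v] <- setdiff(alleles, minor[v])
    } else if (length(alleles) == 1L) {
      major[v] <- alleles[1L]          # monomorphic: minor unobserved
    }
    d <- rep(NA_integer_, ns)
    if (!is.na(minor[v])) {
      d[!miss] <- (a1[!miss, v] == minor[v]) + (a2[!miss, v] == minor[v])
    } else {
      d[!miss] <- 0L
    }
    dosage[, v] <- d
  }

  variants <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                         allele1 = allele1, allele2 = allele2,
                         minor_allele = minor, major_allele = major,
                         maf_tie = tie, stringsAsFactors = FALSE)
  g <- new_genotype_matrix(dosage, variants, samples)
  attr(g, "pedigree") <- ped
  g
}

#' Write genotypes as PED/MAP-dialect lines
#'
#' Heterozygotes are emitted in alphabetical allele order; missing dosage as
#' `"0 0"`. Reading the result back with [read_genotypes()] reproduces the
#' dosage matrix.
#'
#' @param g A `genotype_matrix`.
#' @param ped Optional pedigree supplying the six leading PED columns; by
#'   default the `"pedigree"` attribute is used, else singleton families.
#' @return `list(ped = lines, map = lines)`.
#' @export
write_genotypes <- function(g, ped = attr(g, "pedigree")) {
  v <- g$variants
  map <- paste(v$chrom, v$snp_id, 0, v$pos)
  if (is.null(ped)) {
    lead <- paste(g$samples, g$samples, "0 0 0 -9")
  } else {
    lead <- write_pedigree(ped)[match(g$samples, ped$iid)]
  }
  ns <- length(g$samples)
  geno <- character(ns)
  for (i in seq_len(ns)) {
    pair <- vapply(seq_len(nrow(v)), function(j) {
      d <- g$dosage[i, j]
      if (is.na(d)) return("0 0")
      mi <- v$minor_allele[j]; ma <- v$major_allele[j]
      if (is.na(mi)) mi <- "0"
      switch(as.character(d),
             "0" = paste(ma, ma),
             "1" = paste(sort(c(mi, ma)), collapse = " "),
             "2" = paste(mi, mi))
    }, "")
    geno[i] <- paste(pair, collapse = " ")
  }
  list(ped = paste(lead, geno), map = map)
}

#' Read a phenotype/covariate table
#'
#' Tab- or whitespace-separated text with a header naming an id column
#' (`iid`, or the first column) plus `bmi` (kg/m^2), `age` (years), `sex`
#' (1/2 or male/female), `t2d` (0/1) and optionally `affected` (0/1).
#' Missing codes `NA` and `-9` are accepted. Rows with unparseable or
#' invalid values (e.g. non-positive BMI, unknown sex code) are flagged and
#' returned via the `"flagged"` attribute rather than silently dropped.
#'
#' @param x File path or lines.
#' @return `data.frame` of valid rows with columns `iid`, `bmi`, `age`,
#'   `sex` (integer 1 = male, 2 = female), `t2d`, and `affected` when
#'   present; attribute `"flagged"` is a `data.frame(row, iid, reason)`.
#' @export
read_phenotypes <- function(x) {
  lines <- .as_lines(x)
  fields <- .split_ws(lines)
  if (length(fields) < 1L) stop("empty phenotype input")
  header <- tolower(fields[[1L]])
  body <- fields[-1L]
  idcol <- if ("iid" %in% header) match("iid", header) else 1L
  need <- c("bmi", "age", "sex", "t2d")
  if (!all(need %in% header))
    stop("phenotype header must name columns: ",
         paste(setdiff(need, header), collapse = ", "))
  getcol <- function(f, name) f[match(name, header)]
  num <- function(s) {
    if (is.na(s) || s %in% c("NA", "-9", ".")) return(NA_real_)
    suppressWarnings(as.numeric(s))
  }
  rows <- vector("list", length(body))
  flags <- list()
  for (i in seq_along(body)) {
    f <- body[[i]]
    if (length(f) < length(header)) {
      flags[[length(flags) + 1L]] <- data.frame(row = i, iid = f[idcol],
                                                reason = "too few columns")
      next
    }
    iid <- f[idcol]
    bmi <- num(getcol(f, "bmi")); age <- num(getcol(f, "age"))
    t2d <- num(getcol(f, "t2d"))
    sexs <- tolower(getcol(f, "sex"))
    sex <- if (sexs %in% c("1", "m", "male")) 1L
           else if (sexs %in% c("2", "f", "female")) 2L
           else if (sexs %in% c("na", "-9", "0", ".")) NA_integer_
           else -1L
    reason <- NULL
    if (!is.na(bmi) && bmi <= 0) reason <- "non-positive bmi"
    if (is.na(bmi) && !(getcol(f, "bmi") %in% c("NA", "-9", ".")))
      reason <- "unparseable bmi"
    if (identical(sex, -1L)) reason <- paste0("unknown sex code '", sexs, "'")
    if (!is.na(age) && age < 0) reason <- "negative age"
    if (!is.na(t2d) && !(t2d %in% c(0, 1))) reason <- "t2d not 0/1"
    if (!is.null(reason)) {
      flags[[length(flags) + 1L]] <- data.frame(row = i, iid = iid,
                                                reason = reason)
      next
    }
    row <- data.frame(iid = iid, bmi = bmi, age = age, sex = sex,
                      t2d = as.integer(t2d), stringsAsFactors = FALSE)
    if ("affected" %in% header) row$affected <- as.integer(num(getcol(f, "affected")))
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) out <- data.frame(iid = character(), bmi = numeric(),
                                      age = numeric(), sex = integer(),
                                      t2d = integer())
  attr(out, "flagged") <- if (length(flags)) do.call(rbind, flags)
                          else data.frame(row = integer(), iid = character(),
                                          reason = character())
  out
}

#' Write phased genotypes as a VCF with origin-ordered GT
#'
#' Emits a minimal VCFv4.2 with the major allele as REF, minor as ALT, and
#' `GT` phased as `paternal|maternal` (1 = minor allele); unresolved or
#' origin-unassigned cells become `.|.`.
#'
#' @param ph A `phased_genotypes` object.
#' @param path Optional output path; when `NULL` the lines are returned.
#' @return Character vector of VCF lines (invisibly when written to `path`).
#' @export
write_phased_vcf <- function(ph, path = NULL) {
  v <- ph$variants
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype, paternal|maternal\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ph$samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(j) {
    gt <- ifelse(is.na(ph$paternal[, j]) | is.na(ph$maternal[, j]), ".|.",
                 paste0(ph$paternal[, j], "|", ph$maternal[, j]))
    paste(c(v$chrom[j], v$pos[j], v$snp_id[j],
            ifelse(is.na(v$major_allele[j]), "N", v$major_allele[j]),
            ifelse(is.na(v$minor_allele[j]), "N", v$minor_allele[j]),
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, "")
  lines <- c(hdr, body)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read pre-phased genotypes from a VCF
#'
#' Accepts a VCF whose `GT` fields are phased with `|`, interpreted in this
#' pipeline's convention as `paternal|maternal` with 1 counting the ALT
#' allele. Such input bypasses [phase_pedigree()]. All samples are treated
#' as origin-assigned (`eligible`), since founder status is not encoded in
#' VCF; resolved cells carry the phase-source tag `"external"`.
#'
#' @param path Path to an uncompressed or bgzipped VCF file.
#' @return A `phased_genotypes` object.
#' @export
read_phased_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  samples <- colnames(gt)
  nv <- nrow(gt)
  unphased <- !is.na(gt) & grepl("/", gt, fixed = TRUE)
  if (any(unphased)) stop("unphased '/' GT encountered; phased '|' required")
  pat <- mat <- matrix(NA_integer_, length(samples), nv)
  for (j in seq_len(nv)) {
    parts <- strsplit(ifelse(is.na(gt[j, ]), ".|.", gt[j, ]), "|", fixed = TRUE)
    p1 <- vapply(parts, `[`, "", 1L); p2 <- vapply(parts, `[`, "", 2L)
    pat[, j] <- suppressWarnings(as.integer(p1))
    mat[, j] <- suppressWarnings(as.integer(p2))
  }
  variants <- data.frame(snp_id = ifelse(is.na(fix[, "ID"]),
                                         paste0("var", seq_len(nv)), fix[, "ID"]),
                         chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                         allele1 = fix[, "REF"], allele2 = fix[, "ALT"],
                         minor_allele = fix[, "ALT"], major_allele = fix[, "REF"],
                         maf_tie = FALSE, stringsAsFactors = FALSE)
  src <- matrix(ifelse(is.na(pat) | is.na(mat), "unresolved", "external"),
                length(samples), nv)
  new_phased_genotypes(pat, mat, src, variants, samples,
                       eligible = rep(TRUE, length(samples)))
}
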