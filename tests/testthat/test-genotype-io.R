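test_that("a minimal trio pedigree parses with founder status", {
  ped <- read_pedigree(c("F1 dad 0 0 1", "F1 mom 0 0 2", "F1 kid dad mom 1"))
  expect_equal(nrow(ped), 3L)
  expect_equal(ped$founder, c(TRUE, TRUE, FALSE))
  expect_equal(ped$sex, c("male", "female", "male"))
  expect_true(is.na(ped$father[1]))
})

test_that("pedigree structural violations are errors naming the culprit", {
  expect_error(read_pedigree("F1 kid kid mom 1"), "cycle|not present")
  expect_error(read_pedigree(c("F1 a b 0 1", "F1 b a 0 1")), "cycle")
  expect_error(read_pedigree(c("F1 x 0 0 1", "F1 x 0 0 2")), "duplicate.*x")
  expect_error(read_pedigree(c("F1 kid dad 0 1")), "dad")
  expect_error(read_pedigree("F1 kid 0 0"), "fewer than 5")
})

test_that("pedigree write-read round-trips modulo whitespace", {
  lines <- c("F1  dad 0 0 1", "F1 mom 0 0 2", "F1\tkid dad mom 2")
  ped <- read_pedigree(lines)
  expect_identical(read_pedigree(write_pedigree(ped)), ped)
})

test_that("dosage counts the data-determined minor allele", {
  # alleles observed {A:6, G:2} over 4 samples -> minor G
  ped <- c("F1 a 0 0 1 -9 A A", "F1 b 0 0 1 -9 A A",
           "F1 c 0 0 1 -9 A G", "F1 d 0 0 1 -9 G G")
  g <- read_genotypes(ped, "1 rs1 0 100")
  expect_equal(g$variants$minor_allele, "G")
  expect_equal(unname(g$dosage[, 1]), c(0L, 0L, 1L, 2L))
  # missing allele pair -> NA dosage
  g2 <- read_genotypes(c(ped[1:3], "F1 d 0 0 1 -9 0 0"), "1 rs1 0 100")
  expect_true(is.na(g2$dosage["d", 1]))
})

test_that("a 4-sample 2-variant fixture matches the hand-computed table", {
  ped <- c("F1 a 0 0 1 -9 A A C C", "F1 b 0 0 1 -9 A G C T",
           "F1 c 0 0 2 -9 G G T T", "F1 d 0 0 2 -9 A G 0 0")
  g <- read_genotypes(ped, c("1 rs1 0 100", "1 rs2 0 200"))
  # rs1: A x4, G x4 tie -> lexicographic A; rs2: C x3, T x3 tie -> C
  expect_equal(g$variants$minor_allele, c("A", "C"))
  expect_true(all(g$variants$maf_tie))
  expect_equal(unname(g$dosage),
               matrix(c(2L, 1L, 0L, 1L, 2L, 1L, 0L, NA), 4, 2))
})

test_that("malformed PED/MAP input is rejected with position information", {
  expect_error(read_genotypes("F1 a 0 0 1 -9 A", "1 rs1 0 100"),
               "row 1.*expected 8")
  expect_error(read_genotypes("F1 a 0 0 1 -9 A X", "1 rs1 0 100"),
               "non-ACGT.*X")
  expect_error(read_genotypes("F1 a 0 0 1 -9 A A", "1 rs1"), "3 or 4")
})

test_that("genotype write-read round-trips and re-polarization complements dosage", {
  set.seed(5)
  d <- matrix(sample(c(0:2, NA), 40, replace = TRUE), 10, 4)
  g <- make_gmat(d)
  out <- write_genotypes(g)
  g2 <- read_genotypes(out$ped, out$map)
  # where polymorphic, dosage is recovered up to global allele polarity
  for (v in 1:4) {
    a <- g$dosage[, v]; b <- g2$dosage[, v]
    expect_true(isTRUE(all.equal(a, b)) || isTRUE(all.equal(a, 2L - b)))
    if (!isTRUE(all.equal(a, b))) {
      # flipped polarity: complement holds at every non-missing entry
      expect_equal(unname(a[!is.na(a)] + b[!is.na(b)]),
                   rep(2L, sum(!is.na(a))))
    }
  }
})

test_that("phenotype rows are typed and bad rows flagged, not dropped silently", {
  tsv <- c("iid bmi age sex t2d",
           "kid 26.1 45 1 0",
           "a 31.5 60 2 1",
           "b -1 50 1 0",
           "c 24.0 40 3 0",
           "d NA 33 2 0")
  ph <- read_phenotypes(tsv)
  expect_equal(nrow(ph), 3L)
  expect_equal(ph$bmi[ph$iid == "kid"], 26.1)
  expect_equal(ph$age[ph$iid == "kid"], 45)
  fl <- attr(ph, "flagged")
  expect_equal(nrow(fl), 2L)
  expect_match(fl$reason[fl$iid == "b"], "non-positive bmi")
  expect_match(fl$reason[fl$iid == "c"], "sex")
})

test_that("phased VCF round-trips the origin-ordered haplotypes", {
  pat <- matrix(c(1L, 0L, NA, 0L, 1L, 1L), 3, 2)
  mat <- matrix(c(0L, 0L, NA, 1L, 1L, 0L), 3, 2)
  ph <- make_phased(pat, mat)
  path <- tempfile(fileext = ".vcf")
  write_phased_vcf(ph, path)
  ph2 <- read_phased_vcf(path)
  expect_equal(unname(ph2$paternal), unname(pat))
  expect_equal(unname(ph2$maternal), unname(mat))
  expect_equal(ph2$samples, ph$samples)
  unlink(path)
})
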