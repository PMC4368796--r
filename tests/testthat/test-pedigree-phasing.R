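test_that("forced transmissions and homozygotes phase in a trio", {
  ped <- trio_ped()
  # father hom minor (AA), mother hom major (GG), child het
  ph <- phase_pedigree(ped, trio_geno("A A", "G G", "A G"))
  expect_equal(ph$paternal["k", 1], 1L)
  expect_equal(ph$maternal["k", 1], 0L)
  expect_equal(ph$phase_source["k", 1], "trio-forced")
  # homozygous child phases regardless of parents
  ph2 <- phase_pedigree(ped, trio_geno("A G", "A G", "G G"))
  expect_equal(ph2$paternal["k", 1] + ph2$maternal["k", 1], 0L)
  expect_equal(ph2$phase_source["k", 1], "homozygote")
  # founders never get origin labels
  expect_true(all(is.na(ph$paternal[c("f", "m"), ])))
  expect_equal(ph$eligible, c(FALSE, FALSE, TRUE))
})

test_that("an all-heterozygous trio stays unresolved (no guessing)", {
  ph <- phase_pedigree(trio_ped(), trio_geno("A G", "A G", "A G"))
  expect_true(is.na(ph$paternal["k", 1]))
  expect_true(is.na(ph$maternal["k", 1]))
  expect_equal(ph$phase_source["k", 1], "unresolved")
})

test_that("grandparental genotypes resolve through an untyped parent", {
  ped <- read_pedigree(c("F1 gf 0 0 1", "F1 gm 0 0 2", "F1 fa gf gm 1",
                         "F1 mo 0 0 2", "F1 k fa mo 1"))
  # father ungenotyped but both his parents hom AA -> he must transmit A;
  # child AG thus has paternal A, maternal G
  g <- read_genotypes(c("F1 gf 0 0 1 -9 A A", "F1 gm 0 0 2 -9 A A",
                        "F1 mo 0 0 2 -9 A G", "F1 k fa mo 1 -9 A G"),
                      "1 rs1 0 100")
  ph <- phase_pedigree(ped, g)
  a <- match("A", c(g$variants$major_allele, g$variants$minor_allele)) - 1L
  expect_equal(ph$paternal["k", 1], a)
  expect_equal(ph$maternal["k", 1], 1L - a)
  expect_equal(ph$phase_source["k", 1], "propagated")
})

test_that("a child's resolved allele feeds back into a parent's phase", {
  # mother het with hom-minor father of her own; her child's genotype is
  # resolved through the child's hom father
  ped <- read_pedigree(c("F1 gf 0 0 1", "F1 gm 0 0 2", "F1 mo gf gm 2",
                         "F1 fa 0 0 1", "F1 k fa mo 1"))
  g <- read_genotypes(c("F1 gf 0 0 1 -9 A A", "F1 gm 0 0 2 -9 A G",
                        "F1 mo gf gm 2 -9 A G", "F1 fa 0 0 1 -9 G G",
                        "F1 k fa mo 1 -9 A G"), "1 rs1 0 100")
  ph <- phase_pedigree(ped, g)
  # mother received A from her hom father, G from her mother
  expect_equal(ph$paternal["mo", 1], 1L)
  expect_equal(ph$maternal["mo", 1], 0L)
  # child: father GG forces paternal G, so the A came from the mother
  expect_equal(ph$paternal["k", 1], 0L)
  expect_equal(ph$maternal["k", 1], 1L)
})

test_that("Mendelian inconsistencies abstain and are logged, not fatal", {
  ph <- phase_pedigree(trio_ped(), trio_geno("G G", "G G", "A A"))
  expect_true(is.na(ph$paternal["k", 1]))
  me <- attr(ph, "mendel_errors")
  expect_equal(nrow(me), 1L)
  expect_equal(me$fid, "F1")
})

test_that("phasing is sound against gene-dropping truth in every family shape", {
  for (shape in c("trio", "nuclear", "three_generation")) {
    cfg <- sim_config(n_families = 60, family_shape = shape, n_snps = 4,
                      maf = c(0.1, 0.3, 0.5, 0.2), seed = 91)
    sim <- simulate_pedigree_genotypes(cfg)
    ph <- phase_pedigree(sim$pedigree, sim$genotypes)
    el <- ph$eligible
    expect_equal(sum(ph$paternal[el, ] != sim$truth$x_pat[el, ], na.rm = TRUE), 0)
    expect_equal(sum(ph$maternal[el, ] != sim$truth$x_mat[el, ], na.rm = TRUE), 0)
    # resolved alleles always sum to the observed dosage
    both <- !is.na(ph$paternal) & !is.na(ph$maternal) & !is.na(sim$genotypes$dosage)
    expect_equal(ph$paternal[both] + ph$maternal[both],
                 sim$genotypes$dosage[both])
  }
})

test_that("phasing output does not depend on family or sample order", {
  cfg <- sim_config(n_families = 20, family_shape = "three_generation",
                    n_snps = 3, seed = 17)
  sim <- simulate_pedigree_genotypes(cfg)
  ph <- phase_pedigree(sim$pedigree, sim$genotypes)
  set.seed(1)
  perm <- sample(nrow(sim$pedigree))
  ped2 <- sim$pedigree[perm, ]
  g2 <- new_genotype_matrix(sim$genotypes$dosage[perm, , drop = FALSE],
                            sim$genotypes$variants,
                            sim$genotypes$samples[perm])
  ph2 <- phase_pedigree(ped2, g2)
  back <- match(sim$genotypes$samples, g2$samples)
  expect_equal(unname(ph2$paternal[back, ]), unname(ph$paternal))
  expect_equal(unname(ph2$maternal[back, ]), unname(ph$maternal))
})

test_that("unphased rate counts unresolved eligible samples", {
  pat <- matrix(1L, 10, 1); mat <- matrix(0L, 10, 1)
  expect_equal(unname(phasing_missing_rate(make_phased(pat, mat))), 0)
  pat[1:3, 1] <- NA
  expect_equal(unname(phasing_missing_rate(make_phased(pat, mat))), 0.3)
})

test_that("the unphased-rate filter uses an inclusive 30% bound", {
  # 27 variants over 10 eligible samples; variants 1-5 at rate >= 0.30
  pat <- matrix(1L, 10, 27); mat <- matrix(0L, 10, 27)
  pat[1:5, 1] <- NA                 # 0.5
  pat[1:4, 2] <- NA                 # 0.4
  pat[1:3, 3] <- NA; pat[1:3, 4] <- NA; pat[1:3, 5] <- NA   # exactly 0.30
  pat[1:2, 6] <- NA                 # 0.2, retained
  ph <- make_phased(pat, mat)
  fl <- filter_unphased(ph, threshold = 0.30)
  expect_equal(sum(fl$report$excluded), 5L)
  expect_equal(nrow(fl$phased$variants), 22L)
  expect_false(fl$report$excluded[6])       # 0.29-type boundary complement
  expect_equal(attr(fl$report, "mean_phasing_rate"),
               mean(1 - fl$report$unphased_rate))
})
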