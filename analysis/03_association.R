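#!/usr/bin/env Rscript
# Step 3: the three allelic association tests on ln(BMI) - standard
# dosage, paternal allele only, maternal allele only - adjusted for age,
# sex and T2D, followed by the paternal-vs-maternal slope comparison and
# the Bonferroni threshold alpha / (m * 3). Uses the full pipeline entry
# point on the files produced by steps 1-2.

suppressPackageStartupMessages(library(poefam))
args <- commandArgs(trailingOnly = TRUE)
seed <- if ("--seed" %in% args) as.integer(args[match("--seed", args) + 1]) else 1L

ped <- read_pedigree("scratch/sim/cohort.fam")
g <- read_genotypes("scratch/sim/cohort.ped", "scratch/sim/cohort.map")
pheno <- read_phenotypes("scratch/sim/cohort.pheno.tsv")

res <- run_quant_pipeline(ped, g, pheno, out_dir = "results", seed = seed)
invisible(file.rename(file.path("results", c("qc_report.tsv", "phasing_report.tsv",
                                   "assoc.tsv", "beta_compare.tsv")),
            file.path("results", c("02_qc_report.tsv", "02_phasing_report.tsv",
                                   "03_assoc.tsv", "03_beta_compare.tsv"))))

a <- res$assoc
top <- a[order(a$p), ][1:5, c("snp_id", "mode", "beta", "se", "p", "n")]
message("Bonferroni threshold 0.05/(", res$n_snps_tested, "*3) = ",
        signif(res$bonferroni, 3))
message("top associations:")
print(top, digits = 3)
hits <- res$comparison[res$comparison$p <= 0.05, ]
message(nrow(hits), " SNP(s) with nominally different paternal vs maternal ",
        "slopes: ", paste(hits$snp_id, collapse = ", "))
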