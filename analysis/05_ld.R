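#!/usr/bin/env Rscript
# Step 5: pairwise linkage disequilibrium among the phased candidate SNPs,
# computed by direct haplotype counting (phase known from step 2; no EM).
# Writes the square r2 matrix and a long-format table to results/.

suppressPackageStartupMessages(library(poefam))

ph <- read_phased_vcf("scratch/sim/cohort.phased.vcf")
r2 <- ld_matrix(ph)

dir.create("results", showWarnings = FALSE)
write.table(data.frame(snp_id = rownames(r2), round(r2, 4),
                       check.names = FALSE),
            "results/05_ld_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
long <- data.frame(id1 = rownames(r2)[row(r2)[upper.tri(r2)]],
                   id2 = colnames(r2)[col(r2)[upper.tri(r2)]],
                   r2 = round(r2[upper.tri(r2)], 4))
write.table(long, "results/05_ld_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("LD computed for ", nrow(r2), " SNPs; median off-diagonal r2 = ",
        signif(median(long$r2, na.rm = TRUE), 3),
        " (independent simulated variants, so near zero as expected)")
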