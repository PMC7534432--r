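#!/usr/bin/env Rscript
# Step 2 — variant filtering.
#
# Applies the MAF/missingness filter to the simulated genotypes. With all
# sites on the D genome and family-private donor alleles diluted across the
# pooled population, the appropriate preset is the D-genome second-pass
# threshold (MAF >= 0.01) with the 30% missingness cap; the stricter
# first-pass preset (MAF >= 0.05) is reported for comparison.

suppressMessages(library(wildintro))

rundir <- "results/run"
g <- suppressWarnings(read_vcf(file.path(rundir, "genotypes.vcf")))
cat(sprintf("input: %d sites x %d samples\n", nrow(g$gt), ncol(g$gt)))

gf <- filter_variants(g, maf_min = 0.01, max_missing = 0.30)
cat(sprintf("retained at MAF >= 0.01, missingness <= 30%%: %d sites\n",
            nrow(gf$gt)))
g5 <- filter_variants(g, maf_min = 0.05, max_missing = 0.30)
cat(sprintf("(the MAF >= 0.05 first-pass preset would keep %d sites,\n",
            nrow(g5$gt)))
cat(" dropping family-private donor alleles needed for segment calling)\n")

write_vcf(gf, file.path(rundir, "genotypes_filtered.vcf"))
cat("wrote", file.path(rundir, "genotypes_filtered.vcf"), "\n")
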