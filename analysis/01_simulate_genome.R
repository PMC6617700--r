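#!/usr/bin/env Rscript

# Step 1 — simulate the study inputs.
#
# Draws the default synthetic genome (2000 coding sequences with a bimodal
# GC3 distribution and planted AU3-rich/GC3-rich gene groups), the gene-set
# collection covering the planted groups, and a 25 + 25 control/disease
# cohort under the causal codon-employment-shift model. Everything later
# steps need is written as plain text under results/data/.

suppressPackageStartupMessages(library(codonshift))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- generate_cds_set(genome_spec(seed = seed))
write_fasta(genome$cds, file.path(out, "genome.fa"))
write.table(genome$truth, file.path(out, "ground_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sets <- generate_gene_sets(genome$truth, seed = seed + 1)
write_gene_sets(sets, file.path(out, "gene_sets.gmt"))

cohort <- generate_cohort(genome, cohort_spec(seed = seed + 2))
ab <- data.frame(gene_id = rownames(cohort$abundance),
                 signif(cohort$abundance, 6), check.names = FALSE)
write.table(ab, file.path(out, "abundance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = names(cohort$labels),
                       label = cohort$labels),
            file.path(out, "labels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

n_gp1 <- sum(genome$truth$gp1)
n_gp2 <- sum(genome$truth$gp2)
cat(sprintf(
  "Simulated %d coding sequences (seed %d): %d planted GP1 (AU3-rich), %d planted GP2 (GC3-rich),\n%d gene sets, and a %d control / %d disease cohort (beta = %.1f log2-fold per 100 AU3 pp).\n",
  nrow(genome$truth), seed, n_gp1, n_gp2, length(sets),
  sum(cohort$labels == "control"), sum(cohort$labels == "disease"),
  cohort$truth$spec$beta))
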