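#!/usr/bin/env Rscript
# Stage 3 — binomial mCG-enrichment classification.
#
# Estimates the context-specific background from all coding sequence,
# tests each gene's pooled reads against it (one-sided binomial),
# adjusts per context by Benjamini-Hochberg, and labels genes; gbM
# requires >= 10 covered CG sites, q(CG) < 0.05 and q(CHG), q(CHH) >
# 0.05. Compares the labels against the simulated ground truth and then
# repeats the whole procedure on reads thinned to ~1x to show why
# shallow coverage precludes the test for many genes.

suppressMessages(library(gbmtools))

records <- read_allc("results/sim/allc.tsv")
genes <- read_genes("results/sim/genes.bed")
truth <- data.table::fread("results/sim/truth.tsv")
summaries <- data.table::fread("results/gene_summaries.tsv")

bg <- estimate_background(records, genes)
cat("coding-sequence background:\n")
print(bg)
cls <- classify_genes(summaries, bg)
data.table::fwrite(cls, "results/classification.tsv", sep = "\t")
print(table(cls$label))

m <- merge(cls[, c("gene_id", "label")], truth, by = "gene_id")
cat(sprintf("gbM sensitivity: %.4f\n",
            mean(m$label[m$true_class == "gbM"] == "gbM")))
cat(sprintf("TE-like genes called gbM: %d\n",
            sum(m$label[m$true_class == "TE_like"] == "gbM")))
cat(sprintf("unmethylated genes called gbM: %.4f\n",
            mean(m$label[m$true_class == "unmethylated"] == "gbM")))

thin <- downsample_records(records, 1, seed = 2L)
thin_cls <- classify_genes(summarize_genes(thin, genes),
                           estimate_background(thin, genes))
data.table::fwrite(thin_cls, "results/classification_1x.tsv", sep = "\t")
cat(sprintf("unclassified genes: %d at 20x vs %d at ~1x\n",
            sum(cls$label == "unclassified"),
            sum(thin_cls$label == "unclassified")))
cat("written: results/classification.tsv, results/classification_1x.tsv\n")
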