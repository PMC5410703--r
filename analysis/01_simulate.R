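#!/usr/bin/env Rscript
# Stage 1 — generate the ground-truthed synthetic methylome.
#
# One synthetic chromosome carrying 1000 non-overlapping genes on
# alternating strands: 70% unmethylated, 20% gene-body-methylated (CG at
# 0.8 in the body, depleted toward TSS/TTS by a 20-window profile) and
# 10% TE-like (0.8 in all three contexts). Per-site coverage is
# Poisson(20); unmethylated molecules read methylated at the 0.5%
# non-conversion rate. Writes the allc call table, BED annotation and
# ground truth under results/sim/.

suppressMessages(library(gbmtools))

cfg <- simulation_config(seed = 1L)
sim <- simulate_methylome(cfg)
paths <- write_fixture(sim, "results/sim", gff3 = TRUE)

cat("simulated", nrow(sim$genes), "genes /", nrow(sim$records),
    "cytosines on a", round(sim$genome_length / 1e6, 2), "Mb chromosome\n")
print(table(sim$truth$true_class))
for (ctx in c("CG", "CHG", "CHH"))
  cat(sprintf("genome-wide m%s = %.4f\n", ctx,
              weighted_methylation(sim$records, context = ctx)))
cat("written:", paste(basename(paths), collapse = ", "),
    "-> results/sim/\n")
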