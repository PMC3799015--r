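#!/usr/bin/env Rscript
# Stage 5 — cross-species leading-edge consensus.
#
# Counts, for every gene and Venn gene set, the contrasts per species in
# whose leading edge the gene appears, then applies the two-species
# frequency rule: a gene enters the core if it reaches 10/12 mouse AND
# 5/6 human leading edges for at least one direction-matched set; the
# per-direction lists are unions over sets. Compares the recovered core
# with the planted truth.

library(dcmature)

cfg <- default_config(out_dir = "results/pipeline", seed = 1)
run_stage("consensus", cfg)

core <- read_gmt("results/pipeline/core_signature.gmt")
truth <- read_gmt("results/pipeline/truth_sets.gmt")
cat("Core signature:", length(core$core_up$genes), "UP,",
    length(core$core_down$genes), "DOWN genes\n")
for (d in c("core_up", "core_down")) {
  planted <- toupper(truth[[d]]$genes)
  got <- core[[d]]$genes
  cat(sprintf("%s: sensitivity %.1f%%, %d false positives\n", d,
              100 * mean(planted %in% got), length(setdiff(got, planted))))
}
tab <- read.delim("results/pipeline/core_signature.tsv", comment.char = "#")
cat("Top frequency bins:\n")
print(head(tab[, c("gene", "direction", "bin")], 12))
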