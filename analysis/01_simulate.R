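#!/usr/bin/env Rscript
# Stage 1 — simulate the study panel.
#
# Generates the synthetic cross-condition panel the whole analysis runs
# on: a 12-contrast mouse study and a 6-contrast human study profiled in
# duplicate (2000 genes), with a planted core maturation signature
# (72 UP / 58 DOWN genes, +/-2 log2 effect, active in 11/12 mouse and
# 5/6 human contrasts), per-subset identity fingerprints attenuated upon
# activation, per-contrast private modules, and additive+proportional
# noise. Also writes 200 promoter sequences (-400..+400 nt) in which 60
# core-UP promoters carry planted NF-kB-like sites, plus the planted and
# decoy PWMs and the full ground truth.

library(dcmature)

cfg <- default_config(out_dir = "results/pipeline", seed = 1)
run_stage("simulate", cfg)

mouse <- read_expression_study("results/pipeline/mouse_matrix.tsv",
                               "results/pipeline/mouse_samples.tsv")
human <- read_expression_study("results/pipeline/human_matrix.tsv",
                               "results/pipeline/human_samples.tsv")
cat("Simulated studies:\n")
print(mouse)
print(human)
truth <- read_gmt("results/pipeline/truth_sets.gmt")
cat("Planted:", length(truth$core_up$genes), "core UP and",
    length(truth$core_down$genes), "core DOWN genes\n")
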