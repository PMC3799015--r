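#!/usr/bin/env Rscript
# Stage 4 — GSEA of the Venn gene sets across all 18 contrasts.
#
# Ranks every quiescent-vs-activated contrast of both species by log2
# fold change and tests each Venn-region gene set with the weighted
# running-sum statistic against a gene-set permutation null (200
# permutations per set), recording NES, FDR q and the leading edge.
# Mouse gene sets are translated to human symbols for the human
# contrasts. This is the tabular form of a circle-plot summary: one row
# per (contrast, set) with |NES| as the circle area.

library(dcmature)

cfg <- default_config(out_dir = "results/pipeline", seed = 1)
run_stage("gsea", cfg)

res <- read.delim("results/pipeline/gsea_results.tsv", comment.char = "#")
cat("Tested", length(unique(res$contrast)), "contrasts x",
    length(unique(res$set)), "gene sets\n")
shared <- res[res$set %in% c("pDC_cDC8_cDC11b.up", "pDC_cDC8_cDC11b.down"), ]
concord <- (shared$direction == "up" & shared$es > 0) |
  (shared$direction == "down" & shared$es < 0)
cat(sprintf("Shared-response sets confirmed (q <= 0.05, concordant sign) in %.0f%% of %d tests\n",
            100 * mean(concord & shared$q <= 0.05), nrow(shared)))
print(aggregate(abs_nes ~ set, shared, median))
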