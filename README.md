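# dcmature

Cross-condition, cross-species transcriptome meta-analysis of dendritic
cell (DC) maturation, packaged as a tested R pipeline.

## The problem

DC subsets (plasmacytoid DCs, CD8&alpha;⁺ and CD11b⁺ conventional DCs,
monocyte-derived DCs) each carry a steady-state transcriptomic
fingerprint. When DCs mature after microbial-type stimulation, is the
response subset-specific tinkering, or a shared reprogramming conserved
across subsets, stimuli and species? Answering this takes a panel of
quiescent-vs-activated contrasts — typically profiled in duplicate —
and a chain of analyses whose end product is a **core maturation
signature**: the genes modulated in >80% of conditions in both mouse
and human.

`dcmature` implements that chain for anyone who wants to run, audit or
extend such a meta-analysis:

1. **Global structure** — expression filtering (log2 level > 5, fold
   change > 2), complete-linkage hierarchical clustering of samples,
   PCA with variance fractions.
2. **Differential expression** — duplicate-robust per-gene z test with
   a pooled additive+proportional error model
   (`s²(µ) = σ²_add + σ²_prop·µ²`), Benjamini–Hochberg FDR ≤ 0.05,
   fold change ≥ 2, and the three-subset Venn partition whose regions
   become gene sets.
3. **GSEA** — weighted running-sum enrichment score
   (`weight_p = 1`), gene-set permutation null, NES, FDR q, and
   leading-edge extraction, run pairwise over the whole contrast
   panel.
4. **Consensus** — per-species leading-edge frequencies and the
   two-species rule (≥ 10/12 mouse AND ≥ 5/6 human leading edges for
   at least one direction-matched set) producing core UP / core DOWN.
5. **Motif enrichment** — TRAP biophysical promoter affinities
   (λ = 0.7, ln R₀ = 0.584·L − 5.66, both strands, −400..+400 nt
   windows) and PASTAA-style rank-cutoff-maximised hypergeometric
   association with the core genes, permutation-adjusted.

A first-class synthetic-data module (`generate_study()`,
`generate_promoters()`) produces the full 12-mouse + 6-human contrast
panel with a planted ground truth, so sensitivity, false-positive
rates and statistical calibration of every stage are measured by the
test suite rather than assumed.

## Worked example

The numbered scripts under `analysis/` run the whole study; the same
calls work interactively:

```r
library(dcmature)

cfg <- default_config(out_dir = "results/pipeline", seed = 1)
run_stage("all", cfg)   # simulate -> filter -> cluster -> pca -> de
                        # -> venn -> gsea -> consensus -> motif
```

What the run prints (from `analysis/02` through `analysis/06`):

```
Filter kept 1907 of 2000 genes
2-cluster cut vs activation state:
   states
cl  activated quiescent
  1         0        24
  2        24         0
PC1 27.4%, PC2 9.1% of variance
72 genes induced and 58 repressed in all three DC subsets
Tested 18 contrasts x 8 gene sets
Shared-response sets confirmed (q <= 0.05, concordant sign) in 100% of 36 tests
Core signature: 72 UP, 58 DOWN genes
core_up: sensitivity 100.0%, 0 false positives
core_down: sensitivity 100.0%, 0 false positives
        pwm k_best overlap        p_raw       p_adj
1  NFKB_SYN     50      46 6.602142e-22 0.004975124
2 DECOY_SYN     20       7 6.277063e-01 0.810945274
```

Reading this: the activated/quiescent split dominates the sample
dendrogram; the three discovery contrasts share 72 induced and 58
repressed genes; those Venn sets are confirmed by GSEA in all 18
contrasts of both species; the cross-species leading-edge consensus
recovers exactly the planted 72/58-gene core; and the promoters of the
core-UP genes are significantly enriched for the planted NF-κB-like
matrix (adjusted p ≈ 0.005) but not for a column-shuffled decoy
(p ≈ 0.81).

Every artifact is a plain TSV/GMT/FASTA/Newick file under the output
directory, with a provenance header (config hash, seed, version);
rerunning an identical configuration is byte-identical.

## Package layout

- `R/` — the implementation: I/O (`read_expression_study`, `read_gmt`,
  `read_pwm_counts`, `read_fasta`, `read_bed_intervals`), the
  synthetic generator, unsupervised analyses, differential
  expression, the GSEA engine, the consensus procedure, the motif
  stage, and the `run_stage()` orchestrator.
- `analysis/` — numbered narrative drivers (`01_simulate.R` …
  `06_motif_enrichment.R`).
- `tests/testthat/` — unit, property and end-to-end operating-
  characteristic tests, with brute-force oracles re-deriving every
  statistic independently.
- `vignettes/core-maturation-pipeline.Rmd` — the methods vignette:
  models, assumptions, parameter choices, numerical details and
  limitations.
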