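---
title: "Cross-condition meta-analysis of dendritic cell maturation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-condition meta-analysis of dendritic cell maturation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmature)
```

## The scientific question and the shape of the pipeline

Dendritic cells (DCs) come in distinct subsets — plasmacytoid DCs,
CD8&alpha;⁺-type and CD11b⁺-type conventional DCs, monocyte-derived
DCs — each with its own steady-state transcriptomic fingerprint.
When DCs mature in response to microbial-type stimuli, two things can
happen to those programs: subset-specific fine-tuning, or a shared,
convergent reprogramming. Distinguishing the two requires comparing
many quiescent-vs-activated contrasts across subsets, stimuli and
species, and asking which genes respond in essentially all of them.

`dcmature` implements that comparison as a chain of testable stages:

1. **Global structure** — expression filtering, complete-linkage
   hierarchical clustering of samples, and PCA with per-component
   variance fractions.
2. **Differential expression** — a duplicate-robust per-gene test per
   contrast, FDR control, fold-change gating, and the three-subset
   Venn partition whose regions become gene sets.
3. **GSEA** — a weighted running-sum enrichment engine with a gene-set
   permutation null, normalised enrichment scores, FDR q values and
   leading-edge extraction, applied pairwise across the whole contrast
   panel.
4. **Consensus** — cross-species harmonisation of leading edges and a
   frequency-threshold rule producing the core UP / core DOWN
   signature.
5. **Motif enrichment** — TRAP biophysical promoter affinities and a
   rank-cutoff-maximised hypergeometric association between affinity
   and core membership.

A synthetic-data module generates the whole study panel with a known
planted truth, so every stage's operating characteristics (sensitivity,
false-positive rate, calibration) are measurable rather than assumed.

## The synthetic study panel

`generate_study()` emulates the structure of a real cross-condition
panel: 12 mouse and 6 human quiescent-vs-activated contrasts, each
profiled in duplicate (microarray studies of this kind typically used
two biological replicates per condition, which is precisely why the
error model below exists). Its defaults are the conditions every test
in the package runs under:

* 2000 genes with baseline log2 expression ~ N(7, 1.5²);
* a planted core of 72 induced and 58 repressed genes with a ±2 log2
  effect in activated samples — but only in 11 of 12 mouse and 5 of 6
  human contrasts per gene, so the >80% consensus rule is exercised
  non-trivially rather than trivially satisfied;
* the skipped contrasts are drawn outside the three *discovery*
  contrasts (one per mouse subset) from which the differential gene
  sets are built, mirroring a design in which those sets are by
  construction modulated in the discovery conditions;
* per-subset fingerprints (+2 log2 in their own subset) attenuated by
  a factor 0.5 upon activation, emulating the down-modulation of
  identity programs in maturing DCs;
* 10 condition-private genes per contrast;
* noise drawn as `N(0, sigma_add² + sigma_prop² · true²)` with
  defaults `sigma_add = 0.3`, `sigma_prop = 0.02` — the same
  additive-plus-proportional family the differential test models, so
  the error-model fit can be validated by parameter recovery.

Human features use the upper-cased ortholog symbols of the mouse
universe, which makes the ortholog-mapping step exact on synthetic
data and lets tests isolate consensus behaviour from mapping noise.

What the generator deliberately does **not** simulate: probe-level
artifacts, batch effects, platform differences between series,
non-Gaussian heavy-tailed noise, and correlated genes. Passing tests
therefore demonstrate that the pipeline's logic is correct and its
statistics calibrated under its stated model — not that real
microarray panels satisfy that model.

## Filtering, clustering, PCA

`filter_features()` keeps genes with at least one log2 value above 5
and a maximum-minus-minimum range above log2(2) — the standard "is
expressed, does vary" microarray pre-filter, exposed as two
parameters. Clustering is complete-linkage agglomeration of samples
(`stats::hclust`) under either 1 − Pearson correlation (default, the
common choice for expression profiles) or euclidean distance; the
original analyses of this kind did not state their metric, so both are
configuration, and the tests verify the merges against a brute-force
O(n³) enumeration rather than trusting any one library. PCA
(`stats::prcomp`) is run on the unfiltered matrix with feature
centring and no scaling; variance fractions are checked against a
direct eigendecomposition of the sample covariance.

## The duplicate-robust differential test

With two replicates per condition, per-gene variance estimates are
useless (one degree of freedom). The classical remedy is to pool: the
per-gene replicate variance is regressed across all genes on

\[ s_g^2 \approx \sigma_\text{add}^2 + \sigma_\text{prop}^2 \mu_g^2 , \]

with non-negativity enforced on both parameters
(`fit_error_model()`). The per-gene statistic is then

\[ z_g = \frac{\bar{x}_{a,g} - \bar{x}_{q,g}}
     {\sqrt{v_g(\bar x_q)/n_q + v_g(\bar x_a)/n_a}} , \qquad
   v_g(m) = \sigma_\text{add}^2 + \sigma_\text{prop}^2 m^2 , \]

referred to the standard normal (two-sided), BH-adjusted within the
contrast, and gated on both FDR ≤ 0.05 and |log2 fc| ≥ 1. This is a
deliberate, documented simplification of exact-likelihood
duplicate-robust testers: it is well defined, fast, and its parameters
are recoverable from the generator's matching noise model — the
acceptance tests verify type-I calibration at the global null
(fraction of p ≤ 0.05 within binomial error of 0.05 at 5000 genes)
and ≥95% sensitivity with ≤1% false positives at the planted effect.
The fold-change gate is applied to the difference of log2 means; the
alternative (linear-scale means) was rejected for scale coherence with
the rest of the pipeline.

`venn_partition()` splits three subsets' up- and down-lists into the
seven standard disjoint regions per direction and asserts
disjointness-plus-coverage on every call; `venn_gene_sets()` turns the
regions into directional gene sets.

## The GSEA engine

`enrichment_score()` implements the weighted running-sum statistic:
walking down the ranked list, set members increment the sum by
\(|s_i|^p / \sum_\text{hits} |s|^p\) and non-members decrement it by
\(1/(N - N_h)\); the enrichment score is the signed extremum (bounded
in [−1, 1]) and the leading edge is the set members at or before the
positive peak (at or after the negative one). Defaults: `weight_p = 1`
(standard weighted GSEA), ranking by log2 fold change — the stable
metric with duplicates — with signal-to-noise available behind a
variance floor of `0.2·|mean|`. Ties in ranking scores are broken by
lexicographic gene symbol so rankings are bit-reproducible.

Numerical details worth recording:

* the extremum can only occur at a hit (maximum) or just before a hit
  (minimum), so scoring is O(set size) after ranking; the test suite
  checks this fast path against a position-by-position brute-force
  enumeration, exactly (1e−12), and against an independent library
  implementation of the same statistic;
* an exact tie between the positive and negative extremum resolves to
  the positive one. Such ties are measure-zero for observed sets but
  do occur among permutation draws (whenever the first and last hit
  positions are mirror-symmetric), which is why NES antisymmetry under
  swapping the two phenotypes is exact only up to the Monte-Carlo
  estimate of the null normalisation — the ES itself negates exactly.

The null (`gsea_test()`) is **gene-set permutation**: random same-size
sets drawn from the universe. Phenotype permutation is impossible with
two replicates per group, and gene-set permutation is the standard
recommendation at tiny n. Null sets are drawn from the
lexicographically sorted universe, so identical seeds give identical
null *gene sets* whatever the ranking order — this is what makes the
(A,B)-vs-(B,A) antisymmetry exact at the ES level. NES divides the ES
by the mean |null ES| of matching sign; the nominal p is the
same-sign permutation tail with the usual +1 correction; the FDR q
follows the GSEA tail-ratio procedure over the pooled normalised null.
The panel-scale default is 200 permutations per set (the engine
refuses fewer than 100), chosen as sufficient resolution for q ≤ 0.05
decisions at panel scale; single-contrast analyses in the tests use
500–10000.

`ora_test()` is the annotation companion: a one-sided hypergeometric
over-representation test against user-supplied gene sets, BH-adjusted.
It replaces proprietary pathway tools with a transparent statistic.

## The cross-species consensus

`leading_edge_frequencies()` counts, for every (gene, gene set), the
contrasts per species in whose leading edge the gene appears, after
translating mouse leading edges into human symbol space
(`map_orthologs()`: table lookup, upper-case fallback). Only
direction-concordant enrichments contribute by default — a positive
ES for an up-set, negative for a down-set — because a discordant run
says nothing about the genes the set was built from. Denominators are
the contrasts actually tested per species, so dropped conditions
shrink the denominator rather than silently deflating frequencies.

`core_signature()` applies the frequency rule: a gene enters the UP
core if, for **at least one** up-direction set, its mouse frequency is
≥ 10/12 AND its human frequency is ≥ 5/6; DOWN is symmetric; the
per-direction lists are unions over qualifying sets. The thresholds
are applied per gene set before the union (qualification via any
single set suffices) — this follows the natural reading of
"thresholds for each set, then the union of all these lists", and a
pooled-across-sets variant was considered and rejected because it
would let weak, scattered memberships accumulate across unrelated
sets. The two species are combined with AND, not OR. A gene
qualifying in both directions is a directional conflict: an error by
default, or dropped from both lists under an explicit flag (the
pipeline uses `drop`, and reports the dropped genes).

Two boundary properties are asserted as tests: raising either
threshold never grows the core (anti-monotonicity), and at thresholds
at or below 1/n the core reduces to the genes present in at least one
leading edge *of each species* for some direction-matched set — the
natural minimal-threshold identity given the two-species conjunction.

## Promoter affinity and motif enrichment

`extract_promoters()` cuts −400..+400 nt windows around each TSS
(BED 0-based half-open; TSS = `start` on +, `end − 1` on −;
minus-strand windows reverse-complemented; contig-edge windows clipped
and flagged).

`trap_affinity()` is the biophysical expected-occupancy model: every
length-L window on both strands contributes
\(R_0 e^{-E_i} / (1 + R_0 e^{-E_i})\) with mismatch energy
\(E_i = \lambda^{-1} \sum_j \ln(p_{\max,j} / p_{\text{obs},j})\).
The published TRAP parameterisation is adopted and exposed as flags:
\(\lambda = 0.7\), \(\ln R_0 = 0.584 L - 5.66\). `N` bases contribute
the neutral background probability 0.25. The occupancy is evaluated as
`plogis(ln R0 − E)` for numerical stability, and the implementation is
tested against an explicit window/strand loop at 1e−12. PWMs must be
strictly positive (build them with a pseudocount); a zero entry makes
the energy undefined and is an error, not an Inf.

`pastaa_enrichment()` associates affinity with set membership: genes
ranked by affinity, hypergeometric tail of the top-k ∩ test-set
overlap maximised over a cutoff grid (default {20, 50, 100, 200, 500,
all}, clipped to the universe). Because the minimum over cutoffs is
optimised, the raw p is anti-conservative; the adjustment rates it
against label permutations (random equal-size test sets) and the
adjusted p is additionally clamped to be no smaller than the raw best
p. The clamp is a deliberate conservative choice: a finite permutation
sample cannot guarantee `adjusted ≥ raw` on its own, and we prefer the
invariant to hold by construction. On small universes the
hypergeometric statistic is heavily tied and the adjusted p is
conservative (stochastically above uniform); calibration is uniform in
the regimes the pipeline actually uses (hundreds of genes), and the
test suite checks exactly that. The control set is the profiled
universe minus the test set.

## Determinism and problem sizes

Every stochastic component takes an explicit seed and draws through a
local RNG scope, so identical configurations are byte-identical on
disk — the pipeline tests hash every artifact across two runs. The
default end-to-end run (2000 genes, 18 contrasts in duplicate, 200
GSEA permutations per set, 200 promoters of 801 nt, 200 label
permutations per PWM) completes in well under a minute on one CPU;
the test suite exercises larger single pieces (5000-gene null
calibration, 10000-permutation exhaustive comparisons) where a
property needs the resolution. These sizes were chosen as the smallest
at which the measured operating characteristics are stable; they are
stated here so that reported sensitivities and false-positive rates
are read at the scale they were computed.

## Known limitations

* The differential test inherits the pooled-variance assumption:
  genes with atypical variance are mis-calibrated individually even
  though the ensemble is calibrated.
* Gene-set permutation nulls answer "is this set more coherent than a
  random set of genes", not "than a random phenotype assignment"; with
  duplicate designs this is the only option, but the two nulls differ
  when genes are strongly correlated.
* The consensus rule treats leading-edge membership as binary; a gene
  just past the peak in one contrast counts as absent there.
* Ortholog handling by symbol upper-casing is a fallback, not
  biology; real analyses should supply a curated mapping table.
* The motif stage scores promoter windows only; enhancers and distal
  regulation are out of scope, as are de-novo motif discovery and
  proprietary matrix libraries.
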