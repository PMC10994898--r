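---
title: "Signature graphs from multi-rank NMF: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature graphs from multi-rank NMF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siggraph)
```

# The model

`siggraph` treats each case–control cohort as a nonnegative gene-by-sample
matrix $X$ generated by a small number of additive transcriptional programs:
$X \approx WH$ with $W \ge 0$ (gene loadings, one *signature* per column)
and $H \ge 0$ (per-sample *exposures*). Because the "right" number of
programs is unknowable in advance — and a wrong choice either fuses distinct
programs (rank too low) or shreds them into noise (rank too high) — the
package factorizes at *every* rank $k \in [k_{\min}, k_{\max}]$ and pools
all resulting signatures. Redundancy between ranks is deliberate: the same
biological program typically reappears at several ranks, and the downstream
matching step treats those copies as independent chances to find it in
another cohort.

The cross-cohort step assumes that only the top of a signature's exposure
ranking is meaningful: most genes' loadings are noise, so similarity between
signatures from different cohorts is the Jaccard overlap of their top-$N$
gene sets. Reciprocal best hits (as in ortholog mapping) keep a pair only
when each signature is the other's best match in that cohort pair, and a
permutation null removes pairs that re-form when gene labels are shuffled.
When a surviving edge connects cohorts of *different* diseases, its shared
genes are the candidate comorbidity program.

## Assumptions worth stating

- Expression is nonnegative and roughly scale-comparable across genes after
  row-mean normalization (each gene's mean set to 1). This suits intensity
  data (microarrays) and any nonnegative expression summary, but discards
  absolute-abundance information.
- Diagnosis association is tested per signature with a linear model; the
  test assumes approximately normal residuals of exposures within groups.
  Exposures are sums of many gene contributions, which in practice makes
  this mild.
- Gene identifiers are shared across cohorts (symbols, case-insensitive).
  Genes absent from a cohort simply cannot overlap; there is no imputation.

# Tunable parameters

| parameter | default | meaning / why this default |
|---|---|---|
| `kmin`, `kmax` | 2, 20 | rank range of the ensemble; 2..20 pools `sum(2:20)` = 209 signatures per cohort, spanning coarse to fine granularity while every rank stays well below typical sample counts |
| `alpha` | 0.05 | strict `<` threshold on the raw diagnosis p-value; deliberately uncorrected — the permutation test downstream removes chance matches, and the filter's null retention is calibrated at `alpha` by construction |
| `top_n` | 1000 | genes per signature entering Jaccard; large enough to cover a program's breadth, small enough that noise genes dilute overlap instead of creating it |
| `n_permutations` | 20 | permutation rounds; with the `+1` pseudocount `p = (1+c)/21`, so `p ≤ 0.05` keeps exactly the edges never re-formed under shuffling |
| `edge_alpha` | 0.05 | occurrence-probability threshold (`≤`, attainable: min p is `1/(R+1)`) |
| `max_iter`, `tol` | 500, 1e-5 | NMF stopping rules: stop when the relative per-iteration loss decrease falls below `tol`, warn and keep the best iterate at `max_iter` |
| `min_size`, `max_size` (enrichment) | 10, 2000 | standard over-representation hygiene: tiny terms are unstable, huge terms uninformative |
| `max_depth` (knowledge graph) | 3 | hop bound for neighborhood extraction; the depth is a parameter because curated-graph conventions vary (values of 3 and 5 are both in circulation), and hop-distance BFS is the implemented reading of "connectivity depth" |

# Numerical choices

**Solver.** Single-rank NMF minimizes the squared Frobenius loss with
Lee–Seung multiplicative updates, which are monotone (the loss never
increases; the test suite checks this with slack 1e-8). A small
`.Machine$double.eps` guard in each denominator avoids division by zero
without breaking monotonicity in practice.

**Initialization.** Nonnegative double SVD (NNDSVD): each truncated-SVD
component contributes the dominant nonnegative parts of its singular
vectors. Zeros left by the sign split are filled with a small positive
constant (`mean(X) * 1e-4`) because multiplicative updates cannot leave an
exact zero. NNDSVD is deterministic, so the whole pipeline is reproducible
without averaging restarts; a seeded `init = "random"` option exists for
sensitivity checks.

**Ties.** Top-$N$ selection breaks exposure ties by ascending gene label;
reciprocal-best-hit ties (exact Jaccard equality) are all kept and flagged
rather than broken arbitrarily. Both rules make output order-independent
and bit-reproducible.

**Degenerate cases.** Zero-variance exposures get p = 1 (no evidence) with
a flag; all-zero signature columns are retained but flagged; zero-mean gene
rows cannot be scaled to mean 1 and are dropped with a warning; zero-Jaccard
candidate pairs are discarded before best-hit matching (no information);
collinear covariates are dropped by the fit with a warning.

**Permutation matching.** An observed edge is counted as re-formed in a
permutation only when the *identical* signature pair (cohort, rank, index on
both ends) is again a reciprocal best hit — the conservative reading; a
`match_on = "cohort_pair"` option implements the looser any-edge-between-
the-cohorts reading. Shuffling is within-signature (each signature's
exposure multiset is preserved exactly); shuffling the whole $W$ matrix at
once is a plausible alternative reading but would mix exposure scales across
signatures.

# The synthetic generator

`synthetic_design()` / `generate_cohorts()` emulate the structure the
pipeline assumes: per cohort, expression is a positive per-gene baseline
plus $\sum_f w_f h_f^\top$ over planted factors, all multiplied by
entrywise lognormal noise. Signature genes draw Gamma(4, 4)-distributed
loadings scaled by `exposure_scale` (mean 1 by default); off-signature genes
get the same shape at 1% scale — small but nonzero, so top-$N$ selection is
a genuine inference problem. Factor exposures are Uniform(0.5, 1.5) in the
factor's active group (`case`, `control`, or `all`) and 0 elsewhere.
`noise_scale` (default 0.1, i.e. ~10% multiplicative intensity noise) sets
the default signal-to-noise ratio of 10, the strong-signal regime in which
recovery claims are made.

Two canned designs define the validation conditions: `design_planted_edge()`
(four cohorts — two schizophrenia/brain, two type-2-diabetes/islets, 20
cases + 20 controls each, 2000 genes, one case-active factor of 150 genes
shared by one cohort of each disease, plus a private all-sample background
factor per cohort) and `design_null()` (same shape, no diagnosis-linked and
no shared factors).

What the generator does *not* emulate: probe-level artifacts, batch effects
beyond the per-cohort background factor, heavy-tailed count noise,
correlated gene-gene structure within programs, or partially overlapping
gene universes. Passing tests on this generator therefore demonstrate that
the machinery recovers what it is designed to recover under its own model
assumptions — not that real cohorts satisfy those assumptions.

# Validation design and problem sizes

The test suite and `scripts/acceptance.R` work at sizes chosen to exercise
every code path on one CPU in minutes: the planted-edge recovery runs the
full pipeline on the four-cohort design (2000 genes, `kmax = 8`,
`top_n = 300`, 20 permutations) over 10 seeds and requires the planted
inter-class cohort pair to be re-linked, with ≥ 70% of the planted genes in
the recovered edge's shared set, in at least 9 of 10; null calibration runs
20 seeds of the no-signal design and checks that the diagnosis filter
retains ≈ 5% of signatures and the permutation test kills ≥ 85% of
null reciprocal-best-hit candidates. Recovery is assessed at the cohort-pair
level because multi-rank pooling intentionally produces several parallel
edges between the same two planted programs; demanding that one *specific*
signature pair survive would conflate that redundancy with failure.

Combinatorial kernels (reciprocal best hits, BFS neighborhoods,
all-shortest-path bridges, gene-set categorization) are tested against
independent brute-force oracles on random instances, and closed-form values
(Jaccard identities, the permutation pseudocount table, the exact
hypergeometric tail, the Benjamini–Hochberg step-up) are asserted directly.

# Known limitations

- The diagnosis filter tests signatures one at a time; strongly correlated
  signatures (inevitable across ranks) are each tested marginally, which is
  the intended redundancy but inflates the count of "significant" signatures
  relative to the number of distinct programs.
- With 20 permutations the minimum occurrence probability is 1/21, so
  `edge_alpha = 0.05` is an all-or-nothing filter: one re-formation removes
  an edge. More permutations buy resolution at linear cost.
- Under the strict pair-matching null, an edge between cohorts with very few
  retained signatures re-forms by chance at rate ≈ 1/(n_A + n_B − 1) per
  round, so true edges in signature-poor cohorts can be lost; the parallel
  rank copies mitigate this.
- Enrichment uses the one-sided hypergeometric test with per-edge BH
  control; per-edge control matches a per-pair analysis but does not control
  the FDR across the whole graph (a global flag exists).
- Gene-level aggregation in `rank_genes_for_term()` keeps each gene's
  maximum geometric-mean exposure over edges — one declared choice among
  several defensible ones (mean or sum would weight recurrence instead of
  peak response).
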