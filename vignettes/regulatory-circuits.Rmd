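---
title: "Models and methods behind miRcircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind miRcircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRcircuit)
```

`miRcircuit` turns three differential-expression analyses — miRNAs,
mRNAs, and proteins, tumor versus adjacent-normal tissue — into
mechanism-typed regulatory circuits and clinically characterized hubs.
This vignette documents the statistical models, the choices that were
genuinely open, and what the synthetic-data validation does and does not
establish.

## The differential-expression model

Counts for feature *f* in sample *s* are modeled as negative binomial
with mean `s_s * μ_f(group)` and dispersion `α`, so that
`var = μ + αμ²`. The stage is a deliberately transparent pipeline of
classical estimators:

* **Size factors** by median-of-ratios: `s_j = median_f(k_fj / g_f)`
  with `g_f` the geometric mean of feature *f* across samples, computed
  over features positive in every sample. When no such feature exists
  the estimator refuses with a pointer to `pseudo_reference = TRUE`,
  which instead takes geometric means over positive counts only.
* **Dispersion** per feature by method of moments on the normalized
  scale, pooled across the two groups weighted by their degrees of
  freedom, floored at 0 (the floor matters for low-count features whose
  sample variance falls below the Poisson expectation).
* **Effect size** `log2FC = log2((m_T + ε)/(m_N + ε))` with pseudo-count
  `ε = 0.5` so that one-sided dominance (a gene silent in normals,
  expressed in tumors) yields a finite, large, correctly signed
  estimate. Tumor is always the numerator; this fixes every sign
  convention downstream.
* **Inference** by a Wald z statistic with a delta-method standard
  error, two-sided normal p-values, and Benjamini–Hochberg adjustment.
  Features with zero counts in every sample are excluded before
  adjustment, so they do not inflate the BH denominator.

This is intentionally *not* a reimplementation of the shrinkage-based
NB frameworks used for production differential expression: there is no
dispersion shrinkage, no outlier replacement, no independent filtering
beyond the all-zero rule. The trade-off is full testability — every
estimator has a closed form that unit tests verify against hand
computation — at the price of slightly noisier dispersion estimates.
The suite checks the consequences directly: on 2000 null features with
20 vs 20 samples the type-I error rate at nominal 0.05 stays within
[0.03, 0.07], and with 10% planted effects at |log2FC| = 2 the observed
FDR among adjusted calls stays below 0.10 over 20 simulation seeds.

Call thresholds follow the field's convention for this design: genes at
adjusted p ≤ 0.05 and |log2FC| ≥ 1, miRNAs at adjusted p ≤ 0.05 and any
nonzero fold change (miRNA fold changes are compressed relative to
mRNAs, so a magnitude gate would discard real regulators). Both are
parameters of `nb_wald_test()`/`call_differential()`, not constants.

In place of a variance-stabilizing transformation the package uses
`log2(normalized count + 1)` (`vst_like_transform()`). Its only
downstream uses — quartile stratification, ROC, rank tests, correlation
— depend on ranks or rough scale, for which any monotone
variance-damping transform is equivalent.

## Overlap groups and circuit assembly

The four DEG/DEP groups are plain set intersections after ID
harmonization (gene symbols uppercased, miRNA IDs lowercased, exact
match). Mature-versus-precursor miRNA naming is *not* guessed: an
optional user-supplied alias table maps IDs before matching, and a
protein table with conflicting duplicate directions is rejected at load
time rather than resolved silently.

Circuit assembly applies three direction rules to the filtered
interaction table (rows whose `support_type` contains "negative",
case-insensitively, are dropped; pairs are deduplicated):

| circuit | miRNA | gene mRNA | gene protein | mechanism |
|---------|-------|-----------|--------------|-----------|
| RRC1 | up | down | down | target degradation |
| RRC2 | up | up | down | translational repression |
| IRC | down | up | up | de-repression |

The mRNA-down/protein-up group is deliberately excluded: no miRNA
mechanism explains it, and a circuit built on it would confound the
interpretation of the other three. Assembly is a pure function of its
inputs — tests verify idempotence, row-order invariance, and exact
agreement with a brute-force enumeration of the rules on toy universes.

## Hub detection

Target hubs use maximal clique centrality,
`MCC(v) = Σ_{C ∋ v} (|C|−1)!` over maximal cliques `C`. The clique
enumeration is an authored Bron–Kerbosch with pivoting (pivot = vertex
covering the most candidates), validated against exhaustive subset
enumeration on all random graphs up to 10 nodes and against an
independent graph library. Two conventions required a decision:

* **Isolated nodes score 0** (singleton maximal cliques are skipped).
  Assembled circuits never contain isolated nodes, and this choice keeps
  the identity `MCC = degree` exact on bipartite graphs — which is also
  why, on circuits, the MCC score of a gene always equals its regulator
  count.
* **Ties break lexicographically by ID**, making hub tables
  deterministic; scores themselves carry no order information among
  ties.

Regulator hubs are ranked by out-degree (distinct targets), and the top
`k` is expanded to include *every* regulator tied with the k-th value —
this tie rule is why published hub tables of this kind can contain more
than `k` regulators per circuit. `k = 5` is the default on both sides
but remains a parameter: published analyses in this area do not state a
single (k, tie) rule that explains all reported hub counts, so the
package exposes the knob instead of hard-coding a guess. Coverage is
`100 × out-degree / (distinct targets in the circuit graph)`, rounded
to one decimal. The denominator is always the graph's own target count;
note that published tables occasionally disagree with their prose on
this denominator, which is one reason the package recomputes it rather
than accepting it as input.

## Enrichment

`ora_test()` is the hypergeometric upper tail
`P(X ≥ k)` for overlap `k`, set size `K`, query size `n`, background
`N`, with BH adjustment strictly within one category (adjusting
pathway sets and miRNA-family sets jointly would trade power between
unrelated families of hypotheses). The default background is the set of
features tested for differential expression, the standard ORA practice
when the assay defines the measurable universe; it is overridable
because externally curated tools rarely document their own backgrounds.
Query IDs outside the background are dropped with a message; a fully
disjoint query is an error because it almost always signals an ID-space
mismatch rather than a biological result.

## Clinical statistics

* **ROC/AUC** uses the rank (Mann–Whitney) statistic with half credit
  for ties. Markers are oriented per marker: an AUC below 0.5 is
  flipped and the flip recorded, so down-regulated markers report the
  same discriminative power as up-regulated ones. Bands follow the
  conventional 0.9/0.8/0.7/0.6 cutpoints.
* **Quartile stratification** takes the `floor(n/4)` lowest and highest
  samples (180 patients → 45 per arm), with boundary ties broken by
  sample ID so the design is reproducible.
* **Kaplan–Meier and log-rank** are computed through the `survival`
  package — the field's reference implementation — behind the package's
  own interface; the p-value uses the universal 1-df chi-square
  approximation. The tests keep independent oracles: hand-computed
  product-limit factors and O/E/V tables, and a permutation reference
  for the p-value. Two-group comparisons with no events at all return a
  flagged, NA-valued result instead of erroring.
* **T-stage association** runs Kruskal–Wallis across stages plus all
  pairwise Mann–Whitney tests (exact enumeration when the combined
  sample is ≤ 12 without ties), unadjusted by default to mirror the
  usual per-pair reporting, with an opt-in BH flag. Samples missing the
  stage are dropped with a logged count. The all-ties degenerate case
  reports H = 0, p = 1.
* **Regulator–target correlation** is Pearson's r with the t-test
  p-value; a pair is called a significant inverse correlation only when
  both p ≤ 0.05 and r ≤ −0.3. The double gate is deliberate: with
  hundreds of samples trivially small negative correlations become
  significant, and the magnitude gate keeps the call biologically
  meaningful.

## The synthetic-data generator

`simulate_igc_study()` emulates the study design the pipeline targets:
an imbalanced cohort (default 180 tumor / 18 normal), NB counts with
per-sample size factors drawn log-uniformly in [0.5, 2] (so
normalization is never a no-op), a planted fraction of features shifted
by ±`lfc_magnitude` in tumors only, a protein table derived from the
planted gene directions with a controllable concordance rate, an
interaction table holding planted true edges among DE features plus
decoys among non-DE features and a fraction of "negative"-support rows,
and clinical data in which T-stage probabilities shift monotonically
with the designated gene's expression quartile and survival is
exponential with log-hazard linear in standardized expression
(administrative censoring at a fixed horizon plus independent
exponential dropout). Defaults: 25% DE genes and 23% DE miRNAs
(matching the proportions typical of this tumor/normal contrast),
|log2FC| = 2, dispersion 0.1 (typical bulk RNA-seq), baseline hazard
0.015 events/month with a 120-month horizon, and a hazard coefficient
of 0.75 per SD of expression on a designated degradation-circuit gene.
Every planted effect is recorded exactly once in a truth object, and a
fixed seed makes all outputs bit-identical across runs.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: batch and library-preparation
structure; per-gene dispersion heterogeneity (one shared α by default);
correlated co-expression between a miRNA and its targets (planted edges
live in the interaction table, not in the count covariance, so the
inverse-correlation statistic is exercised on nulls and constructed
fixtures rather than on planted signals); mature/precursor ID
ambiguity; and proteome intensities (only directions are generated,
which is all the pipeline consumes).

## Problem sizes and runtime

The test suite and the acceptance script were sized so a complete run
stays comfortably interactive on a single core: calibration suites use
2000 features at 20 vs 20 samples, FDR recovery uses 20 seeds of 1000
features, the end-to-end recovery check uses 600 genes × 150 miRNAs at
high counts (where planted degradation edges must be recovered at
≥ 90%), and the acceptance script simulates the full 180/18 cohort at
2000 genes. The full suite runs in well under a minute; the acceptance
script in a few seconds.

## Known limitations

The Wald test is anticonservative for very small groups (< 5 per arm)
where the dispersion plug-in is noisy; the package requires only ≥ 2
per group and leaves the judgment to the user. The clique engine is
exact but exponential in the worst case — appropriate for circuit-sized
graphs (hundreds of nodes, bipartite), not for dense general networks.
Cox regression, multivariable prognostic modeling, paired designs, and
predicted (non-validated) target inclusion are out of scope.
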