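---
title: "Supervised tri-factorization for variant deleteriousness: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised tri-factorization for variant deleteriousness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snmtfvar)
```

## The problem

A small fraction of missense variants disrupt protein function and cause
disease. Individual deleteriousness predictors (SIFT, Polyphen2, LRT,
MutationAssessor, PROVEAN, GERP++, phyloP, phastCons, SiPhy) disagree, and
gene-level evidence — which genes interact, which genes are linked to
disease — is informative but dangerous: a predictor that scores variants by
their *gene* alone looks excellent on benchmarks where all variants of a
gene share a label and useless in the clinic ("type 2 circularity").
`snmtfvar` fuses the three evidence layers in a single supervised
non-negative matrix tri-factorization, and its evaluation machinery is built
to expose, not hide, gene-level shortcuts.

## Model and assumptions

The two-source training objective over non-negative factors is

$$J = \lVert R_{VS} - VUS^\top\rVert_F^2 + \lVert Y - VUG_Y^\top\rVert_F^2
      + \gamma_1\,\mathrm{tr}(V^\top L_V V) + \gamma_2\,\mathrm{tr}(S^\top L_S S),$$

with $V \in \mathbb{R}^{m\times k_V}_{\ge 0}$ (variant clusters),
$S \in \mathbb{R}^{n\times k_S}_{\ge 0}$ (score clusters),
$U \in \mathbb{R}^{k_V\times k_S}_{\ge 0}$ (cluster interactions) and
$G_Y \in \mathbb{R}^{1\times k_S}_{\ge 0}$ (label indicator). The label
vector is factorized jointly with the relation matrix, so variant clusters
are pulled toward class-homogeneity during training itself; no external
classifier is used. The three-source objective adds
$\lVert R_{VD} - VU_2D^\top\rVert_F^2 + \gamma_3\,\mathrm{tr}(D^\top L_D D)$
with $D \in \mathbb{R}^{n_D \times k_D}_{\ge 0}$ over diseases. Note there
is no separate trade-off weight between the score and disease reconstruction
terms: the two residuals enter with equal weight, so disease evidence can
also *override* score evidence (this is visible in the synthetic benchmarks
when the score signal is strong).

At test time the column-side factors ($S$, $G_Y$, $D$) are frozen and the
reduced objective is minimized over a fresh $V^{ts}$ (and warm-started
$U^{ts}$); the continuous prediction is
$y^{ts} = V^{ts} U^{ts} G_Y^\top$. Assumptions worth keeping in mind:

* each variant belongs to exactly one gene (multi-gene annotations must be
  resolved upstream);
* labels are complete 0/1 — there is no semi-supervised mode;
* the score matrix is complete after the missing-value filter; bounds for
  normalization always come from training data and test values are clipped
  into [0, 1].

## Solver

The supplementary update equations of the originating work are not
available, so the multiplicative rules are derived in the standard
graph-regularized way: each factor is multiplied elementwise by the ratio of
the positive to the negative part of its gradient, with the Laplacian split
as $L = \mathrm{Deg} - W$ so both parts stay non-negative (for example, for
$V$: numerator $R S U^\top + Y G_Y U^\top + \gamma_1 W_V V$, denominator
$V U (S^\top S + G_Y^\top G_Y) U^\top + \gamma_1 \mathrm{Deg}_V V$).
Denominators are guarded by `eps = 1e-10`. Correctness is enforced by
property tests: the objective trace must be non-increasing (within 1e-9
relative slack) on randomized instances of both algorithms, at train and
test time, and factors must stay non-negative.

Stopping: relative objective change below `tol` (default `1e-5`) or
`max_iter` (default 500) sweeps. Initialization is random-Acol — each column
of $V_0$ averages `acol_p = 5` random columns of $R$, each column of $S_0$
averages 5 random rows; $U_0, G_0 \sim \mathrm{U}(0,1]$ — which is fully
determined by `seed`. A single seed drives initialization and fold
shuffling, so every fit, prediction and cross-validation is reproducible.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k_V` | 10 | variant-cluster rank; grid `{5, 10, 20, 50}` in `grid_search()` |
| `k_S` | 3 | score-cluster rank; the nine constituent scores split naturally into functional/conservation groups |
| `k_D` | 5 | disease-cluster rank (three-source) |
| `gamma1, gamma2, gamma3` | 0.1 | Laplacian penalty weights for the V–V, S–S, D–D networks (dimensionless) |
| `tol`, `max_iter` | 1e-5, 500 | stopping rule |
| `acol_p` | 5 | columns averaged per factor column at initialization |
| `reuse_u` | FALSE | hold the trained core U fixed at test time instead of re-estimating it from a warm start |

The V–V construction gives every variant within-gene degree exactly 1
(pairwise weight $1/(n-1)$ for a gene with $n$ variants), so genes with many
variants do not dominate the Laplacian penalty, and the unnormalized and
random-walk Laplacians nearly coincide.

## Open design choices and how they were resolved

* **S–S edge weight.** The source text measures score–score connection by
  Manhattan distance, but a Laplacian *penalty* needs edge weight =
  similarity (it pulls strongly-connected nodes together; weighting by
  distance would pull the most dissimilar scores together). The stored
  weight is therefore $1 - d/m$; the raw distance matrix is kept in the
  graph metadata and `build_score_network(..., weight = "distance")` gives
  the literal reading.
* **Trace orientation.** The printed regularizers (e.g.
  $\mathrm{tr}(V L_V V^\top)$ with $V$ of size $m \times k_V$) are
  dimensionally inconsistent; the canonical forms
  $\mathrm{tr}(V^\top L_V V)$ etc. are implemented.
* **Shared core.** The label and relation reconstructions share one core
  $U$ (the factorization model dictates it), and test-time $U^{ts}$ is
  re-estimated from a warm start; `reuse_u = TRUE` freezes it instead.
* **Threshold selection.** "Best sensitivity and specificity" is
  operationalized as Youden's $J$, maximized over observed score values
  with ties broken toward the higher cut — and always on *training*
  predictions, never on test data.
* **Degenerate conventions.** Constant score columns normalize to 0.5 (an
  uninformative score should not push either way); precision /
  sensitivity / specificity with a zero denominator report 0 with a
  warning; MCC with a zero factor under the root is 0; AUC uses midranks
  for ties.
* **Disease Jaccard counts variants,** not genes, matching the stated
  definition of the association index.

## What the synthetic generator emulates

`generate_dataset()` produces the five input tables (scores with raw-scale
columns and pre-flip SIFT/LRT, STRING-dialect PPI, gene→protein map, labels,
gene–disease table) with:

* a planted rank-$(k_V^{true}, k_S^{true})$ non-negative co-cluster
  background rescaled into [0.2, 0.4];
* a per-gene deleteriousness propensity (half the genes lean deleterious,
  weight 0.8 vs 0.2) from which exactly `round(m * label_balance)` variants
  are drawn deleterious — so labels correlate with genes without being
  determined by them, and both "pure" and "mix" genes arise;
* an upward shift of `signal` (in normalized units) on deleterious rows,
  then a **shared per-variant noise** term (`variant_noise_sd = 0.15`) and
  per-cell noise (`noise_sd = 0.1`), clipped to [0, 1]. The shared term
  models the correlated part of the constituent tools' errors — the variants
  that fool one predictor tend to fool the others — and is what keeps the
  benchmark away from trivial perfect separability: without it, nine
  near-independent replicates of the shift make even weak signals perfectly
  recoverable, which matches neither the reported single-tool performance
  (AUC 0.7–0.9) nor the difficulty of real meta-prediction;
* a modular PPI graph whose gene modules coincide with the planted variant
  clusters (within-module edge density `ppi_density = 0.3`, confidence
  drawn above the 0.15 retention threshold; sparse weaker between-module
  edges at 5% of that rate);
* disease associations linking disease-leaning genes to one block of
  diseases and the remaining genes to the complementary block, for an
  `disease_informative_fraction` of genes, plus 10% uniform noise pairs.

What it does **not** emulate: allele-frequency spectra, mutation-type
composition, realistic inter-score correlation structure beyond the shared
noise term, hub-dominated PPI topology, or disease-ontology structure. A
green benchmark therefore establishes that the pipeline recovers planted
signal under leakage-free evaluation — not that it would reach the same
numbers on real annotation databases.

Two numerical caveats are deliberate: (i) clipping to [0, 1] compresses the
realized class shift near the interval edges, so the "mean deleterious −
neutral ≈ signal" contract is asserted at a moderate signal (0.3) where
clipping is negligible; (ii) generated PPI confidences are drawn strictly
above 0.15 so that ingest's strict retention threshold reproduces the edge
list exactly on round trip.

## Limitations

* The shared core and equal-weight residuals mean the three-source
  algorithm can underperform the two-source one when score evidence is
  strong and disease evidence is partly misleading; the benchmark with
  reduced score signal (0.3) shows the intended ordering.
* Multiplicative updates converge linearly; for very large m the
  projected-gradient family would be faster (out of scope here).
* Gene-aware folds require at least as many genes as folds; datasets with
  few genes need smaller `k`.
* Test-time scores are on the reconstruction scale of $V^{ts}U^{ts}G_Y^\top$
  and are comparable within a prediction run; the stored threshold from
  training transfers approximately (it is selected on training
  reconstructions), which is why threshold-free AUC is the primary metric.
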