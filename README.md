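# snmtfvar

Supervised non-negative matrix tri-factorization for classifying missense
variants as **deleterious** or **neutral**. The package is aimed at
variant-effect-prediction method developers and bioinformaticians who want a
meta-predictor that fuses three heterogeneous sources without an external
classifier:

1. a variant × score relation matrix built from nine published
   deleteriousness/conservation predictors (SIFT, Polyphen2, LRT,
   MutationAssessor, PROVEAN, GERP++, phyloP, phastCons, SiPhy);
2. a variant–variant network derived from protein–protein interactions
   (STRING-style edge lists);
3. gene–disease associations (DisGeNET-style tables), in the three-source
   variant of the algorithm.

## The model

Scores are oriented (SIFT and LRT become 1 − score) and min-max normalized
into [0, 1], giving the relation matrix `R_VS` (m variants × n scores). The
**two-source** algorithm jointly factorizes `R_VS` and the 0/1 label vector
`Y` over non-negative factors,

```
R_VS ≈ V U Sᵀ        Y ≈ V U G_Yᵀ
```

minimizing

```
J = ‖R_VS − V U Sᵀ‖²_F + ‖Y − V U G_Yᵀ‖²_F + γ₁ tr(Vᵀ L_V V) + γ₂ tr(Sᵀ L_S S)
```

where `L_V`, `L_S` are unnormalized Laplacians of the variant–variant and
score–score networks. V (m × k_V) and S (n × k_S) are cluster indicators, U
the cluster-interaction core, and factorizing `Y` alongside `R_VS` pulls the
variant clusters into alignment with the class structure — the supervision
needs no downstream classifier. The **three-source** algorithm adds a binary
variant–disease relation `R_VD ≈ V U₂ Dᵀ` and a Jaccard disease–disease
network penalty `γ₃ tr(Dᵀ L_D D)`.

Network construction rules:

* **V–V**: variants on the same gene with n variants are pairwise connected
  with weight 1/(n − 1) (each variant's within-gene degree is exactly 1);
  variants on different genes whose proteins interact with confidence c are
  connected with weight c (edges with confidence ≤ 0.15 are discarded).
* **S–S**: score columns are compared by Manhattan distance over variants;
  the stored edge weight is the similarity 1 − d/m (the raw distance is kept
  as metadata).
* **D–D**: the Jaccard index of the variant sets associated with each
  disease pair.

Training uses multiplicative updates (monotonically non-increasing
objective, non-negativity preserved); at test time `S`, `G_Y` (and `D`) are
frozen and a fresh `V` is fit to the test relation matrices, giving the
continuous deleteriousness score `yᵗˢ = Vᵗˢ Uᵗˢ G_Yᵀ`. Evaluation is
gene-aware: cross-validation folds never split a gene, which blocks the
train/test leakage ("type 2 circularity") that inflates gene-level
predictors.

## Worked example

Simulate the standard synthetic benchmark (40 genes, ~400 variants, nine
scores with planted co-cluster structure, a modular PPI graph and partially
informative disease associations), then cross-validate the two-source
algorithm with gene-aware folds:

```r
library(snmtfvar)

ds <- generate_dataset(synthetic_config(seed = 1))
ds
#> snmtf_synthetic: 409 variants on 40 genes, 9 scores, 30 diseases, 58 PPI edges

bundle <- as_bundle(ds)
hp <- snmtf_hyperparams(k_V = 10, k_S = 3, max_iter = 300)
cv <- cross_validate(bundle, hp, k = 5, repeats = 1, seed = 1)
round(cv$summary, 3)
#>              mean variance
#> accuracy    0.835    0.016
#> precision   0.982    0.001
#> sensitivity 0.699    0.033
#> specificity 0.982    0.001
#> f1          0.807    0.015
#> mcc         0.712    0.038
#> auc         0.965    0.002
```

Mean held-out AUC 0.965 says the learned factors rank unseen-gene
deleterious variants above neutral ones almost perfectly in this benchmark;
the threshold (chosen on training predictions by Youden's J) is
conservative here, trading sensitivity (0.70) for specificity (0.98).

The same workflow from the shell:

```sh
Rscript inst/cli/snmtfvar.R simulate --out data/ --seed 7
Rscript inst/cli/snmtfvar.R train    --data data/ --out model/ --algorithm three_source --seed 7
Rscript inst/cli/snmtfvar.R predict  --model model/ --data data/ --out preds.tsv
```

`preds.tsv` holds one row per variant: continuous score and the binary call
at the stored threshold.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch
against the installed package — it simulates the default benchmark,
cross-validates the two-source algorithm and runs a three-source held-out
evaluation — and writes its JSON report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
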