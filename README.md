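# genegate

Gene-pattern-gated neural networks for predicting cellular
radiosensitivity and survival after radiotherapy.

## The problem

Radiotherapy response varies widely between tumors, and gene-based
models are the standard route to predicting it — either the surviving
fraction of cells after a 2 Gy dose (SF2, a continuous value in
[0, 1] measured on cell-line panels) or overall survival of patients
treated with radiotherapy. Plain feedforward networks fit these data
but overfit easily and learn biologically arbitrary features: every
hidden node mixes every gene.

`genegate` implements a feedforward network whose first weight layer
is gated by a binary **selectively connected mask** (SCM)
`M ∈ {0,1}^(genes × nodes)`: effective first-layer weights are
`W1 ⊙ M`, so each first-hidden-layer node receives input only from
the genes the mask assigns to it. The mask is built so that *similar
genes feed the same node* — from the gene-side factor of a
non-negative matrix factorization of the input (`X ≈ WH`, rank =
first-layer width, `W` binarized at a global quantile cutoff), or
from the absolute encoder weights of a single-bottleneck autoencoder
when a prior gene-interaction network defined the panel. Hidden
layers use the SELU activation (λ = 1.05070098736,
α = 1.67326324235); the output node is a sigmoid for SF2 or `exp`
for survival.

Three costs are available, minimized by mask-preserving full-batch
gradient descent:

* quadratic cost `(1/2m) Σ (h_i − y_i)²` for SF2;
* **NLPL**, the Cox negative log partial likelihood over event risk
  sets, for survival;
* **PQC** (partial quadratic cost)
  `(1/2m) Σ_{i∈S} (h_i − T_i)²` with
  `S = {events} ∪ {censored with h_i < T_i}` — a censoring-aware
  squared error that costs O(m) per evaluation instead of the
  risk-set sums of NLPL, at equivalent predictive accuracy.

Around the core model the package provides per-sample rank
normalization of omics channels, Harrell's concordance index,
cross-validation with fold-internal mask construction, occlusion-based
gene importance, deep-ensemble epistemic uncertainty, a gene-pattern
reproduction diagnostic for the hidden layer, Cohen's-kappa validation
of the mask against a prior interaction network, and a synthetic
multi-omics generator with planted gene modules for end-to-end
validation.

## Worked example

Plant a 3-module panel (module 1 drives SF2), build the mask, fit,
cross-validate, and score genes by occlusion:

```r
library(genegate)

sim  <- generate_multiomics(n_genes = 60, n_modules = 3, n_samples = 200,
                            within_module_corr = 0.7, seed = 1)
sf2  <- generate_sf2(sim$truth, effect_size = 2, precision = 40, seed = 2)

mask <- build_scm(sim$X, K = 6, sparsity = 0.8, seed = 1)
mask
#> sc_mask: 60 genes x 6 nodes, sparsity 0.800

cfg    <- net_config("quadratic", learning_rate = 0.2, iterations = 3000, seed = 4)
folds  <- make_folds(200, "kfold", k = 5, seed = 3)
report <- cross_validate(sim$X, sf2, c(60, 6, 1), folds, config = cfg,
                         mask_builder = function(Xtr)
                           build_scm(Xtr, 6, sparsity = 0.8, seed = 1))
report
#> metric_report (rmse): mean train 0.0767, mean test 0.0954 over 5 folds
sqrt(mean((sf2 - mean(sf2))^2))   # constant-mean baseline
#> [1] 0.3263

model <- fit_network(sim$X, sf2, c(60, 6, 1), mask = mask, config = cfg)
occ   <- occlusion_test(model, sim$X, sf2)
head(occ[order(occ$rank), ], 5)
#>     feature      score rank
#> 19 Exp:G019 0.02559445    1
#> 20 Exp:G020 0.01659440    2
#> 13 Exp:G013 0.01349511    3
#> 5  Exp:G005 0.01289255    4
#> 18 Exp:G018 0.01156569    5
```

The gated network's held-out RMSE (0.095) is roughly a third of the
baseline (0.326), and 18 of the top 20 occlusion-ranked genes belong
to the planted informative module (genes G001–G020): occlusion scores
are the increase in RMSE when a gene's first-layer weights are zeroed,
so they directly measure each gene's contribution to the fit.

For survival, pass a `survival_data(time, event)` object and a
survival loss (`net_config("pqc")` or `"nlpl"`); predictions are
evaluated with `c_index()`, which handles the two losses' opposite
orientations (predicted time vs risk) automatically. Interpretation
tools follow the same pattern: `ensemble_uncertainty()` for M-member
deep-ensemble disagreement, `pattern_reproduction()` to check that
first-layer node groups reproduce their genes' sample similarity,
and `mask_kappa()` to compare the mask's connection profiles against
a prior gene-interaction edge list.

A thin command-line wrapper with `train`, `interpret`, `simulate` and
`evaluate` subcommands is installed at `inst/cli/genegate`; it drives
the same functions from flat YAML configurations.

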