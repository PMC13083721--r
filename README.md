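# ubiqtree

Uncertainty-decomposed SHAP explanations for bagged tree ensembles.

## The problem

SHAP values are the workhorse of feature attribution for clinical and
epidemiological tree-ensemble models (risk classes, length-of-stay
categories, survival status). But a single SHAP value is a point estimate:
it hides how much the attribution would change under a slightly different —
yet equally plausible — realization of the model. For high-stakes decisions
that hidden variability matters: a feature can look decisive while its
attributed direction flips between sub-models.

`ubiqtree` treats each tree of a bagged ensemble as one hypothesis about
feature attribution and quantifies how much those hypotheses disagree:

1. **Base measure.** Each tree k gets an out-of-bag accuracy a_k, mapped to
   a simplex weight `w_k = exp(β a_k) / Σ_j exp(β a_j)`.
2. **Hypothesis sampling.** Sub-ensembles are drawn from the Dirichlet
   posterior over trees: `π ~ Dirichlet(α w)`, tree indices
   `~ Categorical(π)` with replacement. Small `α` concentrates draws on few
   high-weight trees; large `α` tracks the base measure.
3. **Exact SHAP.** Interventional (background-marginalized) Shapley values
   of each tree's per-class score are computed exactly per tree, and
   verified in the test suite against a brute-force subset-enumeration
   oracle.
4. **Variance decomposition.** Per feature, with μ_s and σ²_s the
   within-sample mean and variance of SHAP across the trees of hypothesis
   sample s:
   - aleatoric `A = mean_s(σ²_s)` — irreducible within-hypothesis spread,
   - epistemic `E = Var_s(μ_s)` — disagreement between hypotheses,
   - entanglement `C = Cov_s(μ_s, σ²_s)` — the model–data coupling term,
   - `total = A + E − C`.
5. **Uncertainty report.** Per feature and class: mean SHAP, std, 95%
   percentile credible interval, differential entropy (KDE), sign
   stability with high/moderate/low categories, and a σ-based action flag
   (automated ≤ 0.05 < expert verification ≤ 0.1 < retrain).
6. **Evidence layer.** A Dempster–Shafer mass function over a partition of
   the SHAP range (each sub-ensemble is one evidence source) yields belief,
   plausibility and an explanation-conflict score; an empirical uncertainty
   distribution Γ provides entropy and a variance-driven data-acquisition
   ranking.

## Worked example

```r
library(ubiqtree)

ds  <- make_dataset(scenario_config(n_rows = 300, seed = 7))   # known truth: x1..x4 informative
fit <- ubiqtree(y ~ ., cbind(ds$X, y = ds$y),
                n_trees = 20, n_samples = 10, n_explain = 30, seed = 7)
fit
#> ubiqtree explanation fit
#>   trees K = 20 | hypothesis samples S = 10 | alpha = 0.5 | beta = 5
#>   classes: c1, c2, c3
#>   features: 10 | explained instances: 30 | background rows: 128
#>   mean per-tree OOB accuracy: 0.579

summary(fit, top_n = 2)
#> Top features per class (importance = mean |SHAP| across hypothesis samples)
#>
#>  class feature mean_shap    std  ci_low ci_high ... sign_stability stability_category
#>     c1      x1    0.1123 0.0268  0.0762  0.1560 ...            1.0               high
#>     c1      x4    0.0289 0.0189  0.0028  0.0558 ...            1.0               high
#>     c2      x1   -0.0711 0.0166 -0.0902 -0.0407 ...            1.0               high
#>     ...
#> Importance-vs-uncertainty entanglement correlation (Pearson rho):
#>    c1    c2    c3
#> 0.915 0.806 0.895
```

Reading this: `x1` (the strongest true signal) carries the largest mean
|SHAP| for every class, its sign never flips across the 10 hypothesis
sub-ensembles (sign stability 1.0, category `high`), and its 95% credible
interval for class c1, [0.076, 0.156], excludes zero. The entanglement
correlations near 0.9 say the features this forest leans on hardest are
also the ones whose attributions vary most between sub-models — the
importance–uncertainty coupling the decomposition is designed to expose.

Per-feature variance components live in `fit$decomposition`
(aleatoric/epistemic/entanglement/total), the belief layer in
`fit$evidence`, figures via `plot(fit, type = "summary" | "distribution" |
"entanglement")`.

A file-based pipeline with report bundle (report.csv, decomposition.csv,
evidence.json, entanglement.json, manifest.json, PNG figures) is available
as `run_ubiqtree()`, or from a shell:

```sh
Rscript inst/cli/ubiqtree.R synth --preset baseline --out data/
Rscript inst/cli/ubiqtree.R run --data data/data.csv --target y --out out/ --seed 42
```

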