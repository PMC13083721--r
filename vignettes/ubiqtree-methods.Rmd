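---
title: "How ubiqtree quantifies uncertainty in SHAP explanations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How ubiqtree quantifies uncertainty in SHAP explanations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A bagged classification forest is not one model but K of them. Each tree
was grown on its own bootstrap sample and encodes its own opinion about
which features matter; the forest's SHAP attribution is the average of K
per-tree attributions that may disagree in magnitude and even in sign.
`ubiqtree` makes that disagreement measurable instead of averaging it away.

The machinery has four layers.

**Out-of-bag base measure.** Tree k is scored on its out-of-bag rows
(the training rows missing from its bootstrap sample): `a_k` is the
fraction it classifies correctly (argmax of its class-score vector; ties
resolve to the lowest class index, for determinism). The accuracies map to
a probability simplex through a softmax with temperature β,

$$w_k = \frac{e^{\beta a_k}}{\sum_j e^{\beta a_j}},$$

computed with max-subtraction so large β cannot overflow. β = 0 gives
uniform weights; the weights are invariant to adding a constant to every
accuracy. A switch substitutes the per-tree one-vs-rest AUC for accuracy
when a rank-based score is preferred. When an ingested ensemble carries no
bootstrap record, a user-supplied held-out set scores every tree instead —
per-tree OOB membership is not recoverable from tree structure alone. A
tree whose OOB set is empty falls back to the full training data with a
warning.

**Dirichlet hypothesis sampling.** A hypothesis sample is one plausible
reading of the forest: a simplex draw π ~ Dirichlet(α·w) followed by
`n_draw` tree indices drawn i.i.d. from Categorical(π) with replacement.
E[π] = w for every α, while α controls concentration: for α ≪ 1 a single
draw piles its mass on very few (high-weight) trees, for α ≫ 1 the draws
hug the base measure. We implement this mathematical behavior directly and
expose `effective_diversity()` (the exponential of the Shannon entropy of
the sampled tree frequencies) so users can observe the realized
exploration–exploitation balance rather than trust a verbal gloss; prose
descriptions of the "direction" of α in the literature are inconsistent,
the Dirichlet density is not. `n_draw` defaults to K — the
Bayesian-bootstrap convention, which keeps sub-ensemble prediction variance
comparable to the parent forest. Dirichlet parameters are floored at 1e-8
before drawing (gamma-sampler stability), and each sample gets its own RNG
substream derived from the root seed, so raising the number of samples
never perturbs the ones already drawn.

**Exact interventional SHAP per tree.** For a tree, an instance x, and a
background set B, the value function of a coalition S is the tree output
with features in S fixed to x and the rest marginalized over B. For a
decision tree this Shapley value is computable exactly: a leaf is reached
under coalition S iff every deciding feature on its path takes the correct
source, and summing Shapley weights over the non-deciding ("free")
features collapses to the closed form
`(p−1)! n! / (p+n)!` (and its mirror), where p and n count the
path features that must, respectively, be inside and outside the
coalition for that background row. We chose the interventional convention
over path-dependent TreeSHAP deliberately: it is the convention with a
clean independent oracle. The test suite checks the implementation against
`brute_force_shapley()` — direct subset enumeration of the defining
Shapley average, feasible up to 12 features — at 1e-8 on randomly generated
trees, and checks local accuracy (Σφ + base = f(x)) on every tensor cell.

For a sub-ensemble, per-tree SHAP vectors (a tree drawn twice counts
twice) give the mean attribution φ_mean, the between-tree feature
covariance Σ (population convention), and the interaction-adjusted
φ_adj = φ_mean + 0.5·diag(Σ). φ_adj deliberately breaks local accuracy —
it shifts magnitudes by half a variance — so it is reported as a separate
column and never fed into the decomposition, which consumes the raw
per-tree distributions.

**Decomposition and reporting.** With μ_s and σ²_s the within-sample mean
and variance (population convention throughout, so the identity tests are
exact):

- aleatoric A = mean_s σ²_s,
- epistemic E = Var_s μ_s,
- entanglement C = Cov_s(μ_s, σ²_s),
- total = A + E − C.

A positive C means the hypotheses that attribute more to a feature are
also the ones whose trees disagree most about it — aligned uncertainty
sources, which *reduce* the corrected total. When model sampling is
independent of the data the covariance term vanishes; see the note on
testing this below. The decomposition runs per explanation instance and
the components are averaged over the instance set for the class-level
report (the order of aggregation is a genuine choice; per-instance output
remains available via the lower-level functions).

The per-feature report row summarizes the S per-sample mean attributions:
mean, population std, 95% percentile interval (type-7 linear
interpolation), differential entropy, and sign stability — the fraction of
samples agreeing with the majority sign, zeros counted with the majority,
exact ties scored 0.5. Sign stability maps to categories at the monotone
cuts 0.90 and 0.67, and the epistemic σ maps to an action tier at 0.05
and 0.1 (automated / expert verification / retrain). Both printed
threshold sets circulating for these rules are internally inconsistent as
stated; the monotone readings implemented here are the only orderings
under which the worked examples (e.g. stability 97.2% labeled high, 46.5%
labeled low, σ = 0.133 flagged for retraining) come out right.

## The evidence layer

The observed SHAP range is cut into M equal-width cells (default M = 10 —
small enough that 20–50 sub-ensembles give several values per cell, large
enough to resolve sign and magnitude structure; configurable). Each
hypothesis sample is one evidence source whose focal element is the *set*
of cells its per-tree values hit. A source whose trees agree lands in one
cell and contributes singleton (Bayesian) mass; a dispersed source
contributes genuinely set-valued evidence. This set-valued construction
matters: a purely additive cell-count assignment would make belief equal
plausibility everywhere and the conflict measure identically zero. With
it, belief (mass of focal elements inside a cell set) and plausibility
(mass of those intersecting it) bracket the evidence, the duality
Bel(A) + Pl(Ω∖A) = 1 holds exactly, and the conflict score
max_j [Pl(I_j) − Bel(I_j)] is a meaningful per-feature ambiguity flag.
With many single-value sources, singleton belief converges to the cell
probability — the tests check this convergence explicitly. Values that
fall outside a partition built from other data clamp to the nearest cell
with a warning rather than failing the run.

The empirical uncertainty distribution Γ (an ECDF over the per-sample
attributions) satisfies its three defining laws by construction — zero
below the observed minimum, one at the maximum, monotone — and its
density's differential entropy, estimated with the same KDE as the report
column, summarizes attribution dispersion. Because the marginal entropy
reduction from new data scales with a feature's attribution variance,
features rank for data acquisition by variance, entropy breaking ties.
Combining mass functions across features (Dempster's rule) is out of
scope; no combination is performed.

## Numerical choices

- **Entropy estimator.** Gaussian KDE with Scott's-rule bandwidth
  `(4/3)^{1/5} sd(x) n^{-1/5}`, 512-point grid spanning exactly the
  observed range, density renormalized to integrate to one on that grid,
  then −∫ p log p by the rectangle rule. The renormalized, range-limited
  grid is a boundary correction: letting the grid extend past the sample
  range counts kernel mass smoothed beyond the support and inflates the
  entropy of compactly supported distributions by ~0.1 nats at n = 5000 —
  twice the estimator's validated tolerance. As implemented, the estimator
  is within 0.05 nats of the closed forms for Uniform(0,1), Uniform(0,2),
  and Normal(0,1) at n = 5000, is translation-invariant, and respects
  H(aX) = H(X) + log a. Zero-spread input returns a −Inf sentinel flagged
  degenerate; fewer than 10 values return NA in the report.
- **Population moments everywhere** (variance, covariance, std), so the
  law-of-total-variance and hand-arithmetic identities in the tests hold
  to machine precision rather than up to n/(n−1) factors.
- **Degenerate cases.** Single-tree sub-ensembles define Σ = 0; an
  all-equal sample makes a single-cell partition flagged degenerate;
  degenerate entanglement correlations (zero-variance vectors) return NA
  with a flag instead of NaN.
- **Determinism.** One root seed drives the train/test split, forest,
  background subsample, explanation subsample, and every Dirichlet
  substream. Two runs with equal manifests produce byte-identical report
  files; the manifest records configuration and library versions, no
  timestamps.

## The synthetic study conditions

The generator emulates the tabular clinical settings the method targets:
i.i.d. rows, mixed numeric and label-encoded categorical features,
multiclass labels from a softmax of sparse linear logits, optional uniform
label flipping, controllable class imbalance, and exact duplicate columns
for collinearity studies. Class intercepts are log class ratios so the
no-signal case reproduces the target marginals. The baseline scenario
(n = 1000, d = 10, 4 informative features with coefficients
1.8 × (1.6, 1.3, 1.0, 0.8), 3 balanced classes) was calibrated once, by
Monte-Carlo integration of the true softmax, to a Bayes accuracy of about
0.85 — high enough that a forest finds the signal, low enough that label
noise and sample-size sweeps leave visible headroom — and then frozen.
Preset sweeps cover label noise (0–0.3), training size (200–2000), a
60/20/15/5 four-class imbalance, and duplicated features.

What the generator does *not* emulate: longitudinal or hourly structure,
missingness, measurement error correlated with class, or realistic
categorical cardinalities. Tests passing on these scenarios demonstrate
that the estimator machinery behaves as theory predicts under known
ground truth; they do not certify behavior on any particular clinical
dataset.

## Testing the independence null

The claim "the covariance term vanishes when model and data are
independent" is an expectation over model draws. Conditionally on one
realized forest it is generally false: resampling from a fixed, finite
population of per-tree attributions gives Cov(mean, variance)
proportional to that population's empirical third moment, and a trained
forest's dozen trees do not have zero empirical skewness. Averaging more
replicates shrinks the standard error but not this bias, so the näive
version of the check fails for the wrong reason. The suite therefore
verifies the null on a forest that is symmetric by construction — trees in
mirrored pairs whose leaf values are swapped, making the per-tree
attribution population exactly sign-symmetric and E[C] = 0 an identity
under exchangeable Dirichlet sampling. Under uniform weights and 200
seeded sampling replicates, every feature's mean entanglement lies well
within three standard errors of zero.

## Problem sizes used by the test and acceptance runs

Unit tests run on hand-built stumps, a 12-tree forest over 300 rows, and
small Monte-Carlo panels (200–5000 draws). The oracle comparison uses 50
random trees × 5 instances × 2 classes. The monotonicity sweeps use 10
seeds per condition with 25-tree forests, 10 hypothesis samples, 15
explained instances, and 48 background rows. The end-to-end determinism
check and the acceptance script run the full baseline scenario: n = 1000,
d = 10, K = 50, S = 20, 128 background rows, 200 explained instances.
These sizes are the package's reference configuration for desk-scale
reproduction; all of them are plain function arguments and scale up
freely.

## Known limitations

- Only bagged ensembles are first-class; boosting-specific weighting is
  out of scope.
- The interventional value function is the verified path; path-dependent
  TreeSHAP conventions will differ where features are correlated.
- The report's entropy column needs at least 10 hypothesis samples; S = 2
  still yields means, intervals and the decomposition, with entropy NA.
- Mean-versus-variance entanglement is a covariance, not a causal
  statement; its class-level value depends on the explanation instance
  set.
- The decomposition's estimator targets the conceptual
  aleatoric/epistemic/entanglement split through per-sample moments; the
  expectation-level identity and its finite-sample estimator are distinct
  objects, and no attempt is made to force them equal.
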