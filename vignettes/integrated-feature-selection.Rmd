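---
title: "Integrated vegetation-index feature selection for yield prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated vegetation-index feature selection for yield prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viselect)
```

## The problem

UAV multispectral surveys of field trials deliver, after photogrammetric
processing and zonal statistics, one mean reflectance per plot in five bands:
blue, green, red, red edge and near infrared. Dozens of vegetation indices —
arithmetic combinations of these bands such as NDVI = (NIR − R)/(NIR + R) —
are candidate predictors of plot yield, but they are highly redundant (many
are monotone transforms of one another) and not all of them track yield in a
given trial. Feeding all of them to a regression model wastes its capacity on
noise and collinearity. `viselect` implements an integrated feature-selection
workflow that combines the three classic selector families:

1. **Filter** — rank indices by the absolute Pearson correlation
   $|r(x, y)| = |\mathrm{Cov}(x,y)| / \sqrt{\mathrm{Var}(x)\mathrm{Var}(y)}$
   with yield and keep those strictly above a threshold (default 0.53).
2. **Embedded** — rank indices by random-forest permutation importance
   (out-of-bag increase in MSE when a feature is permuted, normalized
   %IncMSE scale) and keep those strictly above a threshold (default 1.9).
3. **Wrapper** — take the union of the two retained sets and refine it by
   recursive feature elimination (RFE): repeatedly drop the least important
   feature of a base regressor, score each candidate subset by inner
   cross-validated RMSE, and stop after a *patience* budget (default 10) of
   consecutive non-improving eliminations, keeping the best subset seen.

Accuracy is then assessed by k-fold cross-validation (default k = 10) of the
base models on six subsets: all 35 indices, the filter subset, the embedded
subset, their union and intersection, and the integrated (RFE-refined)
subset.

## The index library and its dialects

The 35-formula library is carried verbatim from the source compilation,
including its quirks, because reproducing a published feature set exactly
matters more than tidying it. The default `"as_printed"` dialect therefore
evaluates, for example, TVI as NDVI + 0.5 (no square root), CCCI as the
chained division (NIR−RE)/(NIR+RE)/(NIR−R)/(NIR+R) interpreted
left-associatively, and the tabulated ATSAVI/IVI/NLI/WDRVI coefficient
variants. The `"corrected"` dialect substitutes standard literature forms
only where the printed form is a known typographic variant — TVI =
√(NDVI + 0.5) and CCCI = NDRE/NDVI — and changes nothing else; the printed
TCARI and MCARI already match their standard definitions. Three
consequences of the printed forms are worth knowing:

* GCI ≡ CIg and RECI ≡ CIre are duplicate formulas, kept as separate
  (perfectly collinear) columns because downstream feature counts treat
  them as distinct.
* MRVI = (NIR/R − 1)/(NIR/R + 1) is algebraically identical to NDVI, and
  the as-printed TVI is NDVI + 0.5; correlation-based rankings therefore
  always score NDVI, TVI and MRVI identically.
* Zero denominators yield missing values, never clamped or sentinel values
  — silent clamping would corrupt the rankings downstream. `compute_all()`
  flags affected rows and counts missing values per index.

Index names are matched case-sensitively against the canonical list
(`vi_names()`), whose order is also the tie-break order everywhere.

## Design decisions in the selector

**|r|, not signed r.** Indices that correlate *negatively* with yield (the
redness family RI, NormR, RGR) are as predictive as positive ones, so the
filter threshold acts on the magnitude.

**Importance scale.** The 1.9 embedded threshold lives on the normalized
%IncMSE scale of a regression forest (500 trees, mtry = ⌊p/3⌋). Absolute
importance scales are data-dependent, so the threshold is an ordinary
argument; for a different dataset a quantile rule (keep the top q) may be
more appropriate, which `apply_threshold()` supports trivially by passing a
quantile of the ranking as `tau`.

**Strict thresholds.** "Exceeding" a threshold means strictly greater:
a feature scoring exactly 0.53 is dropped.

**RFE scoring.** Whether RFE "performance" should be training or
cross-validated error is an open choice; we score candidate subsets by
inner k-fold CV RMSE (default 10 folds, fold assignment fixed once per run
so successive iterations are comparable), and an elimination counts as an
improvement only if it beats the best RMSE seen by more than 1e−9, so
floating-point jitter cannot reset the patience counter. Per-iteration
importance comes from the base model itself: attribute usage frequency
(share of rules using a feature in a condition or regression) for the rule
tree, permutation importance on the training data for the network. Ties are
broken by canonical index order, with the later-table feature dropped first.

## Base regressors

**Rule-based model tree.** The Cubist/M5 family regressor partitions by
maximizing standard-deviation reduction (children of at least 2 rows, nodes
of at least 4 rows, growth stops when a node's response SD falls below 5%
of the root SD), fits an OLS model per node restricted to the attributes
tested in its subtree, prunes bottom-up by complexity-corrected mean
absolute error (factor (n + v)/(n − v)), and smooths predictions along the
root-to-leaf path with the classic (n·p_child + k·p_node)/(n + k) blend,
k = 15. A dataset admitting no split reduces exactly to one global OLS
regression — a property the tests pin against the normal equations. We run
a single committee with no instance-based correction; rank-deficient region
regressions drop aliased terms, falling back to the region mean if the fit
fails outright. `model_spec("cubist")` is deterministic: no seed affects it.

**Recurrent-network regressor.** The reference work uses a plain recurrent
network on tabular features without describing how a feature vector becomes
a sequence; we adopt the smallest arrangement consistent with a
three-layer RNN diagram: the d features, in canonical index order, are fed
as a length-d sequence of scalars to a single tanh recurrent layer (hidden
size 32, recurrent matrix initialized near the identity so gradients
survive 35 steps), and the final hidden state feeds a linear output.
Training is full-batch backpropagation through time with Adam (lr 0.01),
global gradient-norm clipping at 5, at most 500 epochs, and early stopping
on a held-out 15% split with patience 25, restoring the best checkpoint.
Features and response are z-scored internally from the training data; the
rule tree, by contrast, consumes raw features (tree partitions are
scale-equivariant). Everything stochastic — the validation split, the
initialization — derives from the model seed, so fits are bit-reproducible.

## The synthetic trial generator

Plot-level data of the motivating design are not publicly available, so the
generator is the package's test bed. It emulates a four-treatment
water-stress trial (W1 severe drought … W4 extreme surplus), 10 cultivars ×
3 replications per treatment = 120 plots, with per-treatment yield means
(7.77, 8.32, 8.97, 8.19 t/ha) and SDs (1.56, 1.39, 1.19, 1.26 t/ha) taken
from the reference trial's descriptive statistics. Per plot, a latent
canopy vigor v is drawn from a treatment-shifted standard normal; yield is
the treatment mean plus a vigor share s·z and residual share √(1−s²)·ε,
scaled so the treatment SD matches the configuration after adding cultivar
random intercepts (SD 0.3 t/ha, motivated by the cultivar spread of such
trials), truncated below at 0.1 t/ha (inactive in practice — the reference
minimum is 3.35 t/ha).

Signal enters through the *bands*, not through individual indices: red
decreases and NIR increases with v such that the NDVI response is exactly
linear in v, while three further independent latent axes — soil-background
brightness in red, greenness, and red-edge level — vary between plots
without tracking yield. The consequences are deliberate:

* whole index families become informative together, with a wide spread of
  index-yield correlations (roughly 0.15–0.90 at the default signal 0.9),
  as in real trials — so the filter and embedded stages retain mid-size
  subsets and the wrapper has genuine redundancy to remove;
* the planted (informative-by-construction) set is the exact-duplicate
  family of the NDVI response — NDVI, TVI and MRVI — which is the only set
  whose top ranking is stable across seeds, because any non-duplicate
  competitor is a strictly more curved transform of v;
* at signal 0 the planted indices decouple from yield entirely.

The default signal strength 0.9 encodes a strong but not noise-free
canopy-yield coupling; band noise SD 0.005 is typical of plot-mean
reflectance. One global seed drives a per-plot counter-based substream, so
record order can never change results. What the generator does *not*
emulate: radiative transfer (bands are phenomenological), inter-band
covariance structure of real canopies, spatial autocorrelation between
neighbouring plots, and cultivar × treatment interactions. Passing
recovery tests on these trials therefore demonstrates the selectors'
mechanics — not field-level validity on real imagery.

A second, index-level generator (`simulate_planted_vitable()`) plants an
exactly known number of informative columns (loading √0.7 on a shared
factor that drives yield) among pure-noise columns. It bypasses the band
model and exists for selector benchmarking, where "3 informative among 32
noise" must be literally true.

## Numerical and testing choices

* Quartiles use linear interpolation (R type 7); the sample SD uses n − 1.
* Treatment comparisons are two-sided Welch tests (treatment variances
  differ materially in such trials); p-values are reported raw, with Holm
  adjustment available but off by default.
* Cross-validation partitions are simple random with a fixed seed;
  stratification by treatment is available as an argument.
* Model serialization writes every double as a 17-significant-digit
  decimal string, which round-trips IEEE doubles exactly; reloaded models
  predict bit-identically.
* Test problem sizes are chosen to keep the full suite to a few minutes:
  recovery properties run 100 seeds at n = 150 on the index-level
  generator, the selection-helps-accuracy property runs 20 seeds at the
  default 120-plot design, and the determinism check runs the full
  pipeline twice at reduced fold/epoch counts (determinism does not depend
  on problem size). The acceptance script mirrors these sizes.

## Known limitations

* The headline accuracies of the motivating study are not reproducible
  here by design — they depend on restricted field data; on synthetic
  trials the package verifies the *direction* of its claims (integrated
  selection does not hurt, and typically helps, rule-tree accuracy).
* The recurrent regressor is a faithful small baseline, not a tuned deep
  model; on 120-plot tables it is consistently the weaker base model, as
  in the reference work.
* The flowering-stage set-combination bookkeeping reported by the
  reference (16- and 20-member subsets sharing 10, union 25) is internally
  inconsistent with inclusion–exclusion; `combine_subsets()` follows set
  arithmetic.

## A worked example

```{r, eval = FALSE}
library(viselect)

trial <- simulate_experiment(sim_config(seed = 1))
vit <- compute_all(trial$plots)
sel <- pcrf_rfe(vit, trial$plots$yield_t_ha, config = rfe_config(seed = 1))
print(sel)
summary(sel)   # RFE score trace

cv <- kfold_cv(vit, trial$plots$yield_t_ha, subset = sel,
               spec = model_spec("cubist"), k = 10, seed = 1)
print(cv)

run <- run_pipeline(trial$plots, run_config(seed = 1))
print(run)     # 6 subsets x 2 models accuracy grid
```
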