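---
title: "Modelling tree richness from environment and attributing its drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tree richness from environment and attributing its drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Local (plot-scale) tree species richness in tropical forests varies by an
order of magnitude, and a central question in macroecology is how much of
that variation is predictable from contemporary environmental conditions —
and which *kind* of condition (temperature, precipitation, growing season,
solar radiation, soil or topography) dominates where. `richdrivers`
implements a complete, testable pipeline for this question on networks of
standardized one-hectare inventory plots:

1. estimate per-plot α diversity from stem abundance data;
2. model richness from environmental covariates with a random forest,
   optionally augmented with Moran eigenvector spatial predictors, and with
   a negative-binomial GLM as an interpretable counterpart;
3. attribute each plot's predicted richness to a dominant driver category
   through a leave-one-category-out sensitivity procedure, with a
   *co-limitation* label where no single category dominates.

Because real pantropical plot data are not redistributable, the package
ships a synthetic plot-network generator with known ground truth, so every
stage can be validated end to end.

## Diversity estimation

For a plot with `S` species among `N` stems the package computes:

* **Fisher's α**, the diversity parameter of the log-series abundance
  model, defined implicitly by `S = α·ln(1 + N/α)`. The left side minus
  the right side is strictly monotone in α, so the package solves it by
  bracketing and bisection to an absolute tolerance of 1e-8. When `S = N`
  (all singletons) no finite root exists and the plot is flagged rather
  than dropped.
* **Sample coverage** `Ĉ = 1 − (f1/N)·(N−1)f1 / ((N−1)f1 + 2f2)`, the
  estimated fraction of the community's individuals belonging to species
  already observed (`f1`, `f2` = singletons, doubletons); exactly 1 when
  `f1 = 0`.
* **Coverage-standardised richness.** Richness is compared across plots at
  a common coverage rather than a common number of stems. Below the plot's
  own coverage the integer size-to-coverage map is inverted (binary search
  plus linear interpolation between adjacent sizes) and the classical
  hypergeometric rarefaction expectation is used; above it, Chao1-based
  extrapolation, with the bias-corrected `f1(f1−1)/(2(f2+1))` form of the
  undetected-species estimate wherever `f2 = 0`. The default common
  coverage is the *minimum* of the plots' own coverages, so no plot is
  extrapolated by default; this choice is overridable. Extrapolation past
  twice the observed sample size is flagged.

## The forest models

`fit_rf()` grows a bootstrap ensemble of regression trees (ranger;
defaults 500 trees, `mtry = ⌈p/3⌉`, minimum node size 5, one thread,
seeded). Model quality is reported as out-of-bag R²: each plot is
predicted only by trees that did not sample it, which is essential here
because in-bag forest predictions nearly interpolate the training data.
Permutation importance (mean increase in out-of-bag error when one
predictor is permuted) is floored at zero.

`fit_spatial_rf()` addresses the fact that inventory plots are spatially
clustered and their residuals autocorrelated. Moran eigenvector maps
(MEMs) are computed from the great-circle distance matrix using the
principal-coordinates-of-neighbour-matrices convention: distances beyond a
truncation radius (default: the longest minimum-spanning-tree edge, the
smallest radius that keeps the graph connected) are replaced by four times
the truncation, similarities `1 − (d*/max d*)²` are double-centred and
eigendecomposed, and eigenvectors with positive eigenvalues become
candidate covariates. Candidates are ranked by their Moran's I and
forward-selected while the absolute Moran's I of the out-of-bag residuals
decreases and the out-of-bag R² does not fall more than 0.005 below the
non-spatial fit; if the non-spatial residuals are already non-significant
(permutation p ≥ 0.05) nothing is added. Two deliberate choices:

* Residual autocorrelation is judged with the package's default Moran
  weights — inverse distance truncated at the 25th percentile of pairwise
  distances, row-standardised — not with the MEM connectivity radius. On a
  multi-continent network the spanning-tree radius includes the
  inter-continental bridges, which dilutes Moran's I towards zero and
  would blind the selection to strong *local* autocorrelation.
* Base and trial forests in the forward selection share one fixed set of
  bootstrap in-bag samples, so the R² comparison is paired and the
  selection rule's tolerance is meaningful.

The negative-binomial GLM (`fit_nb_glm()`, NB2 with log link, dispersion
estimated by maximum likelihood via `MASS::glm.nb`) is the interpretable
counterpart: region main effects and optional region × environment
interactions are encoded as explicit dummy columns so that spatial
cross-validation folds that exclude an entire region still yield defined
(baseline) predictions. Its predictive quality is reported as R² on
spatially blocked cross-validation folds — the same folds used for the
forest — because a GLM has no out-of-bag observations. In the Poisson
limit the ML dispersion estimate diverges; the fit then falls back to the
nested Poisson GLM with `theta = Inf` and is flagged.

Spatial folds come from k-means on unit-sphere coordinates (chord distance
orders pairs identically to great-circle distance), which keeps folds
spatially coherent on irregular plot networks where regular blocks would
be empty. Distance-based thinning uses randomised greedy elimination with
restarts and always returns a set satisfying the minimum-distance
constraint.

### Variable screening

`vif_screen()` iteratively removes the predictor with the largest variance
inflation factor until all are at or below the threshold (default 10),
breaking ties towards the later column. `boruta_screen()` implements the
shadow-feature idea: each iteration appends a permuted copy of every
predictor, fits the forest, and scores each real predictor against the
*maximum* shadow importance; confirmation/rejection uses two-sided
binomial tests with Bonferroni correction (conservative and in the spirit
of the original algorithm).

`suggest_interactions()` encodes a candidate pairwise interaction as the
first principal component of the standardised pair (named `a..pca..b`) and
keeps it only if it improves out-of-bag R². The required margin defaults
to 0.025: on networks of a few hundred plots the *chance* improvement from
adding an uninformative column has a standard deviation near 0.01 (we
measured this on pure-noise responses), so a 0.01 margin would admit noise
interactions in roughly a fifth of runs. The improvement is additionally
averaged over five paired bootstrap replicates to remove forest Monte
Carlo noise from the comparison.

## Driver attribution (the core procedure)

Variables belong to six categories: E1 temperature, E2 precipitation, E3
growing season, E4 solar radiation, E5 soil, E6 topography. With `f` the
fitted forest and `X(s)` the predictors at plot `s`:

1. predict `Y_all(s) = f(X(s))` from the full model;
2. for each category `Ek`, refit the model *from scratch* on all variables
   except those charged to `Ek` and predict `Y_−Ek(s)`;
3. compute the relative sensitivity `R(Ek) = |Y_all − Y_−Ek| / Y_all`;
4. label the plot with the category of largest `R` provided that maximum
   reaches the threshold 1/7;
5. if all six sensitivities fall below 1/7, label the plot E7,
   *co-limitation*: no single type of environmental factor dominates
   there.

Design choices where the procedure is underdetermined:

* **Out-of-bag predictions are used for both `Y_all` and `Y_−Ek`.**
  In-bag forest fits nearly interpolate, which would drive every `R`
  towards zero and label everything co-limited by construction.
* **Full refit, not prediction-time masking.** Withholding a category must
  let the model redistribute weight onto the remaining variables, as a
  genuinely reduced model would.
* **Interaction columns (`a..pca..b`) are charged to both parents'
  categories** and removed when either is withheld; MEM columns belong to
  no category and are never removed — they encode space, not environment.
* **Ties** at the maximal `R` break by the fixed order E1→E6 (ties are
  measure-zero but determinism matters).
* **The plot is the unit of classification.** Gridding or smoothing labels
  into continuous maps is out of scope; the GeoJSON export lets users grid
  downstream. The 1/7 comparison is applied per plot.

`category_shares()` and `band_profiles()` aggregate the labels globally
and along 2° latitude/longitude bands (half-open `[lo, lo + band)`
intervals anchored at integer multiples of the band width; a plot exactly
on a boundary belongs to the upper band).

## The synthetic plot network

The generator emulates the structure of a pantropical inventory network
while keeping the truth known:

* **429 plots** split 197/150/82 across three regional boxes (Americas,
  Africa, Asia) inside the tropical belt, placed uniformly within each
  box.
* **24 environmental variables in six categories**, each a Gaussian random
  field over the plot locations with exponential covariance
  `exp(−d/ρ)` (`ρ` = 500 km by default), simulated exactly by Cholesky
  factorisation with a 1e-8 diagonal jitter. Region-specific mean offsets
  are concentrated on the moisture variables and soil pH, so ordination of
  the generated fields separates regions along a moisture axis — the
  qualitative regional structure seen in real pantropical networks.
  Variables are mutually independent apart from these offsets, which is
  the main idealisation relative to real climate surfaces (where variable
  blocks are strongly cross-correlated): passing tests therefore
  demonstrate method correctness, not robustness to real-world
  collinearity.
* **Ground truth:** `log α_true = intercept + Σ coef·variable + noise`.
  Three presets: `single-category` (one strong precipitation driver,
  +0.6), `two-category` (the default study-like condition: precipitation
  +0.30 and soil pH −0.22 on `log α`, intercept `log 50`, residual sd
  0.08) and `balanced-all` (weights of 0.08 on one variable from each
  category, so that no category dominates and the expected attribution is
  co-limitation).
* **Communities** are sampled by a Hoppe urn (Chinese-restaurant process)
  with parameter `θ = α_true`: stem `i+1` founds a new species with
  probability `θ/(θ+i)`. This is the exchangeable analogue of a log-series
  community and has the exact expected richness
  `Σ_{i<n} θ/(θ+i)`, which makes the generator testable against a closed
  form. Stem counts per plot are `round(Normal(600, 100))` truncated at
  50 — plausible densities of stems ≥ 10 cm diameter in one hectare. These
  defaults give Fisher's α between roughly 15 and 165 and sample coverage
  above 0.8 for nearly all plots, matching what high-effort 1-ha
  inventories report.

What the generator does *not* emulate: taxonomic structure shared between
plots (each plot's species pool is independent), dispersal limitation,
within-plot habitat mosaics, and observation error in species
identification.

## Numerical choices and degenerate inputs

* Fisher-α bisection on `[1e−8, 10N]` with automatic bracket expansion;
  tolerance 1e-8.
* Rarefaction ratios are computed via `lchoose` differences to avoid
  overflow; non-integer subsample sizes interpolate linearly between
  adjacent integers.
* Earth radius fixed at 6371.0088 km (haversine); ellipsoidal precision is
  immaterial at 50–200 km thinning scales.
* Moran's I permutation tests use 999 (or a configured number of) seeded
  shuffles; the expectation under the null is `−1/(n−1)`.
* Constant columns are errors for the PCA, reasons-for-dropping in the
  VIF screen, and "zero variance" errors for Moran's I.
* All randomness is derived from one master seed through stage-tagged
  sub-seeds, so stages are independently reproducible and the end-to-end
  pipeline reproduces its metrics manifest bit-identically.

## Problem sizes used by the tests

The test-suite simulations were sized to be decisive yet quick: the full
429-plot network for model contracts and driver-attribution recovery, a
62-plot network for module-level checks, 500 urn replicates for generator
calibration, 10,000 subsampling draws for the rarefaction oracle, 100
replicates for the count-regression coverage check, and 20 seeded runs for
the pure-noise forest contract. The end-to-end pipeline runs the default
network through diversity, screening, 24 forest fits (three richness
measures × two model types × full plus three thinned subsets), three
GLMs, and the seven-refit sensitivity analysis in a few minutes on one
CPU.

## Known limitations

* Out-of-bag sensitivities inherit forest Monte Carlo noise; with few
  trees the attribution of plots near the 1/7 threshold can flip. The
  default 500 trees keeps this small.
* The co-limitation label is relative to the fitted model: a category the
  model never learned (e.g. because its variables were screened out)
  cannot be attributed.
* The NB GLM's spatial-CV R² is not directly comparable to published
  out-of-bag values for GLMs, which are not well defined; we report the
  spatially blocked analogue and say so.
* Band profiles are empirical shares per band; no smoothing or
  interpolation between bands is attempted.
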