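---
title: "Trophic-energy-informed distribution modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trophic-energy-informed distribution modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Species distribution models (SDMs) overwhelmingly rely on abiotic
predictors — climate and land use — even though the realized niche of a
consumer is also shaped by where its food is. For a generalist top
consumer such as a large omnivorous carnivore, the energy available from
food species varies strongly across its range: different subpopulations
eat different species, in different proportions, and those food species
themselves shift under climate and land-use change. `eltonsdm` implements
a pipeline that makes this trophic dependence explicit and testable:

1. **Diet energetics** — convert published diet-study tables into
   per-item energy shares and per-subpopulation representative diets.
2. **Diet–environment associations** — relate diet composition and
   diversity to environmental covariates around study sites.
3. **Food-species habitat models** — simple reproducible ensemble SDMs
   for each food species.
4. **Biotic layers** — spatial surfaces of potential dietary energy,
   quantitative and binary.
5. **Hierarchical Bayesian distribution model** — a binomial GLMM for the
   focal species with informative priors transferred from a coarse
   historical-range model, compared across predictor sets by WAIC.
6. **Scenario projection** — range change under coupled climate/land-use
   scenarios with abiotic-only, biotic-only and combined change modes,
   plus a sensitivity analysis on the biotic inputs.

Because the original continental data cannot be redistributed or
re-assembled at desk scale, the package ships a first-class synthetic-data
generator that emulates every input with known ground truth, so each stage
— and the pipeline as a whole — is verifiable end to end.

## Diet energetics

Within one diet study, each food item *i* has a relative frequency of
occurrence `rF_i = f_i / sum(f)` and a relative volume
`rV_i = v_i / sum(v)`; both are simplex-valued per study. Not all studies
report volumes, so `impute_rv()` fits an ordinary least-squares
relationship `rV ~ rF` on the pooled items of complete studies, predicts
the missing values, clips at zero and renormalizes within each study. The
functional form of this relationship is not prescribed by the underlying
field literature; OLS with an intercept is the minimal monotone choice and
is isolated behind one function so it can be replaced. Observed values are
never altered, and every imputed item is flagged.

Energy weighting follows
`rEDEC_i = CF_Ei * rEDC_i / sum_j(CF_Ej * rEDC_j)`, where `CF_E` is an
item- or category-level energy correction factor and the corrected
relative content defaults to `rEDC_i = rV_i` (an optional volume
correction `CF_V` can be configured; the exact published correction tables
live in supplementary material we do not reproduce, so correction factors
are inputs here). `rEDEC` is invariant to rescaling all `CF_E` by a common
constant.

The representative diet of a subpopulation weights studies by their
sampling effort `Z` (number of scats or stomachs):
`rEDEC_Subp,S = sum_i(Z_i * rEDEC_S,i) / sum_i(Z_i)`, with a species
counted as zero in studies where it is absent. Items not resolved to the
species level are excluded from the per-species map but retained in
category and origin totals, so the species shares plus the unresolved
remainder always sum to one.

## Diet–environment associations

`extract_buffer_covariates()` averages each layer over cells whose center
lies strictly within 18 km of a study site — on a 1-km equal-area grid an
interior buffer holds 1005 cells, the discrete counterpart of the
1017.9 km² continuous disc. Collinear covariates are removed by an
iterative VIF filter (threshold 10, computed as `1/(1 - R²)`), and
`fit_averaged_models()` fits all covariate subsets (capped at 8 terms to
bound the 2^k enumeration), ranks them by AICc and averages coefficients
over the models within 3 AICc of the best, using conditional (subset)
averaging with renormalized Akaike weights. Because the significance
measure used for averaged models is ambiguous in common practice, the
coefficient table reports both the averaged-model z-test p-value and the
best single model's t-test p-value, asserting neither. Diversity of the
five food categories (reproductive plants, vegetative plants, unknown
plants, invertebrates, vertebrates) is summarized by Shannon, Simpson and
inverse-Simpson indices via **vegan**.

## Food-species habitat models

Occurrences are gridded to unique 1-km presence cells ("one cell, one
presence"), species with fewer than 50 presence cells are excluded, and
pseudo-absences are drawn uniformly from the annulus of cells farther
than 3 km but within 10 km of the nearest presence — mirroring the spatial
bias of the presences into the background sample — with exactly as many
absences as presences. Predictor selection is greedy: candidates are
ranked by the AIC of univariable binomial GLMs (linear + quadratic), and
the best-ranked layers are kept while enforcing pairwise |r| ≤ 0.7, up to
six variables, with deterministic name-based tie-breaking.

The ensemble deliberately simplifies large multi-algorithm platforms into
two documented members — a ridge-regularized logistic regression on
linear + quadratic standardized features (lambda by 5-fold
cross-validation) and gradient-boosted trees (depth 3, 40–60 rounds) —
fitted on a stratified 80/20 split, weighted by held-out true skill
statistic (TSS = sensitivity + specificity − 1), and combined as a
weighted mean probability. The binarization threshold maximizes held-out
TSS. Two members are few, but the weighting, evaluation and prediction
machinery is the same as with many, and the member spread doubles as the
uncertainty source for the biotic sensitivity analysis.

## Biotic layers

For food category *c* in subpopulation *Subp*, the quantitative layer is
`sum_{S in c} rEDEC_Subp,S * HS_S(x)` — energy share times habitat
suitability, summed over species; the binary variant replaces the share
with a 0/1 observed-interaction indicator. Summation (not averaging) is
used for "combining" because it preserves the energy-flow semantics: the
all-species total `Bio_All_species` is then the simplex-weighted sum of
all quantitative layers. Binary layers are not normalized by species
count; this is a documented choice. Scenario layer sets use scenario
suitabilities with **current** diets held fixed — diet plasticity under
change is explicitly out of scope. Species without a habitat model (e.g.
human-derived resources) contribute nothing and are logged.

`compare_proxies()` contrasts the two proxies per category with
univariable binomial GLMs (linear + quadratic) by AIC.

## The hierarchical Bayesian distribution model

**Occurrence preparation.** Occurrences are gridded and deduplicated,
non-terrestrial cells masked, presences capped at 2000 per subpopulation
(uniform seeded subsample), pseudo-absences drawn within 5 km of
presences in equal number per subpopulation, and the data split 80/20
into training/validation stratified by subpopulation. The split uses
largest-remainder allocation so the training total is exactly
`round(0.8 * N)`.

**Historical model and prior transfer.** A coarse historical range grid
(50×50 blocks of the fine grid) is sampled by environmental
stratification: the four bioclim-style variables (isothermality `Clim_3`,
temperature seasonality `Clim_4`, mean temperature of the wettest
`Clim_8` and driest `Clim_9` quarters) are quantile-binned, bins are
intersected into strata, and an equal number of presences and absences is
drawn per stratum (strata lacking a class are skipped and logged; the
bin count is configurable because the construction is only loosely
standardized in the field). A Bayesian logistic regression with linear +
quadratic terms then yields a posterior mean and SD per coefficient — the
`prior_set` — together with the standardization constants of the
historical data. Those constants are reused verbatim at fine scale, so
the transferred priors refer to the same coordinate system; without this
the transfer would be meaningless.

**Fine-scale model.** A binomial GLMM (logit link) with a subpopulation
random intercept (the only grouping structure in the data model; a config
switch disables it). Climate enters with linear + quadratic terms —
matching the historical screening and the expected bell-shaped responses
— while land-use and biotic predictors enter linearly. Land-use and
biotic predictors are chosen as the four best uncorrelated candidates by
univariable mixed-model AIC. Variants: abiotic+biotic, abiotic-only,
biotic-only and the intercept-only null; hierarchical variants transfer
the historical priors (intercept + climate, used unmodified), everything
else gets weakly-informative defaults (normal(0, 2.5) on standardized
predictors, normal(0, 5) intercepts). Only climate-containing variants
can be hierarchical.

Sampling uses JAGS. Default settings are 4 chains with 1000 warmup and
1000 sampling iterations; the synthetic study and the test suite use 2
chains with a few hundred iterations each, which the diagnostics show is
adequate at these problem sizes. Because the global intercept and the
subpopulation intercepts are only jointly identified, reported draws are
swept (intercept + mean(u), u − mean(u)); the linear predictor is
unchanged. Convergence is flagged at split-chain Rhat > 1.05; effective
sample sizes and Monte Carlo SEs are reported per parameter. WAIC is
computed from the pointwise posterior log-likelihood with its standard
error, and model comparison reports pairwise ΔWAIC with SEs from the
pointwise differences. With an empty dataset the fit returns the prior
predictive, which the tests use to verify prior transfer exactly.

**Thresholding.** The presence/absence cutoff is the 10th percentile of
predicted probabilities at training presences (type-1 empirical
quantile), so by construction 90% of training presences score at or above
it; the threshold is chosen to overestimate the range of a species
extirpated from suitable areas. Evaluation reports TPR and TNR on
training and validation cells.

## Scenario projection and sensitivity

Projections cover three coupled scenarios (SSP1-2.6, SSP3-6.0, SSP5-8.5)
× three change modes. In abiotic-only mode the biotic layers are pinned
to current values; in biotic-only mode the abiotic layers are pinned;
the current-conditions threshold is reused unchanged for all runs.
Predictions are masked to cells within 200 km of the current thresholded
distribution so biotic layers are never extrapolated into regions with no
diet information. Range descriptors report area, percent change versus
current, percent inside protected areas, and percent currently occupied,
overall and per subpopulation (areas are additive over subpopulations).

The biotic sensitivity analysis refits the model with the biotic
predictors replaced by their lower and upper uncertainty bounds — built
from the pointwise spread of ensemble-member predictions, the natural
in-pipeline uncertainty source since the published construction of the
"extremes of the biotic input" is not fully specified — and reports
coefficient shifts and the correlation of each bound run's prediction map
with the original. Refits use the original fit's RNG seed (common random
numbers), so identical bounds reproduce the original posterior exactly
and small perturbations are not drowned in Monte Carlo noise.

## The synthetic-data generator

The generator defines the study conditions under which the package is
validated:

* **Landscape** — 100×100 1-km cells by default; spatially autocorrelated
  Gaussian fields (white noise smoothed with a Gaussian kernel, length
  scale 8 km) rescaled to bioclim-like units (e.g. `Clim_8` ≈ 10 ± 5 °C);
  land-use fractions are inverse-logit fields; `Natural Landscape` is an
  11×11 km moving-window mean of a natural-cell indicator (urban fraction
  < 0.2). Scenario deltas grow monotonically across the three SSPs
  (+1.0 / +2.1 / +3.5 °C on `Clim_8`, urban +0.02 / +0.05 / +0.08,
  multiplicative forest losses), chosen once as plausible mid-century
  magnitudes. Fractions are clipped to [0, 1] with a warning.
* **Food species** — ten species across the five categories, eight wild
  (modellable) and two human-derived (no habitat model, exercising the
  missing-SDM path); logistic niches with random linear + quadratic
  coefficients on two climate and one land-use layer.
* **Diet studies** — eight studies per subpopulation (32 sites, matching
  the scale of the literature base the method targets), sampling-unit
  counts Z uniform in 30–300, item counts multinomial in the true energy
  shares divided by `CF_E` (so the downstream correction recovers the
  shares), 30% of studies with rV masked. rV is rF plus Gaussian noise
  whose scale is solved numerically so the realized pooled rF–rV
  correlation equals the 0.86 target.
* **Focal species** — a known logistic truth combining bell-shaped
  climate responses, land-use effects and linear biotic effects; the
  coarse historical range is drawn from block-aggregated probabilities of
  a climate-only version of the truth, making the historical prior
  informative but not identical to the fine-scale process. The study
  pipeline aggregates by a factor of 5 (20×20 coarse cells) so the
  9-coefficient historical model is identifiable at desk scale; the
  generator's default remains the 50× scale ratio of the real grids.

A note on validation design: the balanced 5-km pseudo-absence protocol is
a case–control scheme whose controls are deliberately drawn near
presences. That shifts the intercept (class balance) and attenuates
slopes (controls resemble cases in covariate space) for *any* estimator —
a property of the protocol, not of the fit. Parameter-calibration checks
therefore evaluate the model on random grid cells carrying their true
presence/absence state, where the likelihood is correctly specified,
while the pseudo-absence machinery is verified by its own contracts
(per-subpopulation balance, buffer distances, caps, split arithmetic).

What the generator does **not** emulate: real climate physics,
species-specific niche shapes, observation effort gradients, spatial
sampling bias beyond what the pseudo-absence rules induce, dispersal
limitation, and temporal diet variation. Passing tests therefore
demonstrate that the statistical machinery recovers known structure under
the stated assumptions — not that those assumptions hold for any
particular real dataset.

## Numerical choices and degenerate inputs

* Buffer membership and pseudo-absence distances use strict/closed bands
  on cell-center Euclidean distances in km; ties in AIC-based rankings
  break by variable name.
* Simplex renormalizations tolerate 1e-9; predictions clip probabilities
  at 1e-12 in the log-likelihood.
* Perfect collinearity yields infinite VIF and is dropped first; constant
  layers are flagged degenerate in proxy comparison and skipped in
  selection.
* Candidate linear models too small for AICc (n − k − 1 ≤ 0) are skipped
  and logged.
* Ensemble members that fail to fit are dropped with a warning; if all
  fail, the fit errors.
* An empty dataset triggers the prior-predictive path of the Bayesian
  fit; missing layers, inverted sensitivity bounds, subpopulations
  without studies or presences, and annulus shortfalls raise errors that
  name the problem.

## Problem sizes

The shipped defaults — 100×100 grid, ~2,000 training presences, 2-chain
reduced MCMC, 20-replicate simulation checks — are the package's chosen
desk-scale study conditions; they keep the full pipeline and test suite
runnable on a single CPU while leaving every qualitative property of the
full-scale analysis (WAIC ordering of predictor sets, proxy comparison,
prior transfer, threshold construction) measurable.

## Known limitations

* Two ensemble members stand in for the many-algorithm platforms used in
  production SDM work; absolute skill values are not comparable, which is
  why the suite asserts a sanity floor (mean TSS ≥ 0.4) rather than a
  point value.
* Biotic layers are deterministic functions of the abiotic layers through
  the food-species models; in the synthetic truth the biotic signal is
  partially confounded with climate, exactly as in the real system, so
  model-comparison checks are stated as orderings rather than effect
  sizes.
* The subpopulation random intercept is the only spatial structure; no
  residual spatial autocorrelation is modelled.
* Prior transfer assumes the historical and current processes share the
  climate coordinate system; the package enforces shared standardization
  but cannot check ecological stationarity.
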