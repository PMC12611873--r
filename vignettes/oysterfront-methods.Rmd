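---
title: "Methods: hurdle habitat suitability modelling at an invasion front"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hurdle habitat suitability modelling at an invasion front}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Predicting where an invading species will establish is hardest exactly where
prediction matters most: at the leading edge of the invasion, where the
population is not in equilibrium with its environment and occupies only a
fraction of the suitable habitat. `oysterfront` implements a two-part
("hurdle") habitat suitability analysis developed for the Pacific oyster
(*Magallana gigas*) front on the Swedish southwest coast — a region with a
strong north–south salinity gradient (about 25 down to 10 psu), scarce
natural hard substrate in the south, and an abundance of artificial
structures (marinas, piers) suspected to act as invasion hotspots.

The analysis separates two ecologically distinct questions:

1. **Occurrence** — can the species establish at a site at all? Modelled
   from presence–absence with an ensemble of classifiers.
2. **Abundance** — given establishment, how dense can the population get?
   Modelled on the log scale from presence sites only.

Separating the two matters because the drivers differ: availability of
stable hard substrate governs *whether* oysters occur, while shelter from
wave action governs *how many* accumulate. Conflating the two in a single
model blurs both signals.

## Survey design assumed by the models

The data template is a quadrat survey: sites in three habitat types
(marina, pier, natural rocky), five 0.5 × 0.5 m quadrats per site
(0.25 m² each). Site abundance is the mean count across the five quadrats
divided by quadrat area, so the smallest nonzero abundance is
1/(5 × 0.25) = 0.8 ind·m⁻². The first quadrat is *targeted*: placed on the
visually densest patch. This deliberately biases site abundance upward —
the design goal is capturing habitat susceptibility, not census density —
and is why all downstream quantities are interpreted as *possible* (risk)
rather than current abundances. The occurrence model is fitted with the
first quadrat's substrate cover (the substrate the species actually sits
on), while the abundance model uses site-mean covariates.

## Occurrence: the gated ensemble

Four algorithm families are fitted per data split: logistic GLM, spline
logistic GAM (`mgcv`, basis dimension 4 per smooth — small on purpose at
n = 45), gradient-boosted trees (`xgboost`, 100 rounds, depth 2, learning
rate 0.1) and random forest (`randomForest`, 500 trees). Evaluation uses
repeated split-sampling: 100 random 80/20 train/validation splits, all
governed by one seed. Each (family, split) member gets a holdout AUC
(midrank Mann–Whitney; ties count one half) and TSS (maximum of
sensitivity + specificity − 1 over thresholds at midpoints of sorted
unique scores). Members enter the ensemble only if validation AUC ≥ 0.70
**and** TSS ≥ 0.50 — the conventional "fair" boundary. The ensemble
prediction is the unweighted mean of included members' probabilities;
unweighted because no weighting scheme is part of the contract and the
gates already remove poor members.

The ensemble is then calibrated on the full fitting data: its calibration
AUC, and a default probability cutoff maximizing sensitivity +
specificity. Numerical conventions, fixed once: candidate cutoffs are
midpoints of sorted unique predicted probabilities; ties between equally
good cutoffs break toward the value nearest 0.5, then toward the larger;
a probability exactly equal to the cutoff classifies as *absence*.
Training splits containing a single class are skipped with a warning, as
are failed fits; members whose holdout happens to contain one class get
undefined metrics and cannot pass the gates. With three predictors the
1:10 presences-per-predictor rule of thumb is checked and warned about,
not enforced.

Hyperparameters per family are deliberately plain small-sample defaults
exposed through `control`; the package's contract is the gate/ensemble
logic and the evaluation conventions, not tuning.

## Abundance: random forest with retransformation corrections

On presence sites, natural-log abundance is regressed on the covariates
with a random forest (500 trees, past the point where the error rate
stabilises). The variables-per-split parameter is selected by sixfold
cross-validation with 10 repeats (at 30 presence sites each validation
fold holds five points), minimizing mean validation RMSE. Two corrections
are calibrated on out-of-bag predictions of the final forest:

* **Bias line.** Machine-learning regressors compress the response range
  (overpredict low, underpredict high values). A least-squares regression
  of observed on predicted log abundance gives `a_bc + b_bc · prediction`;
  a slope above 1 stretches predictions back toward the observed spread.
  Out-of-bag predictions are used rather than resubstitution ones so the
  line corrects genuine generalization bias; this was a genuinely open
  choice and is switchable by refitting with the components exposed.
* **Duan's smearing.** Exponentiating a log-scale prediction
  underestimates the mean; the smearing factor S = mean(exp(residuals))
  corrects it nonparametrically. Residuals are taken *after* bias
  correction so S matches the scale actually back-transformed. For
  mean-zero residuals S ≥ 1 (Jensen).

The full chain, `exp(a_bc + b_bc · forest(x)) · S`, is strictly positive.
No +1 offset is needed on the log scale because the design granularity
bounds presence-site abundance at 0.8 ind·m⁻². The residual range
compression that survives the bias line is accepted behaviour, not
corrected further.

## Predictor influence

Both models expose the same three diagnostics, occurrence on the
probability scale and abundance on the bias-corrected log scale:

* **Permutation importance**: mean over three seeded runs of
  1 − Pearson r between original predictions and predictions after
  permuting one covariate column. Raw values (range 0–2), deliberately
  not normalized to sum to one. Permutations are drawn independently per
  variable and run; constant predictions yield importance 0 with a
  warning rather than an undefined correlation.
* **Evaluation-strip response curves**: 100 predictions across the
  observed interval of one variable, others fixed at their medians.
* **Two-variable partial dependence**: data-averaged clamping on a grid —
  a different estimand from the median-fixed strip, which is why both are
  implemented and named distinctly. Under an additive model the surface
  reconstructs exactly as the sum of the one-dimensional effects, which
  the tests exploit as an oracle.

## Projection and population arithmetic

Fitted models are projected onto a site table of marinas (substrate
assumed 100%, substrate depth 0.5 m) and randomly placed natural sites in
the 0–1 m band. Exposures are prepared *identically* to training:
marina values above 10,000 (the "very sheltered" class boundary, above
which a fetch model has clearly missed a breakwater) are replaced by the
mean of the sheltered marinas, then attenuated to depth by
`E · exp(−k · depth)` with k = 0.5 m⁻¹ — the exponential form and default
k are this package's documented choice, since no canonical attenuation
constant exists; both are overridable. Wave exposure is treated
throughout as a positive dimensionless index: source fetch models report
inconsistent units, and only its ordering and spread matter here. Because
it spans orders of magnitude, the synthetic truth places it on the log10
scale in both linear predictors.

Per habitat stratum h the possible population size is

  N_h = x̄_h · P_h · A_h

with x̄_h the mean predicted abundance over predicted-present sites (a
simple, unweighted mean — the area-weighted alternative is a one-line
switch but plain means are the reported convention), P_h the predicted
prevalence, and A_h the areal extent. The rocky-habitat area is the total
natural area times the fraction of projection sites with any hard
substrate. "Invaded area" is the product P_h · A_h. Possible biomass
converts N_h through the habitat's shell-length class frequencies (5 mm
bins) and an allometric length–weight model W(L) = a·L^b. The default
length–weight model is calibrated from two size-class anchors
(62.5 mm ≈ 40 g, 107.5 mm ≈ 140 g) because the underlying regression is
unpublished; it is an explicit approximation and replaceable via
`lw_calibrate()`. Per-unit-area standardization (x̄_h·P_h and B_h/A_h) is
what makes a 400 m² marina comparable with kilometres of shoreline.

Uncertainty is a percentile bootstrap (default 1000 resamples) resampling
*projection sites* with replacement within habitat and recomputing every
statistic per replicate; the resampled unit was an open choice, and
site-level resampling matches the dominant uncertainty source here
(which sites are suitable), leaving model-parameter uncertainty out of
scope. Pier habitat is never projected: its substrate depth and
composition cannot be assumed honestly, and its habitat surface is
negligible beside marinas and natural shores.

## The synthetic truth: what it emulates, and what not

`generator_config()` encodes the study conditions: 15 sites in each of
three habitat types, five 0.25 m² quadrats with a targeted first quadrat
(modelled as the maximum over 20 candidate patches, floored at one
individual where the species is present — the targeted quadrat is placed
on individuals actually seen), substrate-driven occupancy
(Bernoulli on a logit-linear predictor), shelter-driven lognormal density
with a piecewise-linear decline of 0.8 log units per psu below 8 psu, and
negative-binomial quadrat counts (dispersion 5; field counts are
clumped). Site minimum salinity is the 25 → 10 psu along-coast trend
minus a half-normal dip (sd 3.5 psu): a site's *minimum* salinity sits at
or below the typical gradient value, which also guarantees that southern
sites regularly sample the sub-breakpoint regime — without that, the
breakpoint would be unidentifiable from most simulated surveys. Shell
lengths are lognormal with the marina mode near 107 mm and the natural
mode near 62 mm, which is what drives marina biomass per unit area far
above the abundance ratio alone.

Default coefficients were frozen by simulation (`tools/calibrate_generator.R`)
so that occupied-site mean abundances land near the west-coast anchors of
10.4 / 3.3 / 2.8 ind·m⁻² for marinas / piers / natural rocky habitat and
overall prevalence near two thirds. These are calibration anchors — the
generator is a test harness, not an inference about the real coast.

Deliberate omissions: no spatial autocorrelation between sites (the field
design enforced ≥ 100 m separation precisely to justify this), no real
geodesy (latitude is a [0, 1] proxy), no detection error beyond the count
noise, no temporal dynamics. Passing recovery tests therefore shows the
pipeline recovers *this* class of structure — monotone covariate effects
with one breakpoint, independent sites — not that it would survive
spatially structured residuals or shifted niches in real data.

## Validation design and problem sizes

The test suite runs every statistic against an independent oracle where
one exists: AUC against brute-force pairwise concordance (exact, with
ties), TSS against exhaustive threshold search, VIF against 1/(1 − R²),
the ANOVA F against hand-computed sums of squares, the bias line and
smearing factor against closed-form toys, partial dependence against
additive reconstruction. Cross-library checks (pROC, car) guard the
implementations from the outside.

Parameter recovery runs the full study design (45 sites, 100-split
committee, 6 × 10 CV) on 20 replicate surveys and requires substrate to
rank first in occurrence importance and exposure first in abundance
importance in at least 90% of them; the sub-8-psu abundance decline
(response at 6 psu below the response at 10 psu) is required in at least
90% of the replicates whose presence data actually contain
sub-breakpoint salinities, since elsewhere the decline is not
identifiable from the data the model saw.

Bootstrap calibration is checked at nominal 95% over 500 lognormal
samples of n = 30 with 1000 resamples each, at mild skew (sdlog 0.2),
where the percentile interval should sit within [92%, 97%]. This is a
check of the interval machinery, not of skew robustness: at this sample
size the percentile interval's true coverage degrades as skew grows
(roughly 92% at sdlog 0.35 and below 92% by sdlog 0.5 in our Monte
Carlo), a known property of percentile intervals for skewed means and a
real limitation when bootstrapping strongly skewed abundance data at
small n.

These problem sizes — and the scaled-down committee used by the shared
test fixture (20 splits, 3 CV repeats, 200 bootstrap resamples) — are the
package's chosen balance between statistical resolution and a test suite
that runs comfortably on one CPU.

## Known limitations

* Real-data performance figures (calibration AUC, CV RMSE, importances)
  depend on the original field data and are not reproduced here; the
  synthetic analogues are structural checks only.
* The ensemble offers no spatial cross-validation and no pseudo-absence
  machinery (true absences are surveyed); applying it to presence-only
  data would require both.
* The length–weight default is a two-anchor approximation; biomass
  estimates inherit its error multiplicatively.
* Bootstrap intervals cover sampling of projection sites, not model
  uncertainty; they narrow as the projection set grows even though model
  error does not.
* The collinearity screen reports; it does not drop. With three
  predictors chosen a priori, automatic dropping would add hidden state
  for no benefit.
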