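# oysterfront

Habitat suitability and possible population size at a marine invasion
front.

`oysterfront` is an R implementation of a two-part ("hurdle") habitat
suitability analysis for invading sessile species, built around the
Pacific oyster (*Magallana gigas*) expansion along the Swedish southwest
coast. It is aimed at quantitative ecologists and coastal managers who
need to rank habitats by invasion risk — in both **occurrence** and
**abundance** terms — from modest presence/absence and quadrat-count
surveys across habitat types (marinas, piers, natural rocky shores).

## The model

Occurrence and abundance are modelled separately, because their drivers
differ (substrate availability vs. shelter from waves):

1. **Occurrence**: an ensemble of presence–absence models (logistic GLM,
   spline GAM, boosted trees, random forest) fitted on repeated 80/20
   split samples. Members enter the ensemble only with validation
   AUC ≥ 0.70 and TSS ≥ 0.50; the ensemble prediction is the unweighted
   mean probability, thresholded at a cutoff that maximizes
   sensitivity + specificity.
2. **Abundance**: a random-forest regression of log abundance on presence
   sites, selected by repeated sixfold cross-validated RMSE, then
   back-transformed through an observed-on-predicted bias line and Duan's
   smearing factor S = mean(exp(residuals)):
   `abundance = exp(a_bc + b_bc · forest(x)) · S`.

Predictor influence is measured identically for both models: permutation
importance (mean 1 − Pearson r over three permutation runs),
evaluation-strip response curves (100 points, other covariates at their
medians), and two-variable partial dependence.

Projection onto a site table of marinas and natural shoreline yields, per
habitat stratum *h*, the **possible population size**

&nbsp;&nbsp;&nbsp;&nbsp;N<sub>h</sub> = x̄<sub>h</sub> · P<sub>h</sub> · A<sub>h</sub>

(mean predicted abundance over predicted-present sites × predicted
prevalence × areal extent), plus possible biomass through shell-length
class frequencies and an allometric length–weight model, with percentile
bootstrap confidence intervals. A calibrated synthetic survey generator
(`generator_config()`, `generate_survey()`) reproduces the study's design
— 45 sites, targeted first quadrats, a 25 → 10 psu salinity gradient, an
abundance collapse below 8 psu — with known truth, so the whole pipeline
is testable without field data.

## Worked example

```r
library(oysterfront)

cfg <- pipeline_config(seed = 1)   # one seed governs every stage
res <- run_pipeline(cfg)

res$field$comparison
#> One-way ANOVA on log abundance: F(2,27) = 7.80, p = 0.00212
#> Group means (ind/m2):
#>        marina natural_rocky          pier
#>          7.54          2.80          3.20

res$ensemble
#> Presence-absence ensemble
#>   304 of 400 candidate members included (76%); gates AUC >= 0.70, TSS >= 0.50
#>   calibration AUC = 0.962; cutoff = 0.585 (sens 0.90, spec 0.93)

res$abundance
#> Random-forest abundance model (log scale)
#>   n = 30 presence sites; mtry = 3 of 3 predictors; 500 trees
#>   CV RMSE = 0.709 log units (6-fold x 10 repeats)
#>   bias line: a = 0.471, b = 0.648; smearing S = 1.261

res$influence$abundance_importance
#> Permutation importance (1 - Pearson r, mean of 3 runs)
#>         variable importance
#>         exposure     1.0470
#>     min_salinity     0.0678
#>  substrate_cover     0.0102

res$estimates
#> Habitat-stratified possible population estimates (95% percentile bootstrap, 1000 resamples)
#>          habitat prevalence % invaded km2 xbar ind/m2 N x1e6           N CI  biomass t
#>           marina        100.0      0.0242         6.7  0.161 (0.138, 0.186)       30.8
#>    natural_rocky         37.3     15.2000         4.0 60.300     (36.1, 86)     3770.0
#>  natural_overall         20.4     15.2000         4.0     NA       (NA, NA)         NA
```

Reading the output: habitat comparison of the simulated survey finds
marinas roughly three times denser than piers or rocky shores where
occupied (F-test on log abundance, Tukey-adjusted pairwise p-values);
the occurrence ensemble separates presences and absences nearly
perfectly on this synthetic truth; permutation importance recovers wave
exposure as the dominant abundance driver; and the projection table
mirrors the invasion-risk summary — marinas are individually tiny
(0.02 km² predicted invaded) yet dense, while rocky shores carry the
bulk of the possible population because of their extent. Per unit of
*total* habitat area the ranking reverses in the marinas' favour:

```r
res$per_unit$abundance_ratio   # marina : natural_rocky
#> [1] 4.5
res$per_unit$biomass_ratio
#> [1] 13.7
```

All numbers above are what the code prints for `seed = 1`; other seeds
give different draws of the same calibrated truth.

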