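# moultshift

Seasonal coat-colour moult phenology and camouflage-mismatch behaviour
analysis for radiotracked mammals.

Snowshoe hares (*Lepus americanus*) moult between a brown summer coat and a
white winter coat. As snow seasons shorten, the moult can fall out of step
with the snowpack, leaving white hares on bare ground or brown hares on
snow — conspicuous to visually hunting predators. Two kinds of phenotypic
plasticity could compensate: shifting the *timing or rate* of the moult
itself, or adjusting *behaviour* (hiding, fleeing, resting-spot choice) when
mismatched. `moultshift` packages the full analysis chain a field study of
this question needs, driven by weekly radiotelemetry sightings scored on a
20% visual grid.

## What it computes

**Moult phenology.** Coat whiteness of hare *i* on day *t* follows a
piecewise-linear change-point trajectory

```
E[w_it] = 100 · clamp((t − init_i) / duration_i, 0, 1)        (autumn)
E[w_it] = 100 · (1 − clamp((t − init_i) / duration_i, 0, 1))  (spring)
```

with hierarchical initiation `init_i = mu_init + eps_i`,
`eps_i ~ N(0, sigma_ind²)`, Gaussian observation error `sigma_obs`, and
covariates acting multiplicatively on the moult rate:
`duration_i = dbar · exp(beta_snow · snow_i + beta_temp · dd_i) +
beta_sex · sex_i` (mean snow cover, cumulative degree days, sex). The
posterior is sampled by an adaptive random-walk Metropolis-within-Gibbs
sampler with vectorised random-effect sweeps and reparameterisation moves,
checked by split-chain R-hat. Derived outputs: population initiation and
completion dates with 95% credible intervals, covariate-driven shifts of
the completion date, and per-individual reaction norms across years.

**Camouflage metrics.** Signed colour contrast (% whiteness − % snow),
mismatch classes at the inclusive ±60% threshold, seasonal degree days
(|T| below 0 °C in autumn, T above 0 °C in spring, accumulated per window),
and weekly phenology curves.

**Behaviour.**

* *Concealment*: linear mixed models (random intercept per hare) over an
  enumerated candidate set screened for collinear pairs (|r| ≥ 0.8), ranked
  by AICc with a best set within 2 ΔAICc, quadratic contrast terms, and 95%
  HPD intervals for the best model's fixed effects.
* *Flight initiation distance*: Cox proportional hazards on the
  approach-progress scale (flight = event; "no flush" at the 3 m minimum
  approach = right-censored), Efron ties, scaled-Schoenfeld proportionality
  checks, AICc selection.
* *Resting spots*: used–available binomial logit model over each sighting's
  nine spots (1 used + 8 pie slices), nested random effects, with a
  conditional-logit cross-check and the presence-probability curve over
  snow cover.
* *Habituation*: both behavioural responses are first truncated at the
  largest attempt index showing no significant decline with repeated
  human approaches.

**Synthetic studies.** A seeded generator reproduces the whole sampling
design — two sites with offset phenologies, weekly detection-thinned
sightings, heavy mortality censoring, grid-snapped scores, snow scenarios
with transient early-autumn snowfalls — and returns the generating truth, so
every estimator in the package is validated by parameter recovery.

## Worked example

```r
library(moultshift)

study <- make_fixture("phenology_small", seed = 20111)   # 30 hares, 2 years
md  <- prepare_moult_data(study$observations, study$temperatures,
                          site = "gardiner", season = "autumn")
fit <- fit_changepoint(md, covariates = c("snow", "sex"),
                       chains = 2, iter = 2000, warmup = 1500, seed = 42)
fit
#> Hierarchical change-point moult model: autumn moult at site gardiner
#> 23 hare-years, 207 sightings; 2 chains x 2000 draws
#>   parameter      mean       sd    ci_low   ci_high  rhat
#>     mu_init 3.189e+01 2.438053 27.117449 36.882004 1.017
#>        dbar 4.100e+01 2.321925 36.661697 45.955595 1.012
#>   sigma_ind 7.949e+00 1.801703  5.194011 12.377277 1.002
#>   sigma_obs 6.881e+00 0.357053  6.213562  7.615272 1.004
#>   beta_snow 7.329e-04 0.002426 -0.003942  0.005664 1.013
#>    beta_sex 1.722e+00 2.598360 -3.610159  6.621233 1.032
#>        init 3.189e+01 2.438053 27.117449 36.882004 1.017
#>  completion 7.289e+01 2.667036 67.352667 77.690576 1.006
```

The population autumn moult is estimated to start on season-day 31.9 (95%
CI 27.1–36.9; the generator's truth is day 28, i.e. late September) and
complete around day 72.9, a duration of about 41 days. `sigma_ind` ≈ 8 days
is the between-hare spread of initiation; `sigma_obs` ≈ 7% is the visual
scoring noise. The snow coefficient is indistinguishable from zero here;
its implied effect on the completion date:

```r
covariate_shift(fit, "snow", low = 0, high = 100)$mean
#> completion shift for 0 -> 100% snow: 2.9 days (95% CI -16.0 to 23.0)
```

— a bare-ground-to-full-snow change moves the mean completion date by only
a few days, i.e. the moult is largely fixed once initiated.

Camouflage mismatch for the same study:

```r
obs <- contrast_metrics(study$observations)
table(obs$mismatch10m)
#>     none negative positive
#>      619        0       62
```

Behavioural fits follow the same pattern (`habituation_truncation()`,
`build_candidates()` + `fit_concealment()`, `fit_fid()`,
`build_choice_rows()` + `fit_resting_spot()`), and
`run_study(study_config(...))` chains every stage into a reproducible
report bundle with a JSON manifest. A thin command-line wrapper lives at
`inst/cli/moultshift.R`.

## Vignette

`vignettes/moult-phenology-and-behaviour.Rmd` documents the model, priors,
sampler, generator design, numerical choices, and known limitations.
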