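---
title: "Moult phenology and camouflage-mismatch behaviour: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moult phenology and camouflage-mismatch behaviour: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moultshift)
```

`moultshift` analyses the seasonal brown–white coat moult of snowshoe hares
and the behaviours that could compensate for camouflage mismatch. This
vignette is the package's account of its models: what is assumed, which
knobs matter, what the synthetic-data generator does and does not emulate,
and where the design was genuinely open.

## The data model

One row per sighting of one radiocollared hare: date, site, sex, coat
whiteness, snow cover in 1-m and 10-m radii, a 1–4 concealment level, an
optional flight trial (distance 3–20 m, or "no flush" at the 3-m minimum
approach), the cumulative location-attempt index, and optionally eight
"pie-slice" snow percentages around the resting spot. Whiteness and snow
are visual estimates in 20% increments; just-initiated and nearly-complete
moults are scored 5% and 95%, so the legal whiteness grid is
{0, 5, 20, 40, 60, 80, 95, 100}. Absent behavioural measurements are `NA`,
never zero — zero is a legal data value. The attempt index is supplied in
the data rather than recomputed because unsuccessful location attempts
leave no observation row but still habituate the animal.

Each site carries its own month-to-season calendar (at the high-elevation
site winter runs November–April; at the low site December–March), because
all seasonal behaviour contrasts are defined relative to local climate.

## The change-point model of the moult

Whiteness of hare-year unit $i$ at season-day $t$ follows a
piecewise-linear ramp between two change points:

$$\mu_{it} = 100\,\mathrm{clamp}\!\left(\frac{t - \mathrm{init}_i}
{\mathrm{dur}_i},\,0,\,1\right)$$

rising in autumn and mirrored ($100(1-\cdot)$) in spring. Observed
whiteness is $y_{it} \sim N(\mu_{it}, \sigma_{obs}^2)$; grid-scored values
are treated as point observations (an interval-censored likelihood over the
20% bins is a documented alternative we did not implement — with
$\sigma_{obs}$ around 7–8% the Gaussian treatment recovers generating
parameters without visible bias in our recovery tests).

Hierarchy and covariates:

* $\mathrm{init}_i = \mu_{init} + \varepsilon_i$,
  $\varepsilon_i \sim N(0, \sigma_{ind}^2)$. Random effects act on
  *initiation*, with the rate shared; the alternative (random rates) is
  noted but not implemented. The unit is the hare-year, so a hare observed
  in two autumns contributes two units — this is what makes between-year
  reaction norms estimable.
* $\mathrm{dur}_i = \bar d\,\exp(\beta_{snow}\,\overline{snow}_i +
  \beta_{temp}\,\overline{dd}_i) + \beta_{sex}\,x_i$, floored at one day,
  with $x_i = -1$ for females and $0$ for males (a positive $\beta_{sex}$
  means females finish earlier). Covariates enter as multiplicative rate
  modifiers through an exponential link; the link is a design choice — the
  direction of effects (snow slows the spring brown-out) is what the model
  is meant to capture, and the sign convention is tested. Time-varying
  covariates are summarised per hare-season as window means; a day-resolved
  rate integral is out of scope.

Priors (all configurable via `moult_priors()`): uniform $\mu_{init}$ over
the season-day window (default 0–120), uniform $\bar d$ over 1–120 days,
half-normal(15) for both SDs, and diffuse $N(0, 10^2)$ for each $\beta$.
$\sigma_{obs}$ is bounded below at 0.05% to keep the likelihood proper.

### Sampler

`fit_changepoint()` uses adaptive random-walk Metropolis-within-Gibbs:

* scalar parameters are updated one at a time with normal proposals whose
  scales adapt every 50 warmup iterations toward a 44% acceptance rate
  (diminishing adaptation; scales are frozen after warmup);
* the conditionally independent $\varepsilon_i$ are updated in one
  vectorised sweep per iteration;
* two reparameterisation moves fix the slow directions of this posterior: a
  *recentering* move ($\mu_{init} \to \mu_{init}+\delta$,
  $\varepsilon \to \varepsilon-\delta$; likelihood-invariant) and a
  completion-preserving *trade-off* move ($\mu_{init}+\delta$,
  $\bar d-\delta$).

Covariates are centred internally, so the derived population completion
date is simply $\mu_{init} + \bar d$ per draw (at observed covariate
means). Two or more chains are run from jittered data-driven starts
(interpolated 50%-crossing days); convergence is summarised by split-chain
potential scale reduction, with a warning flag above 1.05. Intervals are
equal-tailed 95% credible intervals. A seed is mandatory; chains derive
sub-seeds from it, so fits are exactly reproducible.

Weakly identified coefficients (notably $\beta_{sex}$ with few units) mix
slowest; the defaults used by the test suite (2 chains × 1000–2000 draws
after 700–1500 warmup, 20–30 units of ~9 sightings) give R-hat below
1.01–1.05 for the date parameters, which are the quantities of interest.

### Derived quantities

`covariate_shift()` transforms each posterior draw into the change of the
completion date when one covariate moves between two values, holding the
others at their means. `reaction_norms()` extracts, for hares observed in
the same season in two or more years, per-year fitted initiation and
completion (posterior mean of $\mu_{init} + \varepsilon_i$ plus the
unit-specific duration) next to the raw trajectories; a rate shift between
years therefore shows up in the completion difference only insofar as the
unit covariates carry it, which mirrors the model's assumption of a shared
base rate.

## Camouflage metrics

Contrast is the signed difference (whiteness − snow), positive for a white
hare on bare ground. Mismatch thresholds are inclusive at ±60% (the default
threshold is configurable in `classify_mismatch()` and `study_config()`).
Degree days accumulate the *magnitude* of sub-zero daily means in the
autumn window (September–December) and above-zero means in spring
(March–June), so both seasons are non-negative and comparable; windows must
be gap-free — missing days are an error, never imputed, and series that
begin mid-window simply accumulate from their first day. Weekly averages
use ISO weeks within ISO week-based years.

## Behavioural analyses

All three analyses share the candidate-set machinery: terms whose pairwise
|r| ≥ 0.8 (whiteness and snow cover, for most of the year) never co-occur
in a model; a quadratic contrast term is available and only ever appears
with its linear parent; AICc ranks maximum-likelihood fits and the best set
is everything within 2 ΔAICc. Habituation to repeated human approaches is
handled first: for each truncation point $k$, the response is regressed on
attempt index (random intercept per hare) using attempts ≤ `k`; the kept
dataset is the largest `k` whose slope 95% Wald interval includes zero. If
every `k` declines significantly, the minimum is used, with a warning. The
interval criterion is a documented choice (`conf` is configurable) — the
alternative "first significant k minus one" rule coincides with it whenever
the decline is monotone.

*Concealment* is modelled as a continuous 1–4 response with identity link
(an ordered-logit variant is a non-goal). Fixed-effect precision for the
best model is summarised by sampling a normal approximation at the ML mode
(the sampling method is recorded in the fit object) and reporting shortest
95% HPD intervals. Singular random-effect fits are flagged and retained.

*Flight initiation distance* is distance-censored time-to-event data on the
approach-progress scale: progress = 20 − distance, so flight at 12 m is an
event at progress 8 and "no flush" is right-censoring at progress 17 (the
3-m floor). The origin of the scale is a convention; partial likelihood
depends only on the order. Ties are handled by the Efron approximation
(distances are metre-rounded, so ties are common). AICc uses the event
count as sample size. Proportionality is checked per term with scaled
Schoenfeld residuals (`survival::cox.zph`); non-proportionality is reported,
not fatal. Constant covariates are dropped with a warning; models too rich
for the event count get infinite AICc rather than an error.

*Resting spots* form a used–available design: each pie-slice sighting
yields nine rows (1 used + 8 available), excluding locations that are
entirely snow-covered or snow-free (no information about choice). The
binomial logit mixed model uses random intercepts for hare and for location
within hare. Because each location contributes exactly one used spot, the
*marginal* logit slope pooled across a whole season is attenuated relative
to the within-location (conditional) preference whenever between-location
snow variation dominates within-location variation — the seasonal 0–100%
snow sweep does exactly that. The package therefore also provides a
conditional-logit cross-check (`fit_resting_clogit()`, one stratum per
location), and recovery tests use a single-snapshot generator
(`simulate_resting_choices()`) in which the attenuation is negligible.
Complete separation in the fixed-effect fits is detected and refitted with
a Firth (Jeffreys-prior) penalty, flagged in the result.

## The synthetic-data generator

`simulate_hares()` emulates the study design end to end: two sites ~330 km
apart with offset phenologies (the high-elevation site moults to white
about two weeks earlier in autumn and a month later in spring), weekly
location attempts thinned by a detection probability (default 0.8), and
mortality as a discrete weekly hazard (default 0.03, leaving roughly half
the hares alive after a 23-week season; lifespans are geometric, so mean
lifespan is 1/h weeks — a closed form the tests exploit). Default moult
parameters: autumn initiation day 28 (high site) / 40 (low site) from
1 September, spring day 63 / 35 from 1 March, durations 39.9 and 41.9
days, $\sigma_{ind}$ = 5 days, $\sigma_{obs}$ = 8%. Covariate coefficients
($\beta_{snow}$ = 0.002 per %, $\beta_{temp}$ = −2×10⁻⁴ per degree-day,
$\beta_{sex}$ = 2 days) are the generator's own study conditions: the
magnitudes published for this system are on an unstated scale and serve
only as directional context, so values were chosen once to give moderate,
recoverable plasticity at desk-scale sample sizes.

Snow follows a per-site-year scenario: a 10-day ramp to full cover at
onset, a plateau, a 14-day melt, plus transient fluctuations against the
seasonal direction — week-long early-autumn snowfalls (default amplitude
60%) that melt out before the seasonal onset, and optional late-spring
snowfall bumps. The early snowfalls matter: they are what exposes
still-brown hares on snowy backgrounds, making negative mismatch (and its
flight-response coefficient) estimable at all. Each hare carries a
persistent local-snow offset (SD 15%) — microhabitat patchiness — which is
also what makes $\beta_{snow}$ identifiable within a site. Observed scores
are snapped to the legal grids; the noise-free limit ($\sigma_{obs} = 0$)
skips snapping and reproduces the analytic trajectory exactly (such tables
are for diagnostics and deliberately bypass the grid validation).

Concealment is drawn from an ordered logit (site, season, contrast linear
and quadratic, hare random effect, optional habituation decline); flight
trials from a constant baseline hazard over approach progress with
log-linear covariates, inverse-transformed on the distance scale and
censored below 3 m; resting spots by a multinomial choice among nine
candidate spots with logit weights in snow cover, the unchosen eight
becoming the pie slices. All randomness flows from one seed through named
sub-streams (`stream_seed()`), so any stage regenerates identically.

What the generator does **not** emulate: spatial movement (pie-slice snow
is local snow plus noise, not a landscape raster), photo-based scoring
error structure, observer identity, photoperiod mechanisms, and
autocorrelated day-to-day weather. Passing recovery tests therefore show
the estimators are correct under the stated sampling design, not that the
design assumptions hold in any particular field system.

## Numerical and design choices

* Dates are ISO-8601; all day arithmetic is integer days (the field
  resolution is weekly).
* Grid snapping maps to the nearest legal value; ties resolve to the
  smaller value, and latent values below 2.5% snap to 0 while 2.5–12.5%
  snap to 5, mirroring the field convention of scoring just-initiated
  moults as 5%.
* The likelihood with $\sigma_{obs} = 0$ is degenerate and returns −Inf
  unless the fit is exact (documented in `log_likelihood()`).
* Mismatch classes become factors with reference level `"none"`, so model
  coefficients read as the effect of becoming mismatched.
* Cox times are shifted by +1 before fitting (coxph requires positive
  times); the shift preserves risk-set order and thus the partial
  likelihood exactly.
* Habituation truncation conditions in the acceptance suite use 90 hares
  (the field analysis pooled 139) and a latent decline of 2 logits per
  attempt past onset; with every hare collared in week one the attempt
  index is confounded with calendar season, so the "flat" calibration case
  staggers entry — under fixed entry the generator's own seasonal
  concealment cycle is a real decline, and detecting it is correct
  behaviour, not a false positive.
* Problem sizes in tests (30–90 hares, 1–2 years, 2 chains × ≤2000 draws,
  10–20 replicates per calibration) were chosen as the smallest designs at
  which the recovery properties hold with comfortable power.

## Known limitations

* The Gaussian point-observation model ignores the interval censoring of
  grid scores; with realistic scoring noise this is immaterial, but at very
  small $\sigma_{obs}$ the model can be overconfident.
* Random effects on initiation only: a hare whose *rate* genuinely differs
  between years is captured only through its covariates.
* The marginal used–available coefficient is attenuated under strong
  between-location heterogeneity (see above); interpret it jointly with the
  conditional-logit cross-check.
* $\beta_{temp}$ is identified mainly across sites (within a site, window
  mean degree days barely varies between hares); single-site fits estimate
  it from sighting-window differences only.
* The habituation rule tests each truncation point at 95% confidence, so
  across many candidate points occasional early truncation is expected at
  the type-I rate.
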