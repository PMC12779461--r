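---
title: "Surveillance definitions and the counterfactual pre/post estimator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveillance definitions and the counterfactual pre/post estimator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nvhap)
```

Non-ventilator-associated hospital-acquired pneumonia (NV-HAP) is the most
common healthcare-associated infection, yet it has no gold-standard
measurement. This package implements two surveillance definitions over
routine electronic health record data — a deterministic clinical rule set
and a discharge-coding rule — together with the statistical machinery to
track both over calendar time and to estimate the effect of a staggered,
site-level prevention initiative on a risk-difference scale. Because real
multi-site inpatient data cannot be shipped, the package also contains a
full synthetic cohort generator with known ground truth, and every
estimator is validated end-to-end against that truth.

## The electronic clinical definition

A hospitalization is called NV-HAP when a non-ventilated patient shows
*new respiratory deterioration*: at least two consecutive worsening days
of oxygenation after at least two stable-or-improving days, together with
concurrent signs of infection and treatment. Day `d >= 2` of a stay is
labelled *worsening* when the supplemental-oxygen device rank (0 = room
air through 5 = invasive ventilation) increased from the previous day,
or, at unchanged rank, the daily minimum SpO2 fell by at least 3
percentage points. Onset day `d` is a candidate when days `d` and `d+1`
worsen and days `d-1`, `d-2` are stable (day 1, which has no comparator,
counts as stable for the baseline requirement, so the earliest possible
onset is day 3). A candidate becomes an event call only when all of the
following hold:

* fever (daily maximum temperature >= 38.0 °C) or leukocytosis (daily
  maximum WBC >= 12.0 x 10^3/µL) on some day in `[d-1, d+1]`;
* chest imaging on some day in `[d-1, d+2]`;
* a *new* antibiotic class — absent on days `[d-2, d-1]` — first given on
  a day in `[d-1, d+1]` and administered on three consecutive days, with
  no credit for courses cut short by discharge;
* no ventilation on days `[d-2, d]`.

Only the first adjudicated event per hospitalization is counted. All
thresholds and windows are explicit in `detection_rules()` and recorded on
the detector output; the defaults above are our operationalization of the
narrative definition, and the SpO2 drop of 3 points in particular was
chosen because a 1-point criterion would be dominated by measurement
noise. Two consequences of the window arithmetic are worth knowing.
First, a qualifying course can effectively only *start* on day `d` or
`d+1`: a start on `d-1` would contradict the new-class lookback, which
covers `[d-2, d-1]`. Second, the full pattern (two baseline days, two
worsening days, a three-day course from onset) requires a stay of at
least five days, so events in shorter stays are structurally
undetectable. Missing daily values never create evidence: a missing SpO2
cannot worsen, a missing temperature cannot be febrile — the
missing-imputed-as-normal stance applied consistently.

## The diagnostic coding definition

A hospitalization qualifies when a primary or secondary discharge
diagnosis carries a qualifying pneumonia code with an explicit
present-on-admission flag of `N`. The code set comprises the exact codes
B95.3, B96.0, J13, J84.111, J84.116, J84.117, J84.2, J85.1, J85.2 and the
whole J15, J16, J17 and J18 families (the three-character root with or
without extensions). Codes are compared after normalization (uppercase,
dots and whitespace stripped) so both coding dialects classify
identically. POA values `U`, `W` and missing are treated as *not*
qualifying: hospital onset must be affirmatively documented. This is the
conservative reading; a registry that counted `U` as eligible would call
slightly more hospitalizations.

## Temporal trend models

Each outcome gets a population-level logistic model that is linear in
days since the study start; slopes are reported per year (x 365.25) and
the fitted risks at the study's first and last day are contrasted with a
delta-method confidence interval. The two NV-HAP definitions are compared
in one model containing a definition main effect and a definition-by-time
interaction, estimated on the two-rows-per-hospitalization long table.
Clustering by hospitalization is handled with an independence working
correlation and cluster-robust (sandwich) standard errors — for two-row
clusters this is the standard GEE choice, and the interaction's robust CI
is the test for diverging trends. Length of stay is modelled with a
hurdle: admissions always stay at least one day, so the hurdle sits at
LOS = 1 (a logistic component), and LOS - 1 on longer stays follows a
zero-truncated negative binomial with log-linear mean and dispersion
`theta` (variance mu + mu^2/theta). No R package in our stack fits
truncated NB regression, so the count component is maximized directly by
BFGS with an analytic score, a Poisson warm start, and clamped linear
predictors; its covariance comes from the numerical Hessian at the
optimum. Observed-versus-fitted quarterly summaries back the trend plots.

## The counterfactual pre/post estimator

For each site the year after its implementation date is compared with
what the year before predicts. Two models are fitted on pre-period data
only: (1) the hurdle-NB for length of stay given site, calendar year,
week-of-year harmonics and the admission covariates, and (2) a logistic
model for the outcome given the same design plus length of stay. For
each post-period patient the law of total probability combines them into
a counterfactual event probability,

    p_cf(x) = sum_{l=1}^{L_max} P(LOS = l | x) P(event | LOS = l, x),

with the hurdle-NB mass renormalized over `1..L_max`; `L_max` is the
99.9th percentile of pre-period LOS capped at 120 days, so the truncated
tail (heavy, and event-enriched) is folded back proportionally rather
than dropped. Site-level counterfactual risk is the mean of `p_cf` over
the site's post patients, and the risk difference is `actual -
counterfactual`: a protective intervention is negative. Treating length
of stay inside the sum lets the intervention act both directly on
pneumonia risk and indirectly through shorter stays; 30-day mortality is
standardized without the LOS mediator, and the LOS secondary outcome uses
the hurdle model's conditional mean. Calendar enters continuously (year
as a linear term, week-of-year as one sine/cosine pair) because
categorical year levels unseen in a site's pre year could not be
predicted in its post year; the linear year term extrapolates.

Because all sites share the two pre-period fits, the site-specific risk
differences are correlated. Their covariance is obtained by the delta
method: the gradient of each site's counterfactual risk with respect to
the stacked parameter vector is computed by forward finite differences
(relative step 1e-5), the parameter covariance is block-diagonal over the
three component fits (hurdle, truncated NB, outcome — treated as
independent, an approximation the bootstrap study quantifies), and each
site's own diagonal adds the sampling variance of its actual risk. The
matrix is symmetrized; an eigenvalue deficit below 1e-10 relative is
projected away with a warning, anything worse is an error. Pooling uses
classic inverse-variance weights built from the marginal variances, with
the *full* covariance entering the pooled variance, so the shared-fit
correlation properly widens the pooled interval.

One small-sample property matters at low event counts. The natural
plug-in for the binomial part of a site's variance is `p_hat (1 -
p_hat)/n`, but with few expected events per site that estimate is
strongly coupled to the site's own numerator: sites that happened to see
fewer events get smaller variances, hence larger weights, exactly when
their risk difference is most negative, biasing the pooled estimate
downward and degrading interval coverage. `evaluate_effect(...,
stabilize_binomial = TRUE)` substitutes the model-based (counterfactual)
risk in that term, decoupling the weights from each site's numerator;
with roughly ten or fewer expected events per site per window this
variant is the one to use, and it is what the package's replicate studies
use. At the scale of a large hospital system (tens of expected events
per site) the two agree closely.

Secondary analyses reuse the same machinery with a shifted boundary
(91 days earlier for anticipatory effects, or the roll-out completion
date for delayed effects) or restricted to non-ICU admissions.
Readmissions are independent hospitalizations throughout.

## The synthetic cohort generator

`sim_config()` defaults describe the emulated system: 17 sites observed
October 2015 through December 2019, implementation dates staggered so
each site has a full year on both sides, Poisson site-week admissions,
independent Bernoulli admission flags (comorbidities, admission
vital/laboratory abnormality indicators, ICU ward), hurdle-NB length of
stay with mean near 6.1 days, true NV-HAP risk near 0.6% of
hospitalizations rising with length of stay, 30-day mortality near 4.9%,
an annual sinusoid on both the event and LOS scales, and discharge
pneumonia coding with sensitivity 0.55, specificity 0.996 and a secular
log-odds drift of -0.18 per year — so by construction the coding-based
rate declines over calendar time while the clinical-criteria rate stays
flat, the diverging-trends phenomenology the trend models must resolve.
The intervention is null by default (`direct_effect_log_odds = 0`,
`los_effect_multiplier = 1`); any non-null effect is an explicit choice,
and `ground_truth_effects()` integrates the generative model exactly
(covariate enumeration, monthly seasonal quadrature, LOS summation with
tail mass below 1e-12) to give the true marginal risks and risk
difference an estimator run can be compared against. The truth table
also carries a closed-form per-patient counterfactual probability with
all post-implementation indicators switched off.

Day-level records are quiet by construction — stable SpO2 (jitter never
reaches the 3-point criterion), afebrile, normocytic, no imaging — and
event signatures are planted explicitly: onset uniform on days
`3..LOS-2` of stays of at least five days in non-ventilated patients,
with either device escalation or an SpO2 drop, fever or leukocytosis at
onset, imaging at onset, and a reserved antibiotic class given on onset
and the two following days. Planting is restricted to two reserved
classes so background antibiotic courses can never collide with the
new-class lookback. Every planted signature is detected at its planted
onset and nothing else is detected on quiet records; that round-trip at
cohort scale, with all five single-criterion ablations, is the detector's
core validation.

What the generator does *not* emulate bounds what passing tests show
about real data: flags are independent rather than correlated,
oxygenation has no autocorrelated physiology, there are no transfers,
no inter-hospital variation in coding practice or baseline risk, no
documentation artifacts, and the electronic definition is exactly
recoverable by construction. The validation demonstrates that the
estimators recover the truth when their models are correctly specified —
the counterfactual machinery's assumptions, not the definitions'
clinical accuracy.

## Validation studies and problem sizes

The package's replicate studies run at a deliberately reduced scale — a
17-site system with about 1,500 admissions per site per window for the
null-calibration study (500 replicates; the pooled 95% CI should cover
zero in 93–97% of them) and about 1,250 for effect recovery (200
replicates of a -0.15 percentage-point true risk difference induced
through the direct-effect parameter and verified against
`ground_truth_effects()`, with the mean pooled estimate required within
±0.03 points). At this scale the generator has no site effects and no
secular trend in true risk, so the reduced-scale analysis drops the site
indicators and the calendar-year term from the adjustment design (the
model stays correctly specified, and rare-event logistic fits keep a
sound events-per-parameter ratio) and uses the stabilized binomial
variance discussed above; the full-scale defaults keep site and year.
These studies consume the generator's true event indicator directly —
the day-level detector has its own round-trip study — so each replicate
exercises generation, the two pre-period fits, standardization, the
delta-method covariance and pooling. The delta method itself is checked
against a 500-replicate nonparametric bootstrap of the pre-period data
at 4 sites x 2,000 admissions per window, comparing the model-based
variance components site by site within 15%, and the standardization sum
is checked against brute Monte-Carlo integration (10^6 draws from the
fitted truncated hurdle-NB per covariate row).

## Known limitations

The electronic definition here is a faithful operationalization of the
narrative rule, not a certified port of any registry implementation;
concurrency windows and thresholds are configurable precisely because
"concurrent" admits readings. The delta-method covariance treats the
component fits as independent blocks and linearizes; both approximations
are quantified, not removed, by the bootstrap comparison. Fixed-effect
inverse-variance pooling is the design — between-site heterogeneity of
the true effect is out of scope, as are interrupted-time-series designs
and ward-level roll-out modelling. Finally, the continuous calendar-year
term extrapolates one year beyond the fitting window by construction;
with a strong nonlinear secular trend that extrapolation, not the data,
would drive the counterfactual.
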