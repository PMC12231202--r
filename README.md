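# gooseSurv

First-year post-release survival analysis for GPS-tracked migratory
geese.

Newly released geese — wild-caught for surveillance tagging or
rehabilitated after rescue — are most vulnerable between release at the
wintering grounds and their first northward migration. Working out *why*
some survive requires chaining together several kinds of evidence from
hourly multi-sensor telemetry: behaviour (accelerometer-derived activity
counts), movement phenology (when did the bird actually leave?), space
use (kernel home ranges), local weather exposure, and a defensible rule
for deciding that a silent transmitter means a dead bird rather than a
shot one or a failed tag. gooseSurv implements that full chain for
biologists running telemetry-based release programmes, with a synthetic
cohort generator (known ground truth) so every stage can be validated.

## The statistical core

* **Activity**: hourly movement counts increment when overall dynamic
  body acceleration, ODBA = |aₓ| + |a_y| + |a_z| (gravity removed),
  exceeds 0.15 G; daily activity is the 24-hour sum and ActAvg its mean
  from release to migration onset.
* **Mortality rule**: death is confirmed only when three criteria hold
  simultaneously — device temperature within ±2 °C of ambient for
  ≥ 72 h, under 10 counts/h for ≥ 24 consecutive hours, and all
  positions within a 200 m radius for ≥ 72 h — after excluding
  hunting-like abrupt signal loss; survivors are right-censored at 365
  days.
* **Space use**: 95% / 50% isopleths of a Gaussian-kernel utilization
  distribution; hierarchical clustering of individuals; Global Moran's
  I = (n/S₀)·Σᵢⱼ wᵢⱼ(xᵢ−x̄)(xⱼ−x̄)/Σᵢ(xᵢ−x̄)², E[I] = −1/(n−1), on
  survival times.
* **Survival layer (implemented natively, cross-checked against the
  `survival` package in tests)**: Kaplan–Meier product-limit
  S(t) = ∏_{tᵢ≤t}(1 − dᵢ/nᵢ) with log-rank tests; Cox proportional
  hazards h(t|X) = h₀(t)·exp(Xβ) via Newton–Raphson with Efron ties,
  Wald CIs, concordance, Schoenfeld PH diagnostics; VIF > 5 screening;
  all-subsets AIC selection with the ΔAIC < 2 parsimony rule.

## Worked example

The `analysis/` directory is a five-stage narrative over the package
API. Stage 1 simulates the default cohort (40 geese, hourly fixes,
365-day horizon) and writes raw CSVs; stages 2–5 read them back through
the package's own readers. Running

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/03_mortality_fates.R
Rscript analysis/05_survival_models.R
```

prints (abridged):

```
cohort: 40 individuals, 274515 hourly fixes
censored_resident 8 | hunting_loss 6 | natural_death 10 | survivor_migrant 16

fate recovery: 100 % of 40
death-time error (h): max abs 0 over 10 deaths
events: 10 | censored: 30 (incl. 6 hunting-excluded)

VIF screen retained: Releasetime, StayDur, ActAvg, KDE, Weight, VISIB, WDSP, TEMP, PRCP
final model (all-subsets, parsimony within delta-AIC < 2): VISIB + WDSP + PRCP
  term        HR   HR_lower  HR_upper           p
 VISIB 0.2731128 0.10660763 0.6996742 0.006850029
  WDSP 0.2515985 0.08457771 0.7484454 0.013104847
  PRCP 2.0215488 1.18515271 3.4482135 0.009781470
AIC: 55.22  concordance: 0.85
```

Reading this: the classifier recovered every simulated fate, with death
times exact to the hour — the post-mortem signature (thermal
equilibration + quiescence + confinement) pins the triple-overlap start
to the true death. The 40-bird Cox selection lands on 14-day weather
covariates: with only 10 events, covariates that track *season of
death* (visibility, precipitation) can outcompete the true hazard
drivers. That instability is expected at this sample size, which is why
hazard-ratio recovery is validated separately: over 100 replicate
cohorts of n = 500 generated with HR 0.461 (activity) and 2.311 (wind
speed), the native Cox fitter's 95% CIs cover both generating
coefficients ≥ 90% of the time (see below).

Stage 4 output on the same cohort:

```
home range (95% KDE): median 24.8 km2; core (50%): 5.7 km2
clusters at silhouette-best k = 2 : 22/18
Moran's I on survival: I=0.047 (E[I]=-0.026), perm p=0.121
```

No spatial autocorrelation of survival — correct here by construction,
since the generator ties hazard to behaviour and weather, not location.

## Layout

```
R/                  package implementation (generator, IO, activity,
                    migration, mortality, space use, KM/Cox, pipeline)
analysis/01..05_*.R narrative drivers writing results/
tests/testthat/     unit, property and acceptance tests (brute-force
                    oracles live in helper-oracles.R)
scripts/acceptance.R  the reproduction script above
vignettes/          methods vignette: models, assumptions, conventions
inst/extdata/       published design-table counts and tracker masses
```
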