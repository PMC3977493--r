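---
title: "Percentile BMI trajectory models after gastric bypass: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Percentile BMI trajectory models after gastric bypass: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rygbtraj)
```

## The model

Weight loss after Roux-en-Y gastric bypass (RYGB) varies widely between
patients, so a single "average" curve is a poor counselling tool. This
package works with *conditional percentile* trajectories instead: for a
patient with preoperative BMI $B_0$ and age $A$, the $\tau$-th percentile
of BMI at $t$ months after surgery is modelled as

$$
Q_\tau(t \mid B_0, A) = \beta_0
 + \beta_1 (B_0 - 50) + \beta_2 (A - 50)
 + \beta_3 d + \beta_4 d^2 + \beta_5 d^3
 + \beta_6 (B_0 - 50)\, d + \beta_7 (A - 50)\, d,
 \qquad d = t - 6 .
$$

Each percentile (25th, 50th, 75th) has its own coefficient vector, fitted
separately by quantile regression — minimisation of the check (pinball)
loss $\rho_\tau(r) = r\,(\tau - \mathbf{1}\{r < 0\})$ over all pooled
weight measurements. A lower *BMI* percentile means *more* weight loss.

The parameterisation is centred at baseline BMI 50 kg/m², age 50 years
and 6 months post-op, so the intercept $\beta_0$ is directly the
predicted percentile BMI of the "reference" patient at six months. The
packaged default coefficient set (`published_modelset()`) carries the
fitted values of a primary cohort of 2608 RYGB patients with 47,908
pooled weight measurements; converters to and from the raw-covariate
parameterisation are provided (`uncentered_to_centered()`).

Model validity ranges are baseline BMI 35–95 kg/m², age 18–74 years and
0–36 months. The cubic time polynomial is a smoothing device, not a
mechanistic model: outside 0–36 months it is unsafe, which is why queries
beyond the ranges raise an error by default and are only downgraded to a
warning behind an explicit `extrapolate = TRUE`. Preoperative (negative)
times are rejected unconditionally; $t = 0$ is the date of surgery, and
calendar dates convert to fractional months at a fixed 30.4375 days per
month so conversions are deterministic.

### Properties the published curves satisfy

On the whole study domain the three published curves are non-crossing
($Q_{0.25} \le Q_{0.5} \le Q_{0.75}$), strictly increasing in baseline
BMI (the effective slope $\beta_1 + \beta_6 d$ stays positive for
$t \in [0, 36]$), non-decreasing in age, and the median reference curve
has its nadir strictly inside 12–24 months followed by modest regain —
the clinically expected shape. The test suite asserts all of these on a
dense grid. Crossing of *refitted* curves on new data is flagged as an
error where it matters (the simulator) and is never silently repaired;
rearrangement post-processing is out of scope.

## Fitting: an exact simplex for the check loss

`fit_quantile()` solves the quantile-regression linear program exactly
rather than approximately. At a vertex of the check-loss surface the fit
interpolates exactly $p$ observations (the *basis*); the solver walks
between bases along edges of the polytope, choosing at each step the edge
with the most negative one-sided directional derivative and finding the
step length by scanning residual sign-change breakpoints. A smoothed
iteratively-reweighted least-squares pass provides the warm start, which
keeps the number of pivots small (typically a few dozen at $n \approx
30{,}000$, $p = 8$).

Two deterministic conventions make the solver reproducible to the bit:

* **Tie-breaking on flat optima.** Check-loss minimisers can form a flat
  interval (for example the sample median of an even number of points).
  After reaching an optimal vertex the solver slides along any
  zero-derivative edge whenever doing so produces a lexicographically
  smaller coefficient vector (intercept first). For intercept-only
  designs this reproduces the classical lowest-minimiser sample-quantile
  convention, which is what the brute-force oracle in the tests computes.
* **Degeneracy.** Observations with exactly zero residual that are not in
  the basis are accounted for in the directional derivative directly
  (they flip sides the moment the fit moves), so no zero-length pivots
  are taken and the objective strictly decreases at every step — the
  solver cannot cycle.

The achieved mean check loss is reported with the fit and can never
exceed the loss of the generating truth on simulated data — an invariant
the tests verify. A `method = "smooth"` fallback (pure IRLS) is available
for very large problems where a vertex solution is not required.
Repeated measures are pooled as independent observations in the loss,
mirroring how the published model was fitted; no clustering correction is
applied.

Percentile predictions themselves are computed with a fixed left-to-right
accumulation rather than BLAS matrix products, so scalar and vectorised
evaluation agree bit-for-bit; the lookup-table generator
(`lookup_table()`) is therefore exactly `evaluate_percentile()` composed
with round-half-even display rounding (one decimal), and its default
grids reproduce the published 7 × 3 × 3 × 3 = 189-cell table structure.
Hand evaluation of the published formulas can differ from the originally
printed lookup-table cells by roughly 0.1–0.2 kg/m² (the printed tables
appear to have used unrounded coefficients); this package reproduces the
formulas, and no agreement with the printed cells is forced.

## Outcome extraction and tracking

Standard bariatric outcomes are computed from a patient's measurement
series: BMI uses the baseline height throughout; *excess* weight is
defined against the weight at BMI 25 (the dominant convention —
`ideal_weight()`), making percent excess weight loss
$100 (W_0 - W)/(W_0 - W_{25})$ affine in current weight; the weight-loss
nadir is the earliest minimum observed BMI; and the 6-month loss uses the
measurement nearest 6.0 months within ±1.5 months (nearest, then earlier
on ties — the window admits the 5-month clinic visit but excludes the
8-month one; whether the original analysis used a window or interpolation
is not stated, so this rule is a package choice). An absent 6-month
measurement yields a missing value, not an error.

`track()` classifies each measurement against the predicted percentiles
at its time into bands `below_25`, `25_to_50`, `50_to_75`, `above_75`.
Boundaries are half-open upward: a BMI exactly on a percentile curve
belongs to the band above it (less weight loss), a deterministic rule in
the absence of a stated convention.

## The synthetic-cohort generator

Because the source cohort's patient-level records are not public, the
package ships a simulator whose defaults emulate the study conditions; it
is the test bed for fitting, screening and tracking.

* **Covariates.** Age ~ truncated Normal(45.8, 11.2²) on [18, 74] years;
  baseline BMI ~ truncated Normal(49.5, 8.7²) on [35, 95] kg/m²; 81%
  female. Height is not described in the source cohort, so heights are
  drawn from truncated Normal(1.66, 0.09²) m on [1.4, 2.1] — an invented,
  documented and configurable choice that makes weights derivable from
  BMI. A diabetes indicator (default prevalence 0.35, also an invented
  constant) has *no* effect on simulated trajectories: it exists as a
  null covariate for screening tests.
* **Visit process.** Nominal visits at 1 and 2 weeks, 2, 5, 8, 12 months,
  then every 6 months to 36; each visit time is jittered ±10 days
  (uniform) to keep nearest-visit logic honest, floored at 1 day and
  capped at the model time range.
* **Trajectories.** For a query $(B_0, A, t)$ the three percentile
  predictions are interpreted as knots of a conditional BMI distribution:
  piecewise-linear in probability between the knots, with Gaussian-shaped
  tails anchored at the outer knots using
  $\sigma = (Q_{0.75} - Q_{0.25}) / (2 z_{0.75})$, $z_{0.75} \approx
  0.67449$. The inverse CDF is exact at the knot levels by construction,
  so the generator's conditional 25th/50th/75th percentiles equal the
  truth model's predictions *exactly* — the property that makes
  end-to-end parameter recovery a meaningful test. Only three quantiles
  are published, so the tails are necessarily invented and are flagged as
  such.
* **Within-patient persistence.** Patients tend to track a percentile
  rather than bounce randomly between visits. Each patient draws a latent
  normal score $Z_i$; visit $j$ uses the rank
  $U_{ij} = \Phi(\rho Z_i + \sqrt{1-\rho^2}\, \varepsilon_{ij})$ with
  $\rho$ = `persistence` (default 0.8, clipped to (0.001, 0.999)). The
  Gaussian-copula form is essential: it keeps every visit's marginal rank
  uniform for *any* persistence, so the conditional quantiles of the
  generated data stay exactly on the truth curves while within-patient
  correlation is freely tunable. (A naive linear mixture of patient- and
  visit-level uniforms would distort the marginal ranks — its 25th
  percentile at persistence 0.8 sits at rank 0.30 — and would bias every
  recovery experiment.) At persistence 1 a patient's whole series lies on
  a single percentile curve; at 0 visit ranks are independent.
* **Attrition.** Follow-up ends at a censoring time drawn from a
  piecewise-constant hazard; visits after it are dropped (each patient
  keeps at least the first visit). The hazard is calibrated so that the
  *expected fraction of patients with at least one retained measurement
  beyond* 6, 12 and 24 months equals 88%, 77% and 53%. Because retention
  beyond a horizon requires surviving to the first scheduled visit after
  it — and visits nominally at 12 or 24 months straddle their horizon
  once jittered — the calibration integrates the jitter distribution of
  that first-visit time numerically and solves for the hazard by a
  deterministic fixed-point iteration (no randomness is consumed).
  Empirical retention at $n = 10{,}000$ lands within a percentage point
  of the targets.

What the simulator does *not* emulate: preoperative (negative-time)
measurements, EHR-style data errors (cleaning tests build their own
corrupted fixtures), secular trends across surgery years, any real effect
of sex or diabetes, and any dependence of dropout on weight-loss success
(censoring is independent of the trajectory). Passing recovery tests on
this generator therefore shows the estimation machinery is correct under
the stated model, not that the model is correct for any particular
clinic's data.

## Covariate screening

`screen_covariates()` reproduces the selection logic that led to the
two-covariate model: each candidate (baseline BMI, age, sex, diabetes) is
regressed against the two patient-level outcomes (6-month percent excess
weight loss and nadir BMI), adjusting for baseline BMI and age, and the
standardised effect (coefficient × SD(candidate) / SD(outcome)) is
thresholded on both outcomes with a consistency requirement: the two
effects must point in the same *weight-loss* direction (a higher %EWL and
a lower nadir both mean more loss). The default threshold is 0.1
standardised units ("moderate/large" is not quantified in the source, so
the default is a package choice, and the threshold is an argument).

Under the generator's own calibration the true standardised effects are
about −0.5/+0.6 for baseline BMI but only about −0.08/+0.07 for age
(age's influence on the curves is real but small relative to the
between-patient percentile spread), with null covariates near 0.005. The
generator-truth test therefore screens at threshold 0.04, where both true
drivers clear the bar with a wide margin and the nulls cannot: at the
default 0.1, age would be rejected under these simulated conditions —
worth remembering when screening modest cohorts.

## Cleaning rules

The source data were screened for implausible values with unpublished
rules, so the package's rules are explicit, configurable package choices:
BMI outside [12, 100] kg/m²; adjacent-measurement BMI change faster than
1.5 kg/m² per week (the offending series is repaired iteratively by
removing whichever measurement most reduces the total violation,
re-checking after each removal); and identical weights within 0.25 months
collapse to one. Bounds are applied first, then the rate rule, then
duplicate collapse; the operation is idempotent and every removal is
logged with the rule that fired.

## Problem sizes and numerical tolerances

The simulation studies in the test suite use cohort sizes chosen to give
clear statistical margins at modest runtime: 4000 patients
(≈31,000 measurements) for the headline recovery of the baseline-BMI
effects (tolerance ±0.03, observed errors ≈0.01), 500/2000/8000 × 3
replicates for the monotone-RMSE recovery property, 5000 patients for
conditional-quantile fidelity (±0.3 kg/m²), 10,000 for attrition
calibration (±2 percentage points) and screening, and 2600 + 5 × 380 for
the primary-versus-validation comparison, whose sampling-noise bound
(mean of per-replicate maximum trajectory difference < 1.5 kg/m²) is
estimated by repeated simulation because a single small-cohort draw is
noisy at the sparse 36-month edge.

Solver tolerances: optimality is declared when every directional
derivative exceeds −10⁻⁹; flat edges are those within 10⁻⁸ of zero;
lexicographic comparisons use a 10⁻⁹ relative tolerance. These are
conventions for declaring exact-arithmetic facts under floating point,
not statistical tunings.

## Known limitations

* The model is descriptive: a cubic in time with linear covariate shifts,
  valid only on the fitted ranges and for RYGB specifically.
* No inference is provided for fitted coefficients (the source reports
  none): no standard errors, no bands, no bootstrap.
* Quantile crossing of refitted curves is detected and reported, never
  repaired.
* The simulator's tails beyond the 25th–75th knots and its height and
  diabetes distributions are invented; quantities that depend on the
  extreme tails of the BMI distribution should not be validated against
  it.
* Baseline BMI is defined at the initial preoperative visit, 6–12 months
  before surgery (before any preoperative diet-induced loss), matching
  the covariate definition the published coefficients were fitted with.
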