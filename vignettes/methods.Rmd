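---
title: "Estimating daily walking steps from large-scale GPS logs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating daily walking steps from large-scale GPS logs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepscape)
```

## The problem

Commercial smartphone applications produce enormous volumes of GPS logs —
timestamped latitude/longitude records at minute resolution — but almost
never carry physical-activity information. A small minority of users of
pedometer applications additionally report a daily step count. stepscape
implements a pipeline that links the two: it models the relationship
between daily *land-use exposure* along a user's movement trajectory and
their daily steps on the small step-reporting subsample, then applies the
fitted model to the large step-free majority, producing a spatial map of
expected daily walking activity.

The pipeline operates entirely on the Japanese standardized grid-square
(mesh code) system: 1 km Basic Grid Squares of 30″ latitude × 45″
longitude, quartered into 500 m and 250 m squares and split 10 × 10 into
100 m squares, identified by digit-string codes computed from coordinates.

## Pipeline stages

1. **Ingestion.** Logs with horizontal accuracy < 200 m (strict) and a
   non-empty identifier are kept. A user-day is *valid* with ≥ 24 logs
   (one per 30 minutes over a 12-hour activity window); users with more
   than 10 valid days are *active*. Logs sharing a (user, minute) pair
   collapse to their arithmetic mean position.
2. **Interpolation.** Gaps between consecutive observed points are filled
   with equally spaced points on the straight segment in degree space, one
   per intermediate minute: a 5-minute gap yields 4 points, a 2-minute gap
   the midpoint. Interpolation runs across day boundaries and the points
   landing on invalid days are deleted afterwards (create-then-delete), so
   flanking valid days keep their share of a multi-day gap.
3. **Residence.** For each user-day, the first and last 5% of points (at
   least one each; the whole day when 2k ≥ n) locate the day's modal 250 m
   grid; the most frequent modal grid across days is the residential grid.
   Tied grids merge when mutually *co-resident* — adjacent or sharing an
   adjacent grid, operationalized as Chebyshev distance ≤ 2 under queen
   contiguity (a rook option is provided; the choice is configurable
   because the original adjacency convention is not documented). Ties that
   fail the test make the user residence-undefinable. The residence point
   is the centroid of the 5%-set points inside the residential grid(s),
   and all trajectory points in those grids are removed before exposure is
   computed.
4. **Exposure.** Each of the 17 original land-use categories is
   reclassified to 8 types (public facilities and parks/green spaces merge
   into `parks_public`; non-urban categories and unmapped cells become
   `other`). For every trajectory point, the 100 m cells whose centroid
   lies within 100 m (great-circle, boundary-inclusive) are counted by
   type and summed per user-day. A cell hit by m points counts m times:
   the quantity is a visit *frequency*, not a visited-cell count, because
   the model treats repeated presence as repeated exposure.
5. **Model.** Daily steps are modeled as

   $$y_{u,d} = \beta_{0,u} + \beta_1\,\mathrm{SEX} + \beta_2\,\mathrm{AGE}
      + \textstyle\sum_{k=1}^{8} s_k(x_{u,d,k}) + \varepsilon_{u,d},$$

   with $x = \ln(\text{count}+1)$, $\varepsilon \sim N(0, \sigma^2_{L1})$,
   and $\beta_{0,u} \sim N(\alpha, \sigma^2_{L2})$. SEX is 1 for female, 0
   for male; AGE is the decade code 10–60 (users 70 and over are excluded,
   as are records missing sex or age). Each $s_k$ is a centered penalized
   cubic regression spline (basis dimension 10 by default); the user
   intercept is a Gaussian random effect; smoothing parameters and
   variance components are selected by REML.
6. **Prediction and mapping.** Step-free user-days get the fixed-effects
   prediction $\hat\alpha + \sum_k \hat s_k(x_k)$ — sex, age, and user
   intercepts are omitted, since these attributes are unknown for most
   users and exposure is the quantity of interest. Per-user means are
   computed for weekdays, weekends/holidays, and each weekend pair of
   October 2019 separately; users are assigned to the 500 m grid of their
   residence point; grids with fewer than five resident users are
   suppressed.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `max_error_m` | 200 m | accuracy filter, strict inequality |
| `min_logs` / `min_valid_days` | 24 / 11 | valid-day and active-user thresholds |
| `radius_m` | 100 m | buffer radius over 100 m cell centroids |
| `adjacency` | queen | contiguity for merging residential grids |
| `k` | 10 | spline basis dimension per land-use smooth |
| `min_users` | 5 | disclosure threshold per 500 m grid |
| holidays | Oct 14, Oct 22 2019 | national holidays in the study month |

## Numerical choices

- **Half-open cells.** Grid membership uses $[south, north) \times
  [west, east)$, so shared edges belong to exactly one cell. Encoding
  adds an epsilon of $10^{-7}$ cell widths before flooring so that exact
  cell corners land in their own cell despite binary rounding of
  arcsecond fractions; the offset corresponds to well under a millimetre
  on the ground.
- **Distances.** All metric distances are haversine on a sphere of radius
  6,371,000 m. Interpolation, by contrast, is linear in degree space —
  planar, matching the geometry-type semantics of the SQL tooling this
  emulates — which over minute-scale gaps differs from geodesic
  interpolation by far less than GPS noise.
- **Ties.** The daily modal grid breaks ties by lexicographically smallest
  code; day-level tallies count each day once. Both rules are arbitrary
  but deterministic: identical inputs give identical residences.
- **Degenerate smooths.** An exposure index with fewer than four distinct
  values cannot support a spline basis and enters the model linearly; a
  constant index drops out (its smooth is identically zero). Exposure
  values outside the training range are evaluated by the spline's natural
  extrapolation with a warning.
- **Buffer window.** The indexed buffer query examines only the cells
  whose centroid could possibly be within the radius (window half-width
  `ceiling(r / cell_extent + 0.5)` cells), then tests exact haversine
  distance; it is exactly equivalent to the brute-force scan, which the
  tests verify on thousands of random queries.

## The synthetic world

The source data this method targets are proprietary, so the package ships
a generator that emulates their structure end-to-end and makes every stage
testable. The generator's defaults are the package's study conditions:

- **Landscape.** A 24 km × 24 km concentric city: high-rise core (1.2 km),
  dense low-rise ring (3 km), low-rise periphery (7 km), four radial
  railway lines with high-rise station clusters every ~1.6 km, seeded park
  and factory patches, a 1 km road lattice, `other` elsewhere — 57,600
  typed 100 m cells. Original category labels are emitted so the
  reclassification step is exercised.
- **Users.** 200 users whose homes cluster around 12 residential
  neighborhood anchors (clustered residential density is what makes ≥
  5-user 500 m grids attainable at desk scale, as in real cities). The
  home point is the centroid of the planted 250 m cell; a "doorstep"
  anchor ~110 m away stays inside the home 250 m cell but outside the home
  100 m cell, so day-start/day-end logs survive privacy masking and
  residence recovery is possible. 15% of users report steps with complete
  sex/age — far above the ~2% share of the commercial feed being emulated,
  because a random-intercept model is not estimable from the handful of
  reporting users that share would leave at n = 200.
- **Logs.** Anchor-based day paths (doorstep → 1–3 destinations →
  doorstep) over a 07:00–21:30 window, sampled at irregular geometric gaps
  (mean 60 logs/day), with 25 m Gaussian position noise, 5% duplicate
  minutes, 8% of accuracy values above the 200 m threshold, and all logs
  inside the home 100 m cell deleted (privacy masking).
- **Steps.** Daily steps for reporting users are drawn from the model
  equation with $\alpha = 7700$, $\beta_1 = -867.5$, $\beta_2 = -19.67$,
  $\sigma_{L1} = 2000$, $\sigma_{L2} = 500$, and piecewise-linear true
  smooths — rising for high-rise, parks/public and railway exposure,
  falling beyond a threshold for low-rise and factories, rise-then-fall
  for dense low-rise, flat for roads and other. Counts are floored at
  zero; under the default parameters flooring affects well under 1% of
  days. True exposure is computed from each user's own emitted logs
  against the landscape with the package's exposure machinery.
- **Storm scenario.** On the second weekend (October 12–13) destination
  distances contract toward the doorstep by a factor of 0.25, emulating a
  typhoon weekend; the mapped output should show that weekend as the
  minimum of the four.

`simulate_exposure_records()` is a faster parametric sibling that draws
exposure counts directly from negative-binomial distributions; it is the
generator of choice for model-recovery studies, where the trajectory
machinery is not under test.

### What the generator does not emulate

No road network, activity scheduling, or transport modes; positional noise
is isotropic Gaussian rather than urban-canyon-shaped; destination choice
ignores land use except through geography. Passing tests therefore
demonstrate that the pipeline's logic is correct and that the model
recovers a known data-generating process of the stated form — not that the
model is correctly specified for real human mobility.

## Problem sizes

The test suite and the acceptance script run the full pipeline at the
default conditions (200 users × 31 days, ~9 million trajectory points
after interpolation, ~5.5 million after residence filtering), model
recovery on a 200-user × 20-day panel (4,000 records), the null-model
check on an 80 × 10 panel, and oracle-equivalence sweeps of 1,000 random
buffer queries over the 57,600-cell landscape. A full acceptance run takes
about two minutes on a single CPU.

## Known limitations

- The exposure measure weights each minute equally; a stationary hour
  contributes 60 point-incidences. Duration-weighted or deduplicated
  exposure variants are deliberately out of scope.
- Fixed-effects prediction transfers the exposure–steps relationship
  from the step-reporting minority to the majority; any selection bias in
  who reports steps transfers with it.
- The random intercept absorbs user-level heterogeneity but the model has
  no spatial random field; spatial autocorrelation beyond land use is
  unmodeled.
- p-values for smooths are the usual Wald-type approximations on
  penalized coefficients with effective degrees of freedom, and should be
  read as approximate.
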