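---
title: "From rearing counts to invasion forecasts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From rearing counts to invasion forecasts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambrosiarisk)
```

This vignette is the package's own account of the science it implements:
the demographic model, the thermal performance curve, the ellipsoid niche
model, and the metapopulation simulator, together with every numerical and
design decision a maintainer would want to audit.

## 1. Demographic reconstruction

The rearing design is destructive: at each colony opening a fresh set of
tubes is dissected, so no tube is observed twice. Per temperature, the
package first averages each stage's counts across the tubes opened on a
given day, then sums those per-day means across the opening schedule. The
resulting accumulated mean `N_k` per stage drives everything downstream:

* stage survivals `S_k = N_{k+1} / N_k` for egg→larva, larva→pupa, and
  pupa→adult females (live + dead);
* adult-female survival as the live fraction, `live / (live + dead)`. The
  alternative quotient (total over live) can exceed 1 and is not used;
* net reproductive rate `R0 = p · H · ∏ S_k`, with `H` the accumulated mean
  egg count per foundress (one foundress per tube) and `p` the hatching
  proportion predicted by a quadratic `p(T) = aT² + bT + c` fitted by least
  squares to surrogate-species hatching data and clamped to [0, 1];
* generation time `G` = first opening day with any progeny adult female
  minus first day with any eggs; and `r = ln(R0) / G` per day.

Assumptions worth stating: counts tabulate progeny only (the foundress is
recorded separately by the experimenter, not in the stage counts);
consecutive-stage ratios above 1 — possible while oviposition is ongoing —
are capped at 1 with a warning rather than rejected; a temperature with no
progeny females has undefined `G`, is flagged non-viable, and is excluded
from the curve fit by default. `exp(r·G) = R0` is enforced as a tested
identity to 1e-10 relative tolerance.

## 2. Thermal performance curve

```
r(T) = r_max · exp(−v0 (T − T_opt)² + v0 (T − T_opt))
```

- `r_max` (/day, > 0): growth rate at `T = T_opt`, where the exponent
  vanishes exactly.
- `v0` (> 0): curvature/kurtosis; larger means narrower thermal breadth.
- `T_opt` (°C): the curve's location parameter.

The exponent has roots at `T_opt` and `T_opt + 1`, so the curve's literal
maximum sits at `T* = T_opt + ½` with `r* = r_max · exp(v0/4)`, about 1.3%
above `r_max` at the fitted values. The functional form is implemented
verbatim; `growth_curve_maximum()` surfaces the distinction rather than
silently relocating the optimum.

Fitting is Levenberg–Marquardt nonlinear least squares (`minpack.lm`),
with `v0` log-reparameterized to keep it positive; its standard error is
recovered by the delta method, so the reported table (estimate, SE, t,
two-sided p on n − 3 df, R², residual SE) is on the natural scale.
Initialization: `r_max` and `T_opt` start at the largest per-temperature
mean response, and a deterministic three-point multi-start over
`v0 ∈ {0.01, 0.05, 0.2}` guards against local optima when the warm tail is
noisy; the lowest-deviance converged fit wins. Convergence tolerance is
1e-10 on the parameter step, at most 1000 iterations. Noise-free data
reproduce their generating parameters to 1e-6 from any sane start (tested).
Constant-response data are a degenerate design: the fit either fails loudly
or returns flagged (NA) standard errors, never a silent answer.

## 3. Ellipsoid niche model

Occurrences are thinned by a greedy pass in stable input order (a record is
kept iff no previously kept record lies within 0.0083° planar distance),
split 70/30 into calibration/validation by a seeded shuffle, and matched to
the environmental layers of their observation year. Variables are filtered
in input order by pairwise Pearson correlation: a variable is dropped if
|r| ≥ 0.8 against any already-retained variable (the paper-silent tie-break
"first in input order wins" is deliberate and documented).

The niche is an ellipsoid in environment space. Default shape: column
means and sample covariance, giving suitability `exp(−D²/2)` with `D²` the
Mahalanobis distance — exactly 1 at the centroid, strictly decreasing
outward, scale-free. A robust minimum-volume-ellipsoid variant
(`MASS::cov.mve`) is available behind `method = "mve"`. Binarization uses
the 10th percentile (linear-interpolation convention, R quantile type 7) of
calibration-point suitabilities; by construction at least 90% of
calibration records fall inside the binary prediction.

Evaluation: bootstrap partial ROC (default E = 0.10: the curve of
sensitivity against proportion-of-background-predicted-present is
integrated where sensitivity ≥ 1 − E and divided by the diagonal's area
over the same range; 1000 iterations of 50% resamples; p = fraction of
ratios ≤ 1). E = 0 is the documented boundary meaning "no truncation", the
classic AUC ratio. Whether the published analysis truncated at 5% or 10%
omission is ambiguous; 0.10 is the default and it is configurable. Omission
rates, background prevalence, and an exact binomial test
`P(X ≥ hits | n_test, prevalence)` complete the report.

## 4. The r_i map

The fitted curve is evaluated on a mean-annual-temperature grid and
multiplied by the binary suitability grid. The curve is strictly positive
everywhere, so masking is the sole zeroing mechanism: unsuitable cells get
`r_i = 0` but remain in the simulation grid and can still relay migrants,
which keeps the dispersal graph irreducible. Cells outside the study region
are NoData and excluded entirely. Inputs must share the grid exactly; the
package never resamples silently. With no geospatial raster stack among the
package's dependencies, grids are a lightweight in-package class
(`grid_raster`) with ESRI ASCII grid (plain text) I/O and an EPSG:4326 CRS
tag.

## 5. Metapopulation simulator

One ODE per cell: `dx_i/dt = r_i x_i − a x_i² + Σ_h δ_hi x_h − Σ_h δ_ih x_i`.

Parameters, units, defaults:

| parameter | units | default | rationale |
|---|---|---|---|
| `D_max` | km/day | 5 | reported daily travel distance for these beetles |
| `b` | – | 1 | kernel shape; no published value, 1 is the package's documented choice |
| `k` | /day | `max(r_i)/10` (global) | "one tenth of the intrinsic growth rate"; the global mode preserves the kernel's written symmetry and irreducibility, `per_source` mode (`k_i = r_i/10`) is available |
| `a` | /individual/day | 1e-7 | published value; note 1e-7 with `r_max = 0.1314` implies `K = r/a ≈ 1.31e6`, while the text's "≈130,000 individuals" matches `a = 1e-6`; both presets ship, neither is adjudicated |
| `x0` | individuals | 100 | seeding abundance at a port; no published value |
| distance | km | haversine | "Euclidean distance using the cell coordinates" is ambiguous at 2.5′; a planar degrees×111.32 mode exists for replication |

Inter-cell rates are `δ = k·exp(−w^b)` for centre-to-centre distance
`w ≤ D_max`, else 0; the sparse matrix stores only in-range pairs, the
diagonal is zero, and global-k matrices are symmetric to 1e-12 (tested
against a brute-force O(n²) construction). Barriers are honoured by zeroing
both directed rates across user-specified pairs.

Integration: classical fixed-step RK4 (default dt = 0.25 day), implemented
in-package so that trace negative excursions can be clamped to zero at each
step (tolerance: values below −1e-3 abort; the clamp count is logged in the
solver metadata). An adaptive path (`deSolve`'s lsoda, rtol = atol = 1e-8)
is available and agrees with RK4 on test problems. Correctness anchors: an
isolated cell matches the closed-form logistic with `K = r/a` to 0.1%;
pure dispersal (r ≡ 0, a = 0) conserves total abundance to 1e-6 on random
sparse matrices (the in/out sums telescope); a symmetric kernel with zero
growth relaxes to the uniform distribution of the initial total.

Analytics: per-cell arrival time = first output time with `x_i ≥` threshold
(default 1 individual; seeded cells get 0; never-colonized cells `Inf`), and
region coverage = fraction of mask cells at or above the threshold, with
the first time it reaches a target fraction. "Covering" a region is
operationalized as 90% of its cells exceeding 1 individual — the published
phrase "time to cover these areas" has no formal definition, so both the
threshold and the fraction are configurable.

## 6. What the synthetic data do and do not emulate

Generators are pure functions of (scenario, seed); a master seed fans out
to per-stage seeds by a stable string hash, so running stages in a
different order cannot change another stage's draws.

* `synth_cohort`: Poisson stage counts (binomial live/dead split) whose
  per-opening expectations make the accumulated means recover the scenario
  truth exactly in expectation — closed forms are exposed via
  `synth_cohort_expectation()` and verified to 2% at 2000 replicates. No
  overdispersion, no within-tube correlation, no stage-duration dynamics:
  passing tests show the estimators are calibrated to the design, not that
  real colonies are Poisson.
* `synth_growth_points`: curve + iid Gaussian noise at the published
  residual SE (0.0377/day).
* `synth_landscape`: 40×40 cells at 2.5′ (~4.6 km), the simulation
  resolution of the full-extent runs, so the 5 km kernel connects rook
  neighbours exactly as there. Temperature is a smooth gradient with warm
  Gaussian bumps; the corridor variant pins a "warm" band at `T_opt` and a
  "cool" band 4 °C below (about a third of `r_max`), separated by an
  unsuitable gap. Real climate surfaces are rougher and anisotropic.
* `synth_occurrences`: cell-year draws with probability proportional to a
  known ellipsoid's suitability — the recovery tests compare the refitted
  centroid against the generator's exact suitability-weighted expectation,
  not against the unconstrained Gaussian truth, since the landscape's
  environmental support truncates the ellipsoid.

Problem sizes throughout (40×40 grids, 150-record occurrence sets, 20-seed
recovery experiments, 3000-day horizons) are the package's chosen desk
scale: large enough for front propagation, corridor ranking and partial-ROC
behaviour to be diagnostic, small enough that the full suite runs in well
under a minute per module.

## 7. Known limitations

* No Allee effects (defensible for sib-mating ambrosia beetles, wrong for
  many other taxa), no stochastic demography, no long-distance human-aided
  jumps, no time-varying climate.
* The demographic quotients are ratio estimators on accumulated means;
  no uncertainty is propagated from the cohort to the curve fit beyond the
  regression's residual variance.
* The correlative step is a single documented selection pass (thin →
  filter → fit → threshold), not a stochastic model-selection sweep over
  variable subsets.
* Grid I/O is plain-text ASCII grid: adequate for desk-scale work and
  interchange, not a substitute for a full geospatial stack (no
  reprojection, no compression, square cells only).
* At national extents (~63,000 cells) the dense trajectory matrix and the
  O(n·neighbourhood) matrix assembly remain tractable, but the fixed-step
  integrator's cost grows linearly in `t_end/dt`; the adaptive path is
  preferable near carrying capacity.
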