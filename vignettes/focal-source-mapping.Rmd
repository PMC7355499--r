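---
title: "Uncertainty-aware mapping of focal cardiac electrical sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware mapping of focal cardiac electrical sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalmap)
```

## The problem

During atrial arrhythmias, ectopic (focal) sources fire irregular electrical
impulses that collide with the sinus-driven activation, break up, and
spiral. A mapping catheter records intracardiac electrograms (EGMs) from
which local activation times (LATs) — the instants the depolarization
wavefront passes each recording channel — are extracted. Locating the
focal sources from these LATs is complicated by several uncertainties:
LAT estimates are noisy, the conduction velocity (CV) of the tissue is
unknown and variable, and the order in which channels activate changes
from beat to beat as wavefronts collide.

`focalmap` treats activation order as a *random variable* rather than a
deterministic observation. The catheter modeled here is a five-branch,
20-electrode star ("PentaRay"-style): its 10 bipolar pairs form an inner
loop (pair indices 1, 3, 5, 7, 9) and an outer loop (11, 13, 15, 17, 19),
with `D = 5` pairs per loop.

## The model

**Multinomial activation order.** For each loop and each activation cycle,
exactly one of the `D` pairs is activated first (and one last). Over `T`
independent activations the vector of first-activation counts
`n = (n_1, ..., n_D)` is multinomial with probabilities
`p = (p_1, ..., p_D)`, `sum p_j = 1`. The unconstrained maximum-likelihood
estimate is `n_j / T`, but with noisy LATs and colliding wavefronts the
counts fluctuate; the package therefore estimates `p` from `M`
perturb-and-subsample replicates of the observed LAT matrix (Gaussian
noise of standard deviation `sigma` plus random re-selection of `T`
activations), maximizing the summed multinomial log-likelihood subject to
robust bounds.

**Empirical-likelihood bounds.** For each pair, a nonparametric
confidence interval for its activation probability is obtained by
profiling the empirical likelihood of the binary indicator sample: the
bounds are the extreme weighted means `sum_t w_t z_t` over weight vectors
satisfying `sum w_t = 1`, `w_t >= 0` and
`-2 sum_t log(T w_t) <= chisq_{1, 1-alpha}`. For binary data the inner
problem has a two-group structure; the package solves the general profile
through its Lagrange multiplier and root-finds the bounds. All-zero
(all-one) samples anchor one side at 0 (1) and solve the one-sided
equation for the other. The constrained maximum-likelihood estimate is
the KKT water-filling solution `p_j = clip(c_j / lambda, lb_j, ub_j)`
with `lambda` chosen so the probabilities sum to one.

**Hypothesis test and source counting.** Each estimated probability `p*`
is referred to the uniform level `1/D` through the statistic `z = p* D`,
treated as standard normal: the reported p-value is the upper tail
`1 - Phi(z)`. This calibration is statistically unconventional (the
statistic is not a studentized quantity), but it is implemented exactly
as described because it reproduces the worked-example tables that anchor
the package's tests; its raw values lie in `(0, 0.5]` and reported tables
round to two decimals with a floor of 0.01. A pair is *significant* at
level `alpha` (default 0.1, chosen because the worked examples treat
p-values of 0.06–0.07 as significant). The number of sources is the
maximum number of significant pairs across the four probability vectors
(first/last x inner/outer): the maximum rule is needed because two
sources whose waves enter a loop through the same pair are
distinguishable only in the last-activation probabilities.

**Most probable paths.** For source rank `r`, the path
`(FO, FI, LI, LO)` collects the `r`-th largest first-activation pair of
the outer and inner loops and the `r`-th largest last-activation pair of
the inner and outer loops, paired positionally (largest with largest,
ties to the smaller pair index). A rank-2 candidate whose probability
falls below the uniform level `1/D` is taken to share the rank-1 entry —
the behavior required to reproduce both worked-example path sets, where
two sources share the entry pairs 13-3 but are separated by their exit
pairs. Entries that are not significant are flagged but retained.

**Conduction velocity.** The four path sensors give `choose(4, 2) = 6`
sensor pairs; each yields a CV estimate as inter-sensor distance (mesh
geodesic, or Euclidean in planar mode) divided by the absolute median LAT
difference over path-matched activations. The median resists outlying
cycles; pairs whose median time difference is below `min_dt_ms` (default
0.5 ms — below the traversal time of a single electrode gap, hence
uninformative) are excluded. The CV law `N(mu, sigma_c^2)` takes `mu` and
`sigma_c` from the mean and SD of the usable values. Because a chord
between two sensors can never exceed the wave's true path length, these
estimates are biased slightly high for strongly curved (near-field)
wavefronts; the regression tests bound this bias at roughly 10%.

**Localization.** Given a path, its matched activations and a CV value,
the source location `s0` and per-activation source onsets `t_k` minimize

```
sum_k sum_e ( d(s0, s_e) / CV + t_k - x_{e,k} )^2
```

subject to `0 <= t_k < x_{FO,k}` and `d(s0, s_e) <= rho_max` (default 50
mm, the assumed maximum source-to-sensor distance). For fixed `s0` the
optimal onsets are the clipped closed form
`t_k = clip(mean_e(x_{e,k} - d_e/CV), 0, x_{FO,k} - tol)`, so the search
is over locations only. On a mesh the search is exhaustive over candidate
vertices, with distances taken from four Dijkstra fields seeded at the
path sensors (geodesic symmetry makes `d(v, s_e)` available for every
vertex at once); in planar mode a coarse grid seeds a Nelder-Mead polish
of the exact objective. Monte-Carlo replicates redraw CV from the
truncated-positive fitted law and re-subsample the matched activations;
the replicate mean (mesh mode: the vertex minimizing mean geodesic
distance to the replicate estimates) is the point estimate and the
replicate spread its uncertainty. Repeating over multiple catheter
placements and pooling the estimates yields the final region
(`aggregate_placements()`, `run_pipeline()`).

## The synthetic-data generator

No recordings ship with the package; `simulate_lat_matrix()` generates
LAT tables with the statistical structure the method assumes:

* focal sources firing irregularly — inter-onset intervals are normal
  with coefficient of variation `jitter`, rejected below a refractory
  bound, and schedules start one interval into the recording (a
  recording's time origin is arbitrary and must not coincide with a
  firing instant);
* eikonal arrivals — `onset + distance / CV*` with `CV*` drawn once per
  activation cycle from a truncated-positive normal law;
* wavefront collision — with overlapping firing, each sensor records the
  earliest arrival over sources (the dominance property is asserted in
  the tests); with exclusive firing (default) each cycle belongs to one
  source, emulating interleaved ectopic and sinus beats;
* Gaussian LAT observation noise of standard deviation `lat_sd`.

A toy EGM layer (`synthesize_egm()`, `segment_activations()`,
`extract_lat()`) places biphasic derivative-of-Gaussian pulses (width 2
ms, a realistic atrial deflection scale) at the LATs so that
maximum-change LAT extraction can be exercised end to end; it makes no
attempt at fractionated morphology, ionic kinetics, or tissue
heterogeneity. Consequently, passing tests demonstrate the statistical
machinery under the model's own assumptions — Gaussian LAT error, a
single global CV per wave, smooth arrival fields — not performance on
fractionated clinical electrograms.

## Defaults and their reasons

| parameter | default | why |
|---|---|---|
| `alpha` | 0.1 | the worked examples treat p = 0.06–0.07 as significant |
| `resamples` (M) | 100 | the reference resampling protocol |
| `trials` (T) | 30 | activations per resample in the reference protocol |
| `sigma` | 1 ms | LAT noise scale; the source experiments do not state it |
| `cv_mean` | 0.8 mm/ms | typical healthy atrial conduction velocity |
| `cv_sd` | 0.04 mm/ms | 5% relative CV variability |
| inner/outer radius | 5 / 15 mm | plausible star-catheter loop radii (not claimed faithful; configurable) |
| `electrode_gap` | 2 mm | typical bipolar spacing; midpoints land exactly on the loop radii |
| `rho_max` | 50 mm | atrial-scale bound on source-to-sensor distance |
| `min_dt_ms` | 0.5 ms | below one electrode-gap traversal time; excludes uninformative sensor pairs |

## Numerical choices

* Geodesics are edge-graph Dijkstra distances, not exact polyhedral
  geodesics: deterministic, oracle-checkable, and accurate to the mesh
  discretization factor (bounded in the tests at < 1.09 on a unit grid),
  which is adequate at the method's noise level. In planar mode geodesic
  distance is Euclidean distance in the catheter plane, enabling
  closed-form test oracles.
* Ties (simultaneous arrivals, equidistant vertices, equal probabilities)
  always break toward the smallest index, making every stage
  deterministic.
* The EL profile is solved by nested root-finding with tolerance 1e-12;
  degenerate all-zero/all-one indicator samples use the one-sided
  boundary equations.
* The water-filling `lambda` is found by monotone root-finding and then
  made exact on the identified active set, so probabilities sum to 1 to
  1e-12.
* Master seeds derive per-stage child seeds through a counter scheme, so
  pipeline runs are bit-reproducible and single stages can be re-run in
  isolation.
* Problem sizes used by the test suite: 16 catheter placements, 35
  activations per source, M = 100 resamples, 100 Monte-Carlo replicates,
  2 000 coverage simulations, icospheres of 42–162 vertices. These sizes
  make the full suite run in a few minutes while leaving the Monte-Carlo
  error well below the tolerances being asserted.

## Design points that were genuinely open

* The likelihood in the constrained estimate is *maximized* (the printed
  closed form `n/T` only follows from maximization), and the chi-squared
  calibration of the EL constraint uses 1 degree of freedom at level
  `1 - alpha`.
* The EL bounds are profiled per pair (each pair's own weight vector)
  rather than through one coupled constraint across all pairs, because
  the per-pair profile is what the box constraints of the MLE consume.
* Counts are aggregated (summed) across the M resamples before the MLE;
  summing counts is algebraically identical to summing replicate
  log-likelihoods and much cheaper.
* Whether the M resamples perturb LATs, re-select activations, or both is
  ambiguous; both are implemented and on by default.
* The reuse rule for rank-2 path entries uses the uniform level `1/D` as
  its threshold. Significance alone cannot be the criterion: one
  worked-example path keeps a non-significant exit pair (p = 0.16) while
  another discards non-significant entry pairs; the `1/D` threshold is
  the simplest deterministic rule consistent with both.
* `CV*` is drawn once per Monte-Carlo replicate (one wave, one velocity),
  and the regression residual absorbs the observation-noise term of the
  arrival model.

## Known limitations

* **Far-field range identifiability.** With a 30 mm catheter aperture,
  the least-squares objective's range curvature scales as `r^2 / 2L`
  (~3 mm at `L` = 40 mm), so at realistic LAT noise the objective is
  nearly flat in range beyond ~25 mm and per-placement estimates of a far
  source drift toward the catheter. Pooling placements that surround the
  region mitigates but does not remove the bias: in the package's
  two-source recovery study the pooled centroid of the better-covered
  source lands within ~3 mm of truth while the other typically lands
  6–9 mm inward. Estimates improve sharply when the catheter is near the
  source (0.2–3 mm), which is also the regime the method is intended
  for; the accompanying tests assert the rank correlation between
  catheter-to-source distance and error.
* Positional rank pairing can scramble the two sources' entries into
  inconsistent paths when a placement sees the sources from nearly
  opposite directions with ~50/50 firing shares; such paths match few or
  no activations and are skipped with a warning (no geometric consistency
  check is applied by design).
* A single global CV per wave ignores fibrosis and fiber anisotropy;
  spatially varying CV fields are out of scope.
* The hypothesis test's normal calibration is inherited as-is (see
  above); its p-values order probabilities monotonically, which is what
  source counting and path ranking actually require.
* Rotor and re-entry drivers are not modeled or detected; the scope is
  focal sources.

## A worked session

```{r example, eval = FALSE}
lay <- pentaray_layout(center = c(15, 5, 0))
sched <- activation_schedule(n_sources = 1, n_activations = 40,
                             jitter = 0.3, seed = 1)
src <- focal_source(c(40, 20, 0), sched[[1]])
lat <- simulate_lat_matrix(src, lay, cv_mean = 0.8, cv_sd = 0.04,
                           lat_sd = 0.5, seed = 2)
fit <- focalfit(lat, layout = lay, sigma = 0.5, seed = 3)
summary(fit)
plot(fit)
loc <- predict(fit, replicates = 100, seed = 4)
loc
```

The end-to-end multi-placement protocol, with artifacts written to disk,
is `run_pipeline()`; see the README for a complete run and its output.
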