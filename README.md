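# focalmap

Locating focal cardiac electrical sources from multi-electrode activation
times, with the measurement uncertainty carried through every step.

## The problem

Catheter ablation of atrial arrhythmias needs the *focal sources* —
tissue sites firing abnormal impulses — to be found from intracardiac
electrograms. The local activation times (LATs) extracted from those
signals are noisy, the tissue conduction velocity (CV) is unknown, and
colliding wavefronts scramble the activation order from beat to beat, so
any single beat can mislead. `focalmap` is for researchers in cardiac
electrophysiology and biomedical signal analysis who want a statistical
treatment of this problem: activation order is modeled as a random
variable, and localization is posed as robust optimization under CV
uncertainty.

The catheter model is a five-branch, 20-electrode star whose 10 bipolar
pairs form an inner loop (pair indices 1, 3, 5, 7, 9) and an outer loop
(11, 13, 15, 17, 19); `D = 5` pairs per loop.

## The method

For each loop, the index of the first- (and last-) activated pair over
`T` activations follows a multinomial distribution. The pipeline:

1. **Resampling** — `M` replicates of the LAT table, each perturbed with
   `N(0, σ²)` LAT noise and restricted to `T` randomly chosen
   activations.
2. **Robust bounds** — per-pair empirical-likelihood confidence bounds
   `[lb, ub]` for the activation probability: extremes of `Σ w_t z_t`
   over weights with `Σ w = 1`, `w ≥ 0`,
   `−2 Σ log(T w_t) ≤ χ²₁,₁₋α`.
3. **Constrained MLE** — maximize `Σ_j c_j log p_j` on the simplex
   intersected with the box; solution `p_j = clip(c_j/λ, lb_j, ub_j)`
   with `λ` from a monotone root-find.
4. **Hypothesis test** — `z = p*·D` against the standard normal upper
   tail; significant pairs count the sources and rank the most probable
   wave paths `(FO, FI, LI, LO)` (entry/exit pair in each loop).
5. **Conduction velocity** — the 6 sensor pairs of a path give 6 CV
   estimates (distance over absolute median LAT difference); their mean
   and SD define the CV law `N(μ, σ_c²)`.
6. **Localization** — minimize
   `Σ_k Σ_e (d(s₀, s_e)/CV + t_k − x_{e,k})²` over source location `s₀`
   and onsets `0 ≤ t_k < x_{FO,k}`, with `d(s₀, s_e) ≤ ρ`; Monte-Carlo
   over CV draws and activation subsets, then pooled over catheter
   placements. Distances are mesh geodesics (Dijkstra) or planar
   Euclidean.

A synthetic activation simulator (irregular focal firing, truncated-normal
CV, Gaussian LAT noise, earliest-arrival wave collision) and a toy
biphasic EGM trace generator round out the package; no clinical data are
included.

## Worked example

```r
library(focalmap)

lay   <- pentaray_layout(center = c(15, 5, 0))
sched <- activation_schedule(n_sources = 1, n_activations = 40,
                             jitter = 0.3, seed = 1)
src   <- focal_source(c(40, 20, 0), sched[[1]])          # true source, mm
lat   <- simulate_lat_matrix(src, lay, cv_mean = 0.8, cv_sd = 0.04,
                             lat_sd = 0.5, seed = 2)
fit   <- focalfit(lat, layout = lay, sigma = 0.5, seed = 3)
fit
#> Activation-order model fit
#>   40 activations, M = 100 resamples of T = 30 trials, sigma = 0.5 ms, alpha = 0.1
#>   inferred sources: 1
#> Most probable wave paths (FO-FI-LI-LO):
#>   source 1: 11-1-7-17
#>   path-matched activations (T*): 40

predict(fit, replicates = 100, seed = 4)
#> Source localization:
#>   path 1: Localization (100 replicates, T* = 40): point estimate (44.62, 14.77, 0.00) mm
#>   spread 7.29 mm; cv draws 0.923 +/- 0.151 mm/ms
```

Reading the output: every one of the 40 activations entered the catheter
at outer pair 11 and inner pair 1 and left through inner pair 7 and outer
pair 17, so one source is inferred with path 11-1-7-17. The pairwise CV
estimates center on 0.92 mm/ms (slightly above the generating 0.8 — the
chord between two sensors understates the wave's true path, a documented
bias), and the Monte-Carlo point estimate lands 7 mm from the true source
at (40, 20, 0) — typical single-placement accuracy for a source ~30 mm
from the catheter center, and the reason the protocol pools many
placements (`run_pipeline()` sweeps 16 poses and aggregates; see the
vignette). A source close to the catheter localizes to well under a
millimeter of this kind of noise.

The fitted object supports `summary()`, `coef()`, `plot()` (probability
barplots with bounds), `residuals()` and `simulate()`.

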