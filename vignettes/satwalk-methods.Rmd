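---
title: "Self-attracting walks for cell migration: models, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-attracting walks for cell migration: models, inference and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satwalk)
```

`satwalk` models single-cell migration as a random walk that interacts with
the territory it has already explored. This vignette is the package's own
account of the science: the models and their assumptions, the tunable
parameters and why their defaults are what they are, what the synthetic
track generator does and does not emulate, the numerical choices, and the
known limitations.

## The physical picture

Cells migrating on adhesive micropatterned lines (width ~20 um) or on flat
substrates leave behind long-lived deposits — extracellular-matrix
components such as fibronectin and laminin — and respond to them when they
return. The package works with the kinematic proxy for any such deposit:
the *footprint field* `phi(x, t)`, the cumulative time the cell body has
covered position `x` up to time `t`. A cell wholly inside its footprint
reads a flat field at its two ends (`phi_l ~ phi_r`) and shows no net
acceleration; a cell poking beyond the frontier reads a strong asymmetry
(`phi_r ~ 0`, `phi_l` large at the right frontier) and, on average,
accelerates back inward. `compute_footprint_field()`,
`sample_edge_footprints()` and `acceleration_heatmap()` implement this
analysis for 1D tracks.

## The lattice models

The **persistent self-attracting walk (PSATW)** lives on the 1D integer
lattice. Site `i` carries a visit count `n_i`; the memory function is the
saturating step `f(0) = 0, f(n > 0) = 1` (the deposit is bounded: once
marked, a site is marked). Two parameters govern the dynamics:

* `k >= 0`, the persistence parameter. Inside the visited domain the walker
  reverses with probability `p_ri = e^-k / (e^-k + e^k)`, giving a
  persistence length (and time, at unit speed) `l_p = t_p = e^(2k)`.
* `beta`, the footprint coupling. When the site ahead is unvisited the
  reversal probability becomes `p_re = e^(-k-beta) / (e^(-k-beta) + e^k)`:
  for `beta < 0` the walker preferentially turns back into its own
  territory. `beta = 0` removes the frontier entirely and the PSATW reduces
  to the classical persistent random walk (the memoryless `k = 0` case is
  the simple random walk).

The **2D SATW** drops persistence (on flat substrates the measured
persistence length is comparable to the cell size): each step is drawn over
the 4 neighbours with weights `exp(-beta f(n_j))`.

Model-level consequences, all computable with `increments()`, `msd()`,
`survival_probability()` and `fit_power_exponent()`:

* **Ageing.** Increment curves `I(T, t) = <[x(T + t) - x(T)]^2>` depend on
  the age `T` whenever `beta < 0`, because the slowly growing visited
  domain keeps reshaping the dynamics. At `beta = 0` they are
  age-independent.
* **Aged ballistic regime (1D).** For `T >> t_p` and lags `t << t_p` the
  walk is ballistic inside its domain, `I ~ t^2`; at young ages and long
  lags, frontier interactions produce near-diffusive growth.
* **Subdiffusion (2D).** The strongly attractive SATW grows a compact
  visited cluster; asymptotically `I(0, t) ~ t^(2/3)`.
* **First passage.** The survival probability of a target at distance `r`
  decays as `S(t) ~ t^-theta` with `theta = e^-beta / 2`
  (`theta_theory()`): 1/2 for any memoryless walk, larger under
  self-attraction — memory favours local, thorough exploration.

### Initial condition and edge rule

The model definition leaves the first step open; the package starts the
walker at the origin, counted as visited once, with a uniformly random
initial direction. The first step therefore necessarily applies the edge
rule, symmetrically. A step is an *edge* step exactly when the site ahead
in the current direction is unvisited; visit counts are incremented on
arrival, before the next step is classified. Under these dynamics a walker
can never stand on an interior site while facing an unvisited one without
that site being the frontier, so no further case analysis is needed.

### Seeding

Every ensemble derives one independent RNG stream per walker from the
master seed (`derive_seeds()`: the master seed seeds R's generator, which
draws one 31-bit sub-seed per walker). Identical `(params, n_steps, seed)`
give bit-identical trajectories, and any single trajectory can be
regenerated without re-running the ensemble. The Monte-Carlo cores are
compiled (Rcpp) but consume R's own RNG stream, so R-level seeding governs
everything.

## Discretisation and per-cell inference

Experimental 1D tracks are continuous; the model is a lattice. The bridge
(`discretise()`) maps the centroid onto sites `X = floor(x / L_ref + 1/2)`
with `L_ref` the cell-specific reference length — by default the median
instantaneous cell length over the track (`choose_Lref()`), ~20 um on
micropatterned lines. Hop times are interpolated linearly at site-boundary
crossings, and a frame-to-frame change of several sites is split into unit
hops with interpolated times (the model's state machine requires unit
hops; a strict rejection of such frames would discard otherwise good
tracks).

Each hop after the first is classified interior or edge from the discrete
path's *own* visit history, starting at its first site — what an experiment
beginning at plating can observe. The conditional reversal frequencies then
invert algebraically (`invert_params()`):

    k = log((1 - p_ri) / p_ri) / 2,   beta = log((1 - p_re) / p_re) - 2 k.

Degenerate frequencies (0 or 1 on short tracks) get an Agresti-style +1/2
pseudocount and are flagged rather than dropped.

### Debouncing

Real tracks carry positional noise (~1 um). Plain grid rounding turns
noise into spurious hop pairs whenever the centroid hovers near a site
boundary — about 8% extra hops at 1 um noise and `L_ref = 20` um — which
inflates the apparent reversal frequency and biases `k` low, with a bias
that does not average away on longer tracks. `discretise()` therefore
offers a hysteresis margin (`hysteresis_um`): a hop registers only once the
centroid passes the boundary by the margin, the classic two-threshold
debouncing rule. The margin defaults to 0 (the pure grid rule, under which
a noiseless rendering of a lattice path discretises back to it exactly);
the inference pipeline `fit_cells()` uses 2 um, twice the default noise
scale. Hop *times* are still interpolated at the plain boundary crossing.

At the study scale — 100 cells, 150 hops per track, the typical length of
a discretised experimental track — the pipeline recovers `k` with a median
absolute error of ~0.08 and `beta` with ~0.28 under the control preset.
The `beta` figure is the information limit of frequency inversion at that
track length: a 150-hop oscillatory track contains only ~33 edge events,
giving a per-cell standard error of ~0.45 on `beta_hat`; both medians
shrink substantially at 1500 hops.

## The synthetic track generator

No public single-cell track data accompany this problem, so
`generate_dataset()` produces continuous tracks with the statistical
structure the pipeline assumes, plus the ground truth to score against.
Per cell, `(k, beta)` are drawn from truncated normals
(`sample_population()`); a PSATW path is simulated and *dressed* into a
continuous track (`render_continuous_track()`): sites map to positions
`X * L_ref`, each hop gets a duration from a bi-exponential mixture, the
centroid is interpolated linearly and resampled on a regular frame grid,
cell edges are attached, and positional noise is added. Dressing
randomness is seeded separately from the lattice path, so one path can be
re-dressed.

Defaults, chosen once from the scales the experimental system dictates:

| parameter | default | rationale |
|---|---|---|
| `k_mean`, `k_sd` | 0.7, 0.2 | run length `e^1.4 ~ 4` sites (~80 um), oscillations of a few cell lengths |
| `beta_mean`, `beta_sd` (control) | -2, 0.5 | strong frontier reversal (`p_re ~ 0.65`), slowly spreading sawtooth |
| `beta_mean`, `beta_sd` (conditioned) | 0, 0.1 | pre-conditioned substrate: no frontier to sense, same intrinsic `k` |
| `L_ref_um`, `cell_length_um` | 20 | micropattern track width / compact cell length |
| jump mixture | 0.7/0.3 of means 0.3/1.3 h | bi-exponential, overall mean exactly 0.6 h |
| `spread_length_um` | 80 | transient spreading up to ~100 um total during reversals |
| `frame_dt_h` | 0.1 | 6-min time-lapse interval |
| `noise_sd_um` | 1 | sub-micron to micron tracking error |

Two renderer details exist to keep the generator honest as a test
instrument rather than to beautify it. First, hop durations are drawn as
`frame_dt` plus an exponential with correspondingly reduced mean, so no
hop is shorter than one frame while the mixture mean stays exactly 0.6 h:
a sub-frame round trip would be invisible to any frame-sampled track, and
the zero-noise render/discretise round trip is meant to be exact, not
approximate. Second, the frame grid runs to the next frame multiple past
the final hop so the terminal arrival is always sampled. Spreading
episodes are triangular elongation bumps of at most 0.3 h centred on
reversal hops — transient by construction, so the compact ~20 um state
remains the median state that `choose_Lref()` picks up.

What the generator does *not* emulate: image-level artefacts (segmentation
jitter beyond Gaussian noise, missed frames), cell divisions and
collisions, drift of the micropattern, any correlation between speed and
cell length, and 2D experimental tracks (2D output is lattice-scale only).
Passing tests therefore show that the pipeline is correct and well
calibrated on tracks with the stated statistical structure — not that real
microscopy data meet that structure.

## Numerical choices

* **Footprint grid.** Bin width 2 um by default (well below the cell
  length); occupancy is deposited by fractional bin overlap, making the
  conservation identity `sum(phi) dx = integral of cell length dt` exact to
  rounding. The grid is anchored at the track midpoint, so translating a
  track translates the grid with it and mirroring a track mirrors the
  field exactly.
* **Edge sampling is causal.** `phi_l, phi_r` at frame `n` use the field
  accumulated strictly before `n`; the occupancy a frame deposits cannot
  influence its own acceleration reading.
* **Acceleration.** Three-point central difference on a moving-average
  smoothed centroid (window 3 frames), exact for quadratics, valid on
  irregular time grids; endpoints are NA.
* **Exponent fits.** Log-log least squares over an explicit window,
  refusing windows with non-positive values and fewer than 5 points, with
  R^2 as a mismatch diagnostic. Survival-tail fits use the window where
  `S` lies in `[1e-3, 1e-1]`, and their Monte-Carlo standard error comes
  from bootstrap over walkers.
* **First-passage geometry.** A single absorbing site at `+r` on the
  infinite line, walker started at the origin with uniform initial
  direction; walkers not arrived by `t_max` are censored.
* **Oscillation detection.** Turning points from a hysteresis rule on the
  smoothed centroid (minimum excursion 10 um, half a run length), so noise
  does not spawn reversals; the amplitude is the excursion between
  consecutive turning points and the period the time between successive
  same-sign reversals, which makes amplitude/period = speed/2 for an ideal
  bouncing runner.
* **Ageing windows.** Increment curves average the start time over a
  sliding window (12 h in experimental units) and report lags up to a
  third of the window by default, so every lag is averaged over the full
  window; both are configurable for simulation work, where ensembles of
  2000 walkers x ~1e4 steps resolve the aged ballistic exponent to ~0.005.

## Problem sizes

The test-suite and acceptance computations run at deliberately desk-sized
scales, chosen so each printed law is resolved without heroic ensembles:
1e4 walkers for survival exponents (t_max 1e5 for the memoryless case, 1e4
for the attractive cases), 500-2000 walkers and ~1e4 steps for increment
scaling, 100 cells x 150 hops (the experimental track length) for
parameter recovery, and exhaustive enumeration of all 12-step paths as the
simulator's exact oracle.

## Known limitations

* The memory function is fixed to the saturating step; graded or decaying
  deposits are out of scope, as are interacting multi-walker systems.
* The 2D subdiffusive exponent 2/3 is an asymptotic statement: at 1e4
  steps and `beta = -2.5` the measured local exponent is still ~0.55 and
  creeps upward with lag; the package reports what the finite ensemble
  shows.
* `beta` inference from 100-150-hop tracks is information-limited (~0.3
  median error under the control preset); treat per-cell `beta_hat`
  scatter at that length as population-level evidence, not single-cell
  measurements.
* The MSD convention is squared displacement; `msd(squared = FALSE)`
  provides the unsquared norm where that convention is preferred.
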