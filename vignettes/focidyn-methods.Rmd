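---
title: "focidyn: models, parameters, and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{focidyn: models, parameters, and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented by `focidyn`, the default
parameter values with units and rationale, the numerical choices made, and
the known limits of the synthetic data generator. It is a methods reference,
not a tutorial; see the README for a worked example.

## 1. The confined-diffusion model

Focus mobility is summarised by the time-averaged mean-square displacement
(MSD), pooled over all non-event tracks:

$$\mathrm{MSD}(\Delta t) \;=\; r_c^2\left(1 - \exp\!\left(
  -\frac{2\,d\,D_c\,\Delta t}{r_c^2}\right)\right)$$

where $d = 2$ (analysis is in the image plane), $D_c$ is the confined
diffusion coefficient in µm²/min, and $r_c$ is the confinement radius in µm.
At short lags the curve rises like free diffusion, $2 d D_c \Delta t$; at
long lags it saturates at the plateau $r_c^2$.

### Computation of the MSD

`compute_msd()` uses **all ordered frame pairs** within each track (not just
consecutive ones), averaging squared displacements per lag across tracks.
Gapped tracks contribute only the pairs whose frames both exist. The default
maximum lag is one third of the longest track span: beyond that, the number
of independent pairs per lag is too small for a stable estimate, and the
per-lag estimates become strongly correlated.

### Fitting

`fit_confined()` fits the model with Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`), by default weighted by the number of displacement
pairs per lag (`weighted = TRUE`), so well-sampled short lags dominate.
Starting values are derived from the curve itself: $r_c^2$ from the mean of
the last quartile of lags (the empirical plateau) and $D_c$ from the
first-lag slope $\mathrm{MSD}(\Delta t_1)/(2 d \Delta t_1)$.

Two diagnostic flags indicate when a coefficient is poorly identified rather
than erroring out:

* `warn_rc`: the curve has not reached saturation by the last lag
  (the fitted exponent at the last lag is below 1), so $r_c$ is an
  extrapolation.
* `warn_Dc`: the first lag is already deep into the plateau (fitted
  exponent at the first lag above 3, or the first MSD value is at
  ≥ 90 % of the fitted plateau), so the initial slope — and hence
  $D_c$ — is not resolved at this frame interval.

The return value is a classic S3 fitted-model object (`confined_fit`) with
`print`, `summary`, `coef`, `fitted`, `residuals`, `predict`, `plot`, and
`simulate` methods; `simulate()` draws trajectories from the matching
Ornstein–Uhlenbeck process (below).

### Trajectory simulation

`simulate_confined_tracks()` generates trajectories from a stationary
two-dimensional Ornstein–Uhlenbeck (OU) process with per-dimension
standard deviation $\sigma = r_c/2$ and relaxation time
$\tau = r_c^2/(2 d D_c)$, updated as
$x_{t+1} = \alpha x_t + \sqrt{1-\alpha^2}\,\sigma\,\varepsilon$,
$\alpha = e^{-\Delta t/\tau}$. This process reproduces the confined-MSD
formula above *exactly* in expectation at every lag, which makes it a clean
oracle for the fitting code: ensemble MSDs of simulated tracks converge to
the model curve, and fits recover the generating $(D_c, r_c)$. $D_c = 0$
yields frozen trajectories. Note this is a harmonic (Gaussian) confinement,
not reflection inside a hard sphere; the two differ in the shape of the
approach to the plateau but share the same two summary parameters.

## 2. Synthetic nucleus generator

`simulate_nucleus(sim_config(...))` produces a time-lapse stack and full
ground truth. Default parameters:

| parameter | default | units | rationale |
|---|---|---|---|
| `image_size` | 128 | px | keeps a full nucleus in frame at speed |
| `pixel_size` | 0.16 | µm/px | typical 63×/1.4 NA confocal sampling |
| `frame_interval` | 1 | min | one frame per minute protocol |
| `n_frames` | 75 | – | 75 min observation window |
| `nucleus_radius` | 7.5 | µm | U2OS-like nucleus |
| `spot_sigma` | 0.35 | µm | near-diffraction-limited focus PSF |
| `spot_amplitude` | 180 | AU | well above background, below clip |
| `amplitude_sdlog` | 0.2 | – | lognormal focus-to-focus brightness spread |
| `background_nuclear` | 45 | AU | nucleoplasmic GFP signal |
| `background_outside` | 5 | AU | camera offset outside the cell |
| `read_noise_sd` | 2 | AU | Gaussian read noise (plus Poisson shot noise) |
| `nucleus_drift` | (0.15, −0.1, 0.08) | px, px, °/frame | slow rigid stage/cell drift |
| `bleach_slope` | (139.3−104.6)/75 | AU/min | linear fading: 25 % intensity loss over 75 min |
| `min_separation` | 1.8 | µm | dart-throwing seed separation (see limits) |
| `focus_lifetime_mean` | 40 | min | exponential focus lifetime |
| `merge_rate`, `split_rate` | condition-dependent | /focus/frame | rare interaction events |

Per-condition mobility and kinetics defaults (`condition_defaults()`):

| condition | `Dc_true` (µm²/min) | `rc_true` (µm) | FPC anchors (initial → peak @ min → final) |
|---|---|---|---|
| control | 0.008 | 0.55 | 1.5 flat |
| alpha   | 0.012 | 0.65 | 6.4 → 8.1 @ 11 → 6.9 |
| xray    | 0.005 | 0.45 | 9.7 → 15.3 @ 16 → 8.7 |
| mixed   | 0.003 | 0.35 | 7.6 → 10.3 @ 9 → 9.1 |

Foci-per-cell kinetics are realised as a birth–death process whose expected
count follows a piecewise-cubic-Hermite interpolation of the anchors: the
death rate is $\mu = 1/\text{lifetime}$ and the birth rate is
$b(t) = \max(0, m'(t) + \mu\, m(t))$ where $m(t)$ is the anchor profile —
the unique non-negative birth rate giving $\mathbb{E}[N(t)] = m(t)$.

### Generator realism limits

* **Harmonic confinement**, not reflected Brownian motion (see Section 1).
* **Dart-throwing seeding** with `min_separation = 1.8` µm avoids unresolvable
  overlaps at birth, which makes detection counts clean; real clustered
  damage can seed closer pairs.
* **Split geometry**: children of a split are placed adjacent (0.2 µm) but
  anchored `split_offset = 0.7` µm apart on either side of the parent, so
  they separate over subsequent frames; real splits need not be symmetric.
* **Rigid drift only** — no elastic nuclear deformation, no focal-plane
  drift, no z-motion (the generator and analysis are strictly 2-D).
* **Linear bleaching** applied multiplicatively to the whole frame; real
  photobleaching is closer to (multi-)exponential.
* Intensities are clipped to the 16-bit range on rendering; foci leaving the
  field of view are flagged `clipped` in the ground truth.

## 3. Registration

`estimate_rigid()` aligns every frame to a reference (default frame 1) with
a rigid transform $(d_x, d_y, \theta)$ mapping reference coordinates $p$ to
frame coordinates $R(\theta)(p - c) + c + d$ about the image centre $c$.

Numerical choices:

* Frames are Gaussian-smoothed (`smooth_sigma = 1.5` px), downscaled by
  `scale_factor = 2`, and z-scored before matching, which suppresses noise
  and bleaching trends.
* A running template is propagated from the reference frame so each frame is
  matched against its registered predecessor (small increments), with the
  accumulated transform composed analytically.
* The local optimiser is Nelder–Mead on the warp MSE (`reltol = 1e-5`,
  `maxit = 60`), initialised from an FFT cross-correlation shift; when the
  match confidence (1 − MSE/template variance) falls below
  `confidence_threshold`, a coarse rotation grid search
  (`theta_grid = −6…6°`) plus FFT shift is used as a fallback, and the frame
  is flagged `low_confidence`.
* A smoothness prior on $\theta$ (`theta_penalty = 0.02` per squared degree
  of frame-to-frame change) stabilises the rotation estimate on sparse,
  noisy scenes. **Identifiability limit**: a nucleus with a handful of
  nearly round foci constrains rotation weakly; over long stacks the
  accumulated $\theta$ can wander by a degree or more even when
  translations are sub-pixel, and the prior trades a small bias on genuine
  single-frame rotation jumps for that stability. For a *single known pair*
  with a large rotation step, disable the prior (`theta_penalty = 0`) and
  match at full resolution (`scale_factor = 1`) to recover the transform to
  hundredths of a pixel/degree.

`apply_rigid()` resamples with bilinear interpolation; registration is
therefore not exactly invertible at the pixel level (interior mean absolute
round-trip error is of order 1 AU).

## 4. Segmentation

* Nucleus ROI: Gaussian blur (`sigma = 2` px) of the temporal mean image,
  Otsu threshold, largest connected component, hole filling.
* Focus threshold per frame: sigma-clipped nuclear background mean plus
  `max(k · SD, min_prominence)` with `k = 3` and `min_prominence = 15` AU.
  The SD term adapts to noise; the prominence floor rejects background
  texture when noise is very low. Because the threshold is relative to the
  per-frame nuclear mean, it tracks photobleaching automatically.
* Touching foci are split by intensity watershed (`watershed_tol = 10` AU),
  chosen to split clearly bimodal blobs without shattering single foci.
* Area filter `0.3–10` µm²: the lower bound removes hot pixels (a single
  pixel is 0.0256 µm²), the upper removes segmentation failures merging
  many foci; filtering is by physical area, so results are resolution
  independent.

## 5. Tracking and events

* Linking is greedy **mutually nearest neighbour** within
  `linking_radius = 1.0` µm (several times the expected per-frame
  displacement $\sqrt{2 d D_c \Delta t} \approx 0.18$ µm for control), with
  gap closing across up to `max_gap = 2` missing frames.
* Merge/split classification follows label overlap between consecutive
  frames: a detection whose footprint overlaps ≥ `overlap_fraction = 0.3`
  of two or more previous tracks is a merge; the time-reversed pattern is a
  split; a merge later followed by a split of the same fused focus is
  classified `merging_and_splitting`. Fused states lasting a single frame
  (`min_fused = 2`) are ignored as sub-resolution passes, which also makes
  the classification symmetric under time reversal.
* Tracks participating in events are marked excluded (with a reason) and
  skipped by `compute_msd()` unless `use_excluded = TRUE`, since
  merge/split displacements are not diffusive motion.

## 6. Kinetics and statistics

* `build_kinetics()` averages per-nucleus FPC series and smooths with
  `stats::loess` (`span = 0.4`). This span suppresses birth–death counting
  noise at 25 nuclei but displaces very sharp peaks by a few minutes; the
  unsmoothed mean and SEM are retained alongside.
* `summarize_kinetics()` reports initial/highest/final FPC, the peak time,
  *max increase* (highest minus control at the same time) and
  *max reduction* (highest divided by final).
* `expected_mixed()` forms the additive expectation of two single-beam
  kinetics tables on a common time grid.
* `fit_control_fading()` is ordinary least squares of intensity on time;
  `percent_loss` is the fitted relative loss across the window.
* `coefficient_of_variation()` uses the sample SD (n−1) over the
  minute-1–75 window by default (minute 0 is pre-equilibrium); the CV is
  scale invariant by construction.
* `kde_intensity()` wraps `stats::density` with a Gaussian kernel and
  Silverman's rule-of-thumb bandwidth by default; the returned curve
  integrates to 1 (trapezoidal check stored as an attribute). Note that
  `stats::density` bins observations onto a grid before convolving, so
  pointwise values agree with the exact kernel sum only to about a percent
  for tiny samples.
* `compare_conditions()` is one-way ANOVA (`stats::oneway.test` with equal
  variances, i.e. classic F); `compare_counts()` is a chi-squared test on
  event-count tables.

## 7. Limitations

* Strictly 2-D: out-of-focus motion appears as intensity fluctuation and
  possible missed detections, not as displacement.
* The confined-diffusion fit assumes a single homogeneous population; a
  mixture of mobilities yields averaged, fit-dependent parameters.
* Event classification requires the fused focus to be segmented as one
  object; partial-overlap configurations below the watershed tolerance are
  reported as plain track terminations.
* Registration assumes rigid nuclear motion; deforming nuclei leave
  residual apparent motion that inflates $D_c$.
* The generator's parameter defaults describe one imaging configuration;
  analysing data from other optics requires setting `pixel_size`,
  `frame_interval`, and the detection parameters accordingly.
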