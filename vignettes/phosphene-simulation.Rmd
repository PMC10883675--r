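---
title: "Simulating cortical prosthetic vision with phosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cortical prosthetic vision with phosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosim)
```

## The problem

A cortical visual prosthesis electrically stimulates primary visual cortex
(V1) through an array of microelectrodes. Each supra-threshold stimulus
elicits a *phosphene*: a localized flash of light at a visual-field position
determined by the electrode's place in the retinotopic map. Research on
stimulation strategies leans heavily on *simulated prosthetic vision* (SPV):
rendering, for sighted observers or for computational models, the percept a
given stimulation pattern would plausibly produce. phosim implements a
biologically grounded SPV engine: a stateful, frame-based simulator that
maps per-electrode stimulation parameters — amplitude $I_{stim}$ (µA),
pulse width $P_w$ (µs), frequency $f$ (Hz) — onto rendered brightness
images, with every stage expressed through smooth, simple functions so that
derivatives of the rendered image with respect to the stimulation inputs
are well defined (the property that makes end-to-end optimization of
stimulation encoders possible).

## The model

### Visuotopic mapping and cortical magnification

Visual-field positions are polar coordinates $z = r e^{i\theta}$
(eccentricity $r$ in degrees; azimuth $\theta$ in radians,
$-\pi/2 \le \theta \le \pi/2$ within a hemifield, $\theta = 0$ on the
horizontal meridian, positive upward). A wedge-dipole map relates them to
positions $w$ (mm) on a flattened V1:

$$w = k\left[\log(z' + a) - \log(z' + b) - \log(a/b)\right],
  \qquad z' = r e^{i\alpha\theta},$$

with shear $\alpha$, scale $k$ (mm) and dipole singularities $a < b$
(deg). We implement the *normalized* form (the $-\log(a/b)$ term), which
pins the fovea to the cortical origin; without it the printed forward and
inverse expressions are not mutual inverses, and the constant does not
affect any derived quantity. The inverse is

$$z = \Lambda^{-1}\!\left(\frac{ab\,(e^{w/k} - 1)}{b - a e^{w/k}}\right),
  \qquad \Lambda^{-1}(r e^{i\theta}) = r e^{i\theta/\alpha},$$

with a singularity at $e^{w/k} = b/a$; positions within $10^{-9}$ of it are
rejected rather than clamped, as are electrodes whose image falls outside
the hemifield. Cortical magnification, the map derivative along the
horizontal meridian, is

$$M(r) = \frac{k(b - a)}{(r + a)(r + b)} \quad \text{mm/deg},$$

largest at the fovea and strictly decreasing. Defaults $a = 0.75$,
$b = 120$, $k = 17.3$, $\alpha = 0.95$ are the published fit to human V1.
One configuration describes one hemisphere; a right-hemisphere map renders
phosphenes in the left hemifield (screen $x \le 0$) and vice versa.
Alternative retinotopies (mono-/dipole variants, LGN, V2–V4) are not
implemented; the mapping functions are the natural substitution point.

### Phosphene size

Stimulation current spreads in cortex with threshold growing as the square
of distance, so current $I$ (µA) with excitability constant
$K = 675$ µA mm⁻² activates a disc of diameter $D = 2\sqrt{I/K}$ mm,
which subtends $P = D / M(r)$ degrees. (The source texts typeset these
relations without the radical and quotient; $D = 2\sqrt{I/K}$, $P = D/M$
is the only dimensionally consistent reading of the underlying
current-spread model, and is what we implement.) Size uses the
*instantaneous* current only — never the stimulation history — and is
independent of pulse width and frequency.

### Tissue activation, thresholds, brightness

Per electrode and per frame of duration $\Delta t$:

1. **Effective current.** The rheobase $I_0$ (ineffective input component)
   and the memory trace $B$ (reduced excitability after prior stimulation)
   are subtracted, the result rectified and scaled by the duty cycle:
   $$I_{eff} = \max(0,\, I_{stim} - I_0 - B)\cdot P_w f.$$
   Any amplitude at or below $I_0 + B$ is completely ineffective; this is
   what makes a 20 µA train (default $I_0 = 23.9$ µA) produce *exactly*
   nothing.
2. **Leaky integration.** Activation follows an explicit-Euler step of a
   first-order integrator,
   $$A_t = A_{t-\Delta t} + \left(-\tfrac{A_{t-\Delta t}}{\tau_{act}} +
   I_{eff}\, d\right)\Delta t,$$
   with $\tau_{act} = 0.111$ s and duration scale $d \in (0,1]$
   (default 1: train duration is controlled by the number of consecutive
   stimulated frames).
3. **Detection threshold.** Each electrode's threshold $A_{thr}$ is drawn
   once, at session initialization, from $\mathcal N(\theta_{50},
   \sigma^2)$ with $\theta_{50} = 9.14\times10^{-8}$,
   $\sigma = 6.72\times10^{-8}$, and is held fixed thereafter
   (`sim_reset_thresholds()` re-draws it explicitly).
4. **Brightness.** Above threshold, brightness is the sigmoid
   $1/(1 + e^{-\lambda(A - A_{50})})$ with $\lambda = 19.2\times10^7$ and
   $A_{50} = 1.06\times10^{-6}$; below threshold it is zero.
5. **Memory trace.** $B$ integrates past effective current with a slow
   decay, $$B_t = B_{t-\Delta t} + \left(-\tfrac{B_{t-\Delta t}}
   {\tau_{trace}} + I_{eff}\,\kappa\right)\Delta t,$$
   $\tau_{trace} = 1.97\times10^3$ s, $\kappa = 14$. Because $B$ is
   subtracted inside the effective current, repeated identical trains
   produce declining peak activation — brightness accommodation
   (habituation) — with slow recovery over hundreds of seconds. The trace
   affects brightness only, never size.

### Units

Currents are stored internally in amperes, pulse widths in seconds; the
configuration file and all user-facing arguments take µA and µs because
every published value is quoted in those units. The activation variable $A$
inherits the ampere scale of $I_{eff}$; the fitted magnitudes of
$\theta_{50}$ and $A_{50}$ are only coherent with the update equations
under that convention (the sources never state the unit of $A$
explicitly). A related caveat: with the published constants, the
activation reached by the amplitude range of the published
single-electrode brightness experiment (≤ 120 µA over a 166 ms train)
stays more than an order of magnitude below $A_{50}$, so absolute
brightness values cannot be validated against that figure. Our tests
therefore pin down *structural* properties — rectification at the
rheobase, monotonicity in amplitude/pulse width/frequency, the exact
sigmoid midpoint, decay constants — rather than absolute brightness at
given amplitudes.

### Rendering

Phosphenes are rendered as isotropic Gaussian blobs centered at their
visual-field position, with **two standard deviations equal to the
phosphene size** ($\sigma = P/2$), so ~95% of the 1-D profile mass falls
within the nominal size. Blobs are *peak-normalized* (maximum pixel value
equals the brightness) rather than mass-normalized: brightness lives in
$[0,1]$ and mass normalization would render small foveal phosphenes
invisibly dim. Contributions are summed across electrodes (the default
model treats electrodes as independent) and clipped to $[0,1]$ unless
`clip_mode = "none"` — clipping is a pragmatic ceiling; the perceptual
summation of overlapping phosphenes is genuinely unknown, and gradient
work should use the unclipped mode. A Gabor variant multiplies the same
envelope with a $0.5 + 0.5\cos(\cdot)$ carrier and degenerates to the blob
at zero frequency. The pixel grid is square, fixation at the exact image
center, row 1 at the top; all pixel values are continuous in brightness,
center and size.

One choice deserves emphasis because the sources are silent on it: after
stimulation offset, the instantaneous current is zero, so a literal
size-from-current rule would erase the percept in the very frame the
brightness model predicts a *delayed, fading offset*. We therefore let a
phosphene keep the size of its most recent stimulation while its
brightness decays through the leaky integrator. Size still never depends
on accumulated charge — only on the most recent nonzero current.

## Temporal discretization

The default frame duration is $\Delta t = 1/30$ s, a conventional video
rate that satisfies the explicit-Euler stability requirement
$\Delta t < \tau_{act}$ (enforced at configuration time). The Euler scheme
is used deliberately instead of exact exponential integration: it is the
reference behavior, and its first-order error is verified by test
(halving $\Delta t$ halves the error against the closed-form solution). A
pulse train of $T$ ms occupies $\lceil T / (1000\,\Delta t)\rceil$
consecutive frames, which rounds train durations up to whole frames.
Thresholds drawn negative (about 9% of draws under the default
$\theta_{50}, \sigma$) are redrawn until positive — a non-positive
detection threshold is physically meaningless, and the alternative
(truncation at zero) would pile mass at an always-on threshold.

## Interactions between electrodes

By default electrodes are independent and percepts add linearly (verified
exactly: the composed frame equals the sum of single-electrode runs).
Two optional interaction models are provided:

- a **co-stimulation penalty**
  $L = \tfrac1n \sum_i \sum_{j\ne i} I_i I_j / (1 + \lVert p_j - p_i
  \rVert^2)$, a scalar recorded per frame for use as a training loss;
- a **coactivation leak**, adding
  $\sum_{j \ne i,\, I_j > 0} I_j / (1 + 100\lVert p_j - p_i\rVert^2)$ to
  each active electrode's amplitude before the effective-current stage.

Self-pairs are excluded from both sums (a self term would contradict their
purpose), and "active" means nonzero amplitude on the current frame. The
leak kernel decays fast enough that summing over all active electrodes,
not only a neighborhood, is both faithful and cheap.

## Synthetic psychometrics and fitting

The clinical datasets behind the published parameter values are not
redistributable, so every fitting routine is validated by **parameter
recovery on synthetic data** generated by the package itself:

- `generate_detection_data()` simulates the activation $A$ reached by each
  stimulation condition and draws Bernoulli detections with
  $p = \Phi((A - \theta_{50})/\sigma)$ — the closed form implied by
  normally distributed thresholds. Conditions that never exceed the
  rheobase yield $A = 0$ and $p = 0$ exactly (thresholds are strictly
  positive); because the closed form and the truncated-threshold mechanism
  disagree only at $A = 0$, those conditions are excluded from the fit.
- `fit_threshold_distribution()` recovers $(\theta_{50}, \sigma)$ by
  trial-count-weighted nonlinear least squares on per-condition detection
  proportions (Levenberg–Marquardt on a unit-rescaled activation axis; the
  raw scale of $10^{-7}$ is hostile to derivative-based optimizers). The
  optimizer is driven through its residual interface rather than a model
  formula so that degenerate data — e.g. a near-deterministic generator,
  where the fitted $\sigma \to 0$ and the model gradient vanishes — still
  return the boundary estimate instead of failing.
- `fit_brightness_sigmoid()` recovers $(\lambda, A_{50})$ the same way
  from graded brightness responses. Note the design constraint: the
  brightness transition has width $\sim 10/\lambda \approx 5\times10^{-8}$
  in $A$, a band of roughly a dozen µA in amplitude, so informative
  conditions must sample inside it. The test helpers place conditions at
  $A_{50} \pm 20/\lambda$.
- `fit_strength_duration()` fits the threshold-charge line
  $Q_{thr} = I_0 (c + t)$ by ordinary least squares: slope = rheobase,
  intercept/slope = chronaxie. (The chronaxie value behind the published
  rheobase is itself unpublished; it is a free parameter of the synthetic
  data only.)
- `crossvalidate()` partitions conditions into stratified folds (ordered
  by activation, dealt round-robin with a seeded shuffle), fits on $k-1$
  and reports held-out $R^2$ — mirroring, at synthetic scale, the
  validation protocol used for the published fits.

What passing these tests shows — and does not show. Recovery at the tested
sample sizes (20 conditions × 500 trials; 15 conditions × 20 repeats with
response noise 0.05; threefold cross-validation over 30 conditions)
demonstrates that the fitting machinery is consistent and well-conditioned
under the model's own assumptions. Real psychometric data add attention
lapses, non-stationary thresholds, inter-electrode correlations and pulse
shapes outside the model class; none of these are emulated, so synthetic
recovery says nothing about how well the *model family* describes a given
subject.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale by design:
64–512 px frames, single electrodes to 10 × 10 Utah-style grids
(0.4 mm spacing), trains of a few hundred ms, and one long habituation
protocol (50 trains at 4 s intervals, then five at 200 s — about
$3\times10^4$ frames, simulated state-only without rendering). Every
stochastic element (threshold draws, layout perturbation, synthetic
trials, fold assignment) takes an explicit seed, and a session's frame
stream is bit-reproducible: same map, parameters, seed and stimulation
give identical images, and a sequence split at any frame and resumed from
exported state (`sim_state()` / `sim_restore()`) reproduces the unsplit
run exactly.

## Worked example

```{r example, eval = FALSE}
cfg <- phosim_config(resolution = c(128, 128), fov_deg = 16)
map <- make_grid_layout(10, 10, 0.4, origin = c(20, 0), cfg)
session <- sim_init(map, cfg, seed = 1)

tr <- build_train_sequence(map$electrode_id, amplitude_uA = 80,
                           train_ms = 166, pulse_width_us = 170,
                           frequency_hz = 300, interval_s = 1,
                           n_trains = 1, dt = cfg$dt)
out <- run_sequence(session, tr$stim, n_frames = tr$n_frames)
autoplot(out$frames[[tr$n_frames]])
```

## Known limitations

- Round, featureless phosphenes only; elongated or doubled percepts at
  high amplitude, color, and cross-column "amalgamated" features are out
  of scope (the Gabor option is a rendering variant, not a perceptual
  model).
- Symmetric biphasic pulses are assumed; other pulse shapes likely behave
  differently.
- The hard detection gate matches psychometric fitting but is a
  simplification of conscious detection; the smooth gate is a gradient
  convenience, not a perceptual claim.
- V1 only; thresholds constant within a session; no eye movements or
  gaze-contingent rendering.
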