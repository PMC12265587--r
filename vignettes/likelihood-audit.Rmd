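---
title: "Auditing the widefield SPT likelihood: emission versus motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the widefield SPT likelihood: emission versus motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptaudit)
```

## The question this package answers

In widefield fluorescence single-particle tracking (SPT), motion models —
Brownian motion and its anomalous relatives — are almost always learned
from trajectories that were themselves post-processed out of raw image
stacks. Whether that is sound depends on how much of the data likelihood
the motion model actually explains. `sptaudit` builds the full generative
model of such an experiment, factorizes its log-likelihood into an
*emission* part (optics, pixelation, exposure integration, camera noise)
and a *motion* part (the transition density of the particle), and measures
the share of each on synthetic data where the ground truth is known
exactly. It also provides a Bayesian tracker whose credible intervals can
be scored against that ground truth.

## The model

A single emitter moves in 3D through `N` frames; within each frame the
exposure window of length $t_E$ is resolved by $K$ interpolated positions
placed at midpoints of equal sub-intervals (so the exposure integral over
the frame is a midpoint rule, exact as $K \to \infty$). Frames repeat
every $t_F$; the dead time $t_F - t_E$ carries no photons but does carry
motion.

The log-likelihood splits into three additive terms:

1. **Initial position.** $R_1$ is a priori Gaussian around the optical
   axis with the PSF widths $(\sigma_{xy}, \sigma_{xy}, \sigma_z)$ — the
   static localization uncertainty of the instrument.
2. **Pixel emission.** The expected photon load of pixel $p$ in frame $n$
   is $u_{np} = F A_p t_E + (H t_E / K) \sum_k \mathrm{PSF}_p(R_{nk})$,
   with background flux $F$, photon rate $H$, pixel area $A_p$, and the
   pixel-integrated Gaussian PSF written as products of error-function
   differences. At high electron-multiplying gain the measured ADU count
   is Gamma distributed, $w_{np} \sim \Gamma(\beta u_{np}/2,\, 2G/\varphi)$,
   which is accurate for $G \ge 210$ where the multiplication cascade
   dominates Gaussian readout noise (readout noise is therefore omitted).
3. **Motion.** Under Brownian motion with diffusivity $D$, each step on
   the flattened (frame, interpolation) grid contributes
   $-|\Delta R|^2/(4 D \Delta t) - \tfrac{3}{2}\ln(4\pi D \Delta t)$.
   Because the intraframe lags are short, the per-step transition density
   exceeds one and the motion term is typically *positive* (order
   $+10^3$ at the reference configuration), while the emission term over
   $N \times P$ pixels is order $-10^5$.

The headline statistic is the emission share
$|\ell_{\mathrm{emis}}| / (|\ell_{\mathrm{emis}}| + |\ell_{\mathrm{mot}}|)$,
where the initial-position term is booked on the emission side (it
describes the instrument, not the dynamics). The share formula itself is
a package choice — with terms of order $-10^5$ and $+10^3$ it yields
$\approx 99\%$, consistent with the magnitudes it summarizes; a
log-magnitude-ratio variant is available via `fraction_method`.

## Reference parameterization

Defaults throughout (`default_run_config()`): background flux
$F = 10^5\,/\mu m^2 s$, photon rate $H = 10^4\,/s$ (an inexpensive
organic dye), NA 1.45, immersion index 1.515, wavelength 665 nm, EM gain
350, conversion 3.5 e-/ADU, quantum efficiency 0.95, a 32×32-pixel ROI of
133 nm effective pixels, $t_F = 33$ ms, $t_E = 30$ ms. The PSF widths
derive from the standard Gaussian approximation
$\sigma_{xy} = 0.21 \lambda / \mathrm{NA} \approx 96$ nm,
$\sigma_z = 0.78 n \lambda / \mathrm{NA}^2 \approx 374$ nm, overridable
in `optics_params()`. The audit additionally fixes $N = 15$ frames,
$K = 16$ and $D = 1\,\mu m^2/s$; these three are repository defaults
chosen to land in the documented orders of magnitude, not instrument
constants.

Two sources give slightly different pixel sizes (133 nm effective in the
parameter table, 130 nm from 13 µm/100×); the table value 133 nm is the
default and the field is configurable.

## The seven motion models

All simulators write positions onto the same acquisition grid and are
reproducible bit-for-bit from `(model, params, seed)`:

* **BM** — Gaussian steps, per-axis variance $2 D \Delta t$.
* **DBM** — BM plus drift $v\,\Delta t$; an unspecified drift is drawn
  uniformly on (0, 1] µm/s in the image plane only (so the particle stays
  in focus), with the lower limit enforced at machine precision. DBM with
  `v = 0` reproduces BM bit-for-bit under the same seed because both
  share one increment stream.
* **ATTM** — piecewise BM: local diffusivity redrawn from the truncated
  power law $P(D) \propto D^{\varsigma - 1}$ on $[10^{-3}, 1]$ after each
  deterministic sojourn $D^{-\gamma}$ (in frame-period units, so patches
  last $O(\text{frames})$); anomalous exponent $\varsigma / \gamma$. The
  power law is improper on $(0, \infty)$, hence the configurable
  truncation; redraws happen in continuous time and each grid step uses
  the exact time-integral of the piecewise diffusivity.
* **CTRW** — Pareto waiting times (tail exponent $\alpha \in (0,1)$,
  minimum one interpolation interval by default — a pure power law has no
  scale), decoupled Gaussian jumps of variance $2 D \tau_0$, positions
  piecewise-constant between jumps.
* **FBM** — per-axis fractional Gaussian noise via the Davies–Harte
  circulant embedding (FFT diagonalization of the circulant
  autocovariance, eigenvalue-scaled complex white noise, inverse
  transform), cumulative-summed; exact-Cholesky fallback with a warning
  if the embedding is not nonnegative definite. Circulant embedding
  requires a uniform lattice, so FBM paths are generated at the grid's
  mean spacing and the small dead-time irregularity is ignored for path
  generation (grid times act as labels); the FBM *likelihood*
  (`log_motion_alt`) uses true grid times.
* **LW** — constant-speed flights of Pareto duration
  ($\varsigma \in (0, 2)$), isotropic directions, linear interpolation
  within flights; ballistic ($\alpha = 2$) below $\varsigma = 1$,
  superdiffusive $\alpha = 3 - \varsigma$ above.
* **SBM** — independent Gaussian steps with variance
  $2 \mathcal{D}_\alpha (s_\ell^\alpha - s_{\ell-1}^\alpha)$ in elapsed
  time, $\mathcal{D}_\alpha = 1/(2\Gamma(1+\alpha))$, making the ensemble
  MSD exactly $6 \mathcal{D}_\alpha t^\alpha$. The literal
  $(\Delta t_\ell)^\alpha$ reading is available via
  `convention = "power_lag"`.

Persistent trajectories (LW, superdiffusive SBM) are uniformly shrunk to
fit the ROI and re-anchored so their first position is the draw from the
initial-position prior; all other models start at that draw directly.
This keeps the tracking experiment *self-consistent*: the prior the
likelihood asserts about $R_1$ is exactly the distribution the generator
used, which matters because the prior is tight (≈ 0.1 µm) and would
otherwise bias the first frames measurably.

### MSD diagnostics and ergodicity

`msd_curve()` defaults to the *ensemble* MSD (displacement from the
origin). This is deliberate: CTRW, SBM and ATTM are weakly non-ergodic,
so the time-averaged MSD of a single trajectory scales with a different
exponent than the ensemble law that defines $\alpha$. The conventional
time-averaged estimator is available with `average = "time"`. Exponent
recovery tests also need care with pre-asymptotics: CTRW needs lags well
above the minimum waiting time, and ATTM needs windows long enough for
several patch renewals; the tests document the windows they use.

## The tracker

`mcmc_track()` is a Metropolis-within-Gibbs sampler over all $N \times K$
positions under the BM-motion likelihood (whatever model generated the
data — that substitution is the point of the experiment). Moves per
sweep and frame: a rigid translation of the frame's positions, a
single-position perturbation, and an independence refresh of the whole
frame from the exact Brownian-bridge conditional given the neighbouring
anchors — for that move the motion prior cancels against the proposal
density, so acceptance depends on the emission term alone, which mixes
the intraframe path shape efficiently at realistic photon counts.
Scalar parameters get Metropolis steps on the log scale: the diffusivity
$D$ (log-uniform on $[10^{-3}, 10^2]$ µm²/s) and, by default, the photon
rate and background flux. Sampling the emission nuisances mirrors real
trackers, which do not know $H$ and $F$; it also makes the credible
bands slightly conservative, which is what the reference tracking tools
exhibit. Proposal scales adapt toward 20–40% acceptance during the first
third of the chain only (so post-burn-in samples come from a fixed
kernel), and position proposals are anisotropic — the axial component is
scaled up by $\sigma_z / \sigma_{xy}$, because the axial posterior is
that much wider than the lateral one and an isotropic kernel adapted to
the lateral width would leave z critically under-mixed (visible as
under-broadened lateral bands at defocused frames). Initialization is
the background-subtracted brightness centroid per frame.

Per-frame summaries (credible bands, coverage) use the frame's central
interpolation slot; coverage asks whether the true x *and* y lie inside
their marginal equal-tailed intervals. Two honest caveats follow. First,
even a perfectly calibrated posterior gives pooled both-axes coverage of
about $0.98^2 \approx 96\%$ with marginal 98% bands, so coverage near
99.9% (as reported for the reference nonparametric tracker) implies
*conservative* intervals; sampling the emission nuisances moves this
package's tracker in that direction (pooled ≈ 97–98% on matched data).
Second, for jump-dominated models (CTRW) the central-slot snapshot can
sit at one end of a bimodal within-frame blur, which costs a few frames
of coverage under model mismatch; this is a real property of the
experiment, not a sampler defect.

## Contribution audits

`run_reference_audit()` and `run_sweep()` evaluate the decomposition at
the ground-truth trajectory by default — the cleanest definition of "how
much does each factor explain". The source experiments instead average
the terms along post-burn-in MCMC samples; `mode = "mcmc"` reproduces
that protocol. The two agree on the emission share to well under a
percentage point at reference conditions. They differ in one interesting
regime: at large diffusivity ($D \approx 10$ µm²/s at reference timing),
the *sampled* trajectory-and-diffusivity pairs make the motion term
negative — posterior position wiggle and diffusivity uncertainty inflate
$|\Delta R|^2/(4 \hat{D} \Delta t)$ beyond its prior-typical value —
while the ground-truth evaluation stays mildly positive. The sign-flip
criterion therefore runs in MCMC mode; the sweep drivers report signed
motion terms so both behaviours are visible.

## Numerical choices

* Gamma log-densities use `lgamma`; counts below a configurable floor
  (default $10^{-3}$ ADU, relevant only for near-zero expected signal)
  are clipped and counted, never silently dropped.
* Pixels with exactly zero expected signal emit exactly zero ADU
  (degenerate Gamma) and contribute nothing to the log-likelihood; a
  positive count on such a pixel is an error.
* The defocus model broadens the lateral PSF as
  $\sigma_{xy}(Z) = \sigma_{xy}\sqrt{1 + (Z/\sigma_z)^2}$. This Gaussian
  3D approximation is the package's single largest modelling assumption
  (the exact reference PSF is not published in the main text); absolute
  log-likelihood values shift slightly under other PSFs but the
  order-of-magnitude contrasts do not.
* The step across each frame boundary uses the true lag including dead
  time.
* FBM dense likelihoods are limited to 512 time points (O(L³) Cholesky).
* TIFF output is uncompressed float32, one page per frame, so likelihood
  values survive a write/read round trip without quantization; a minimal
  reader/writer for exactly this layout is built in because the target
  environment has no R TIFF package (it has been validated against
  `tifffile`).

## What a green test establishes — and what it does not

The synthetic world contains exactly one always-on emitter, uniform
background, known optics, and Gamma-only camera noise. Green acceptance
tests establish that the *stated model's* emission term dominates its
motion term and that the tracker is calibrated *within this world*. They
do not establish anything about photophysics (blinking, bleaching),
multiple or unresolved emitters, non-uniform background, sCMOS noise
maps, or PSF mismatch on a real microscope. The coverage experiment is a
scaled-down replicate (15 trajectories, 10–20 frames, shortened chains);
its pooled fraction carries binomial noise of a few percentage points.

## Known limitations

* No exact trajectory likelihoods for ATTM/CTRW/LW (not available in the
  main source); `log_motion_alt` covers DBM, SBM, FBM.
* The sampler is single-emitter with a fixed, known PSF; it does not
  infer emitter number.
* The superballistic random walk named alongside the other models has no
  printed generative equation and is not implemented.
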