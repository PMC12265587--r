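# sptaudit

Likelihood audits and Bayesian tracking for widefield fluorescence
single-particle tracking (SPT).

## The problem

Anomalous-diffusion motion models (FBM, CTRW, Lévy walks, ...) are
routinely classified from SPT *trajectories* that were post-processed out
of raw camera frames. Whether a trajectory carries enough information
about the motion model depends on how the data likelihood splits between

* the **emission model** — how photons from a diffraction-limited emitter
  spread over the point-spread function, integrate over pixels and the
  exposure, and pass through EMCCD gain noise, and
* the **motion model** — the transition probability density
  P(Position | Motion) of the particle.

Writing the log-likelihood of a widefield SPT movie as

    ln L = ln P(R1)  +  ln P(Data | Position)  +  ln P(Position | Motion)
           (optics prior)   (pixel-wise Gamma)      (BM transition density)

this package simulates the whole experiment — trajectories under seven
diffusion models, EMCCD image stacks at a realistic reference
parameterization (background flux 1e5 /µm²s, photon rate 1e4 /s, NA 1.45,
EM gain 350, 32×32 px of 133 nm, 33/30 ms frame/exposure) — and measures
each term on data with known ground truth. For typical conditions the
emission side is of order −1e5 while the motion term is of order +1e3:
the emission model carries ≈99% of the log-likelihood's magnitude, which
is why trajectories can be tracked accurately with a Brownian-motion
likelihood regardless of the true motion model, and also why little
motion-model information survives into post-processed trajectories.

It also ships a Metropolis-within-Gibbs tracker (positions at K
intraframe interpolation points, plus diffusivity and emission nuisance
parameters on the log scale) whose 98% credible intervals are scored
against ground truth.

## Worked example

```r
library(sptaudit)

g     <- time_grid(15, 16)                     # N = 15 frames, K = 16
prior <- initial_position_prior(c(2.128, 2.128, 0),
                                optics_params()$sigma_xy,
                                optics_params()$sigma_z)
R1    <- draw_initial_position(prior, seed = 1)
traj  <- simulate_bm(R1, g, D = 1, seed = 1)   # D = 1 um^2/s
stack <- render_stack(traj, seed = 2)          # EMCCD forward model
stack
#> <spt_image_stack> 15 frames of 32 x 32 px (133 nm/px)
decompose(stack, traj)
#> <spt_loglik_decomposition>
#>   ln P(R1)            :         2.35
#>   ln P(Data|Position) :   -127930.88  (pixels; 0 clipped)
#>   ln P(Position|Motion):      948.59
#>   ln L                :   -126979.94
#>   emission fraction   :       0.9926
```

Reading: over 15 frames × 1024 pixels the Gamma emission term contributes
about −1.28e5 to ln L; the Brownian transition density, +949 (positive
because intraframe lags are short, so per-step densities exceed one). The
emission side therefore accounts for 99.3% of the total log-likelihood
magnitude — the motion model explains ~0.7% of the data.

Tracking and coverage:

```r
chain <- mcmc_track(stack, k_interp = 8, n_iter = 6000, seed = 3)
post  <- remove_burn_in(chain, c(2000, 6000))
bands <- credible_bands(post, level = 0.98)
coverage_fraction(bands, traj)        # fraction of frames with true x,y inside
```

Experiment drivers: `run_reference_audit()` (contribution table across
all seven motion models), `run_sweep()` (one-at-a-time parameter sweeps),
`run_coverage_experiment()` (the 15-trajectory tracking-accuracy
experiment), `orders_of_magnitude_report()`.

A command-line front end lives at `inst/cli/spt-audit.R`
(`simulate | render | audit | track | coverage | experiment | fixtures`),
driven by a JSON config (`default_run_config()` documents every field).

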