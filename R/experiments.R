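# Default generative parameters per motion model for the audit and
# coverage experiments: the "stated world" of the reference experiments.
# Values are chosen so trajectories stay within (or are rescaled into) a
# 32 x 32 px, 4.26 um ROI over O(10) frames.
default_motion_params <- function(model) {
  switch(model,
         BM = list(D = 1),
         DBM = list(D = 1),                     # v drawn U(0,1] azimuthal
         ATTM = list(sigma_exp = 0.8, gamma_exp = 1.0),
         CTRW = list(alpha = 0.5, D = 1),
         FBM = list(hurst = 0.3, D = 1),
         LW = list(sigma_exp = 1.5, speed = 1),
         SBM = list(alpha = 0.5),
         stop_invalid("unknown model '%s'", model))
}

needs_rescale <- function(model, params) {
  model == "LW" || (model == "SBM" && (params$alpha %||% 1) > 1)
}

# Simulate one trajectory for an imaging experiment. The first position is
# drawn from the optics prior centred on the optical axis (= ROI centre),
# exactly the initial-position density the likelihood assumes, so tracking
# posteriors are calibrated by construction. Persistent models (LW,
# superdiffusive SBM) are first uniformly shrunk to fit the ROI, then
# re-anchored so their first position coincides with the prior draw; the
# default margin keeps a one-sided path inside the ROI from its start.
simulate_for_imaging <- function(model, grid, optics, camera,
                                 params = list(), seed = NULL,
                                 margin = 0.26) {
  ext <- roi_extent(camera)
  prior <- initial_position_prior(c(ext / 2, ext / 2, 0), optics$sigma_xy,
                                  optics$sigma_z)
  with_rng_seed(seed, {
    R1 <- draw_initial_position(prior)
    traj <- simulate_trajectory(model, R1, grid, params)
    if (needs_rescale(model, traj$params)) {
      traj <- center_and_rescale(traj, ext, margin = margin)
      flat <- traj_flat(traj)
      shift <- R1 - flat[1, ]
      traj <- trajectory(sweep(flat, 2, shift, `+`), grid, traj$model,
                         traj$params, traj$seed)
    }
    traj
  })
}

audit_row <- function(dec, model, parameter, value, replicate) {
  data.frame(model = model, parameter = parameter, value = value,
             replicate = replicate, ln_initial = dec$ln_initial,
             ln_emission_pixels = dec$ln_emission_pixels,
             ln_emission_side = dec$ln_initial + dec$ln_emission_pixels,
             ln_motion = dec$ln_motion,
             emission_fraction = dec$emission_fraction,
             stringsAsFactors = FALSE)
}

# One simulate -> render -> decompose audit. mode = "truth" evaluates the
# likelihood at the ground-truth trajectory; mode = "mcmc" averages the
# decomposition terms over post-warm-up MCMC samples (the protocol the
# contribution figures of the source study follow).
audit_once <- function(model, grid, optics, camera, emission, D_motion = 1,
                       params = NULL, seed = NULL,
                       mode = c("truth", "mcmc"), n_iter = 3000L) {
  mode <- match.arg(mode)
  params <- params %||% default_motion_params(model)
  traj <- simulate_for_imaging(model, grid, optics, camera, params,
                               seed = seed)
  stack <- render_stack(traj, optics, camera, emission,
                        seed = if (is.null(seed)) NULL else seed + 10000L)
  if (mode == "truth") {
    return(decompose(stack, traj, optics, camera, emission, D = D_motion))
  }
  chain <- mcmc_track(stack, optics, camera, emission,
                      k_interp = grid$k_interp, n_iter = n_iter,
                      seed = if (is.null(seed)) NULL else seed + 20000L,
                      D_init = D_motion)
  keep <- remove_burn_in(chain, c(n_iter %/% 3L, n_iter))
  idx <- round(seq(1, length(keep$logliks), length.out = 50))
  terms <- vapply(idx, function(i) {
    tr <- trajectory(keep$samples[i, , ], grid, model = "BM")
    d <- decompose(stack, tr, optics, camera, emission,
                   D = keep$sampled_D[i])
    c(d$ln_initial, d$ln_emission_pixels, d$ln_motion)
  }, numeric(3))
  m <- rowMeans(terms)
  emis_side <- m[1] + m[2]
  structure(
    list(ln_initial = m[1], ln_emission_pixels = m[2], ln_motion = m[3],
         ln_total = sum(m),
         emission_fraction = abs(emis_side) /
           (abs(emis_side) + abs(m[3])),
         n_clipped = NA_integer_, fraction_method = "abs", D = NA_real_),
    class = "spt_loglik_decomposition")
}

#' Reference contribution audit across motion models
#'
#' For each model and replicate: simulate a trajectory at the reference
#' configuration, render the EMCCD stack, and evaluate the decomposed
#' log-likelihood (BM motion term) at the ground-truth trajectory (or
#' along MCMC samples with `mode = "mcmc"`).
#'
#' @param models Character vector of motion models (subset of
#'   [motion_model_names()]).
#' @param grid,optics,camera,emission Reference configuration records.
#' @param replicates Replicates per model.
#' @param seed Base seed; replicate r of model m uses a distinct offset.
#' @param D_motion Diffusivity used in the BM motion term (um^2/s).
#' @param mode `"truth"` (default) or `"mcmc"`.
#' @return A contribution table (`data.frame`) with one row per
#'   model x replicate.
#' @export
run_reference_audit <- function(models = motion_model_names(),
                                grid = time_grid(15, 16),
                                optics = optics_params(),
                                camera = camera_params(),
                                emission = emission_params(),
                                replicates = 10L, seed = 1L, D_motion = 1,
                                mode = "truth") {
  models <- match.arg(models, motion_model_names(), several.ok = TRUE)
  out <- list()
  for (mi in seq_along(models)) {
    for (r in seq_len(replicates)) {
      s <- seed + 1000L * mi + r
      dec <- audit_once(models[mi], grid, optics, camera, emission,
                        D_motion = D_motion, seed = s, mode = mode)
      out[[length(out) + 1L]] <-
        audit_row(dec, models[mi], "reference", NA_real_, r)
    }
  }
  do.call(rbind, out)
}

#' One-at-a-time parameter sweep of the contribution audit
#'
#' Varies a single parameter over a value list while the rest stay at the
#' reference configuration, running `replicates` seeded audits per value.
#' Supported parameters: `N` (frames), `K` (interpolation), `D`
#' (diffusivity, both generative and motion-term), `H` (photon rate), `F`
#' (background flux), `G` (gain), `phi` (conversion), `beta` (quantum
#' efficiency), `ds` (pixel size, um), `t_E` (exposure, s).
#'
#' @param parameter Parameter name (see above).
#' @param values Numeric values to sweep.
#' @param model Generating motion model (default `"DBM"`, the base model
#'   of the emission-parameter sweep figures; use `"BM"` for the
#'   frames/diffusivity panel).
#' @param replicates Audits per value.
#' @param seed Base seed.
#' @param grid,optics,camera,emission Reference configuration.
#' @param mode Audit mode, `"truth"` or `"mcmc"`.
#' @return Contribution table with one row per value x replicate.
#' @export
run_sweep <- function(parameter, values, model = "DBM", replicates = 10L,
                      seed = 1L, grid = time_grid(15, 16),
                      optics = optics_params(), camera = camera_params(),
                      emission = emission_params(), mode = "truth") {
  parameter <- match.arg(parameter, c("N", "K", "D", "H", "F", "G", "phi",
                                      "beta", "ds", "t_E"))
  stopifnot(length(values) >= 1L, all(values > 0))
  out <- list()
  for (vi in seq_along(values)) {
    v <- values[vi]
    g <- grid; cam <- camera; emi <- emission; Dm <- 1
    params <- NULL
    switch(parameter,
           N = { g <- time_grid(v, grid$k_interp, grid$frame_period,
                                grid$exposure) },
           K = { g <- time_grid(grid$n_frames, v, grid$frame_period,
                                grid$exposure) },
           D = { params <- modifyList(default_motion_params(model),
                                      list(D = v)); Dm <- v },
           H = { emi <- emission_params(v, emission$background_flux) },
           F = { emi <- emission_params(emission$photon_rate, v) },
           G = { cam <- camera_params(gain = v,
                                      conversion = camera$conversion,
                                      quantum_efficiency = camera$quantum_efficiency,
                                      pixels_per_side = camera$pixels_per_side,
                                      pixel_size_um = camera$pixel_size_um,
                                      frame_period = camera$frame_period,
                                      exposure = camera$exposure) },
           phi = { cam <- camera_params(gain = camera$gain, conversion = v,
                                        quantum_efficiency = camera$quantum_efficiency,
                                        pixels_per_side = camera$pixels_per_side,
                                        pixel_size_um = camera$pixel_size_um,
                                        frame_period = camera$frame_period,
                                        exposure = camera$exposure) },
           beta = { cam <- camera_params(gain = camera$gain,
                                         conversion = camera$conversion,
                                         quantum_efficiency = v,
                                         pixels_per_side = camera$pixels_per_side,
                                         pixel_size_um = camera$pixel_size_um,
                                         frame_period = camera$frame_period,
                                         exposure = camera$exposure) },
           ds = { cam <- camera_params(gain = camera$gain,
                                       conversion = camera$conversion,
                                       quantum_efficiency = camera$quantum_efficiency,
                                       pixels_per_side = camera$pixels_per_side,
                                       pixel_size_um = v,
                                       frame_period = camera$frame_period,
                                       exposure = camera$exposure) },
           t_E = { cam <- camera_params(gain = camera$gain,
                                        conversion = camera$conversion,
                                        quantum_efficiency = camera$quantum_efficiency,
                                        pixels_per_side = camera$pixels_per_side,
                                        pixel_size_um = camera$pixel_size_um,
                                        frame_period = camera$frame_period,
                                        exposure = v)
                   g <- time_grid(grid$n_frames, grid$k_interp,
                                  grid$frame_period, v) })
    for (r in seq_len(replicates)) {
      s <- seed + 1000L * vi + r
      dec <- audit_once(model, g, optics, cam, emi, D_motion = Dm,
                        params = params, seed = s, mode = mode)
      out[[length(out) + 1L]] <- audit_row(dec, model, parameter, v, r)
    }
  }
  do.call(rbind, out)
}

#' Standard trajectory set for the coverage experiment
#'
#' Thirteen anomalous trajectories (ATTM, CTRW, FBM, LW, SBM variants) and
#' two normal ones (BM, DBM), each with its own frame count in 10-20, the
#' scaled-down replicate of the tracking-accuracy experiment.
#'
#' @return List of specs `list(model, params, n_frames)`.
#' @export
coverage_trajectory_set <- function() {
  list(
    list(model = "ATTM", params = list(sigma_exp = 0.8, gamma_exp = 1.0), n_frames = 14L),
    list(model = "ATTM", params = list(sigma_exp = 0.5, gamma_exp = 1.0), n_frames = 12L),
    list(model = "ATTM", params = list(sigma_exp = 1.2, gamma_exp = 1.6), n_frames = 16L),
    list(model = "CTRW", params = list(alpha = 0.5, D = 1), n_frames = 14L),
    list(model = "CTRW", params = list(alpha = 0.7, D = 1), n_frames = 12L),
    list(model = "CTRW", params = list(alpha = 0.3, D = 0.5), n_frames = 10L),
    list(model = "FBM", params = list(hurst = 0.3, D = 0.5), n_frames = 14L),
    list(model = "FBM", params = list(hurst = 0.7, D = 0.2), n_frames = 12L),
    list(model = "FBM", params = list(hurst = 0.4, D = 1), n_frames = 16L),
    list(model = "LW", params = list(sigma_exp = 1.5, speed = 2), n_frames = 14L),
    list(model = "LW", params = list(sigma_exp = 0.5, speed = 2), n_frames = 12L),
    list(model = "SBM", params = list(alpha = 0.5), n_frames = 14L),
    list(model = "SBM", params = list(alpha = 1.5), n_frames = 12L),
    list(model = "BM", params = list(D = 1), n_frames = 14L),
    list(model = "DBM", params = list(D = 1), n_frames = 12L))
}

#' Tracking-coverage experiment
#'
#' Simulates trajectories under mixed motion models, renders their image
#' stacks, tracks each with the BM-likelihood MCMC sampler, removes
#' burn-in, and scores pooled 98% credible-interval coverage of the true
#' in-frame image-plane (x, y) positions.
#'
#' @param traj_specs List of specs as produced by
#'   [coverage_trajectory_set()].
#' @param optics,camera,emission Configuration records.
#' @param k_interp Intraframe positions used for both simulation and
#'   inference.
#' @param n_iter MCMC iterations per stack.
#' @param burn_frac Fraction of the chain discarded as burn-in (the
#'   `[2e3, 6e3]`-of-6e3 convention corresponds to 1/3).
#' @param level Credible level.
#' @param seed Base seed.
#' @return List: `pooled` fraction, `n_covered`, `n_frames`, and a
#'   per-trajectory `table`.
#' @export
run_coverage_experiment <- function(traj_specs = coverage_trajectory_set(),
                                    optics = optics_params(),
                                    camera = camera_params(),
                                    emission = emission_params(),
                                    k_interp = 8L, n_iter = 6000L,
                                    burn_frac = 1 / 3, level = 0.98,
                                    seed = 1L) {
  stopifnot(length(traj_specs) >= 1L)
  rows <- list()
  n_cov <- 0L
  n_tot <- 0L
  for (i in seq_along(traj_specs)) {
    sp <- traj_specs[[i]]
    grid <- time_grid(sp$n_frames, k_interp, camera$frame_period,
                      camera$exposure)
    s <- seed + 100L * i
    traj <- simulate_for_imaging(sp$model, grid, optics, camera,
                                 sp$params, seed = s)
    stack <- render_stack(traj, optics, camera, emission, seed = s + 1L)
    chain <- mcmc_track(stack, optics, camera, emission,
                        k_interp = k_interp, n_iter = n_iter,
                        seed = s + 2L)
    lo <- max(1L, floor(n_iter * burn_frac))
    chain <- remove_burn_in(chain, c(lo, n_iter))
    bands <- credible_bands(chain, level = level)
    cov <- coverage_fraction(bands, traj, axes = c("x", "y"))
    n_cov <- n_cov + attr(cov, "n_covered")
    n_tot <- n_tot + attr(cov, "n_frames")
    rows[[i]] <- data.frame(
      model = sp$model, n_frames = sp$n_frames,
      n_covered = attr(cov, "n_covered"), fraction = as.numeric(cov),
      anomalous = !(sp$model %in% c("BM", "DBM")),
      stringsAsFactors = FALSE)
  }
  list(pooled = n_cov / n_tot, n_covered = n_cov, n_frames = n_tot,
       table = do.call(rbind, rows))
}

#' Order-of-magnitude summary of a contribution table
#'
#' Per model: the log10 ratio of the emission-side magnitude to the motion
#' magnitude (how many orders of magnitude the emission model dominates)
#' and the log10 magnitude of their signed difference in log space.
#'
#' @param table A contribution table from [run_reference_audit()] or
#'   [run_sweep()].
#' @return `data.frame` with columns `model`, `ratio_order`,
#'   `difference_order`, `motion_zero` (flag for an exactly-zero motion
#'   term, where the ratio is infinite).
#' @export
orders_of_magnitude_report <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L)
  out <- lapply(split(table, table$model), function(d) {
    emis <- mean(abs(d$ln_emission_side))
    mot <- mean(abs(d$ln_motion))
    data.frame(model = d$model[1],
               ratio_order = if (mot == 0) Inf else log10(emis / mot),
               difference_order =
                 log10(mean(abs(d$ln_emission_side - d$ln_motion))),
               motion_zero = mot == 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
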