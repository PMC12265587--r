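# Shared fixtures: the reference parameterization and a cheap small-scale
# variant used where a full 32 x 32 x 15-frame render would be wasteful.

ref_optics <- optics_params()
ref_camera <- camera_params()
ref_emission <- emission_params()
ref_grid <- time_grid(15, 16)

small_grid <- function(n_frames = 6, k_interp = 4) {
  time_grid(n_frames, k_interp)
}

small_camera <- function(npix = 16L) {
  camera_params(pixels_per_side = npix)
}

centre_prior <- function(camera = ref_camera, optics = ref_optics) {
  ext <- camera$pixels_per_side * camera$pixel_size_um
  initial_position_prior(c(ext / 2, ext / 2, 0), optics$sigma_xy,
                         optics$sigma_z)
}

# Ensemble simulation helper: n trajectories of one model, seeds 1..n + off.
simulate_ensemble <- function(n, fun, ..., seed_offset = 0L) {
  lapply(seq_len(n), function(i) fun(..., seed = seed_offset + i))
}
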