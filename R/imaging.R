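#' Optical parameters
#'
#' Widefield optics description. When `sigma_xy`/`sigma_z` are not supplied
#' they are derived from the Gaussian approximation to the widefield PSF
#' (see [derive_psf_widths()]).
#'
#' @param na Numerical aperture (must not exceed `refractive_index`).
#' @param refractive_index Immersion refractive index n.
#' @param wavelength_nm Emission wavelength in nanometres.
#' @param magnification Optical magnification m (metadata only; pixel size
#'   is specified effectively in [camera_params()]).
#' @param sigma_xy,sigma_z Optional PSF width overrides in micrometres.
#' @return Object of class `spt_optics`.
#' @export
optics_params <- function(na = 1.45, refractive_index = 1.515,
                          wavelength_nm = 665, magnification = 100,
                          sigma_xy = NULL, sigma_z = NULL) {
  check_scalar(na, "na", lower = 0, open_lower = TRUE)
  check_scalar(refractive_index, "refractive_index", lower = na)
  check_scalar(wavelength_nm, "wavelength_nm", lower = 0, open_lower = TRUE)
  o <- structure(
    list(na = na, refractive_index = refractive_index,
         wavelength_nm = wavelength_nm, magnification = magnification,
         sigma_xy = sigma_xy, sigma_z = sigma_z),
    class = "spt_optics")
  w <- derive_psf_widths(o)
  o$sigma_xy <- sigma_xy %||% w[["sigma_xy"]]
  o$sigma_z <- sigma_z %||% w[["sigma_z"]]
  check_scalar(o$sigma_xy, "sigma_xy", lower = 0, open_lower = TRUE)
  check_scalar(o$sigma_z, "sigma_z", lower = 0, open_lower = TRUE)
  o
}

#' Gaussian PSF widths from optics
#'
#' Standard Gaussian approximation to the widefield PSF:
#' `sigma_xy = 0.21 * lambda / NA` laterally and
#' `sigma_z = 0.78 * n * lambda / NA^2` axially. Explicit overrides stored
#' in the optics object pass through untouched.
#'
#' @param optics An [optics_params()] object.
#' @return Named numeric vector `c(sigma_xy, sigma_z)` in micrometres.
#' @export
derive_psf_widths <- function(optics) {
  stopifnot(inherits(optics, "spt_optics"))
  if (optics$na > optics$refractive_index) {
    stop_invalid("numerical aperture cannot exceed the refractive index")
  }
  lam_um <- optics$wavelength_nm / 1000
  c(sigma_xy = optics$sigma_xy %||% (0.21 * lam_um / optics$na),
    sigma_z = optics$sigma_z %||%
      (0.78 * optics$refractive_index * lam_um / optics$na^2))
}

#' EMCCD camera parameters
#'
#' @param gain Electron-multiplying gain G (dimensionless). The high-gain
#'   Gamma measurement model is accurate for G >= 210; a warning is issued
#'   below that.
#' @param conversion Conversion factor phi in electrons per ADU.
#' @param quantum_efficiency Quantum efficiency beta in (0, 1].
#' @param pixels_per_side Side length of the square ROI in pixels.
#' @param pixel_size_um Effective (magnification-corrected) pixel side
#'   length Delta-s in micrometres.
#' @param frame_period,exposure Frame period t_F and exposure t_E in
#'   seconds.
#' @return Object of class `spt_camera`.
#' @export
camera_params <- function(gain = 350, conversion = 3.5,
                          quantum_efficiency = 0.95, pixels_per_side = 32L,
                          pixel_size_um = 0.133, frame_period = 0.033,
                          exposure = 0.030) {
  check_scalar(gain, "gain", lower = 0, open_lower = TRUE)
  if (gain < 210) {
    warning("gain G < 210: the high-gain Gamma measurement model may be ",
            "inaccurate", call. = FALSE)
  }
  check_scalar(conversion, "conversion", lower = 0, open_lower = TRUE)
  check_scalar(quantum_efficiency, "quantum_efficiency", lower = 0,
               upper = 1, open_lower = TRUE)
  check_scalar(pixels_per_side, "pixels_per_side", lower = 1)
  check_scalar(pixel_size_um, "pixel_size_um", lower = 0, open_lower = TRUE)
  check_scalar(frame_period, "frame_period", lower = 0, open_lower = TRUE)
  check_scalar(exposure, "exposure", lower = 0, open_lower = TRUE,
               upper = frame_period)
  structure(
    list(gain = gain, conversion = conversion,
         quantum_efficiency = quantum_efficiency,
         pixels_per_side = as.integer(pixels_per_side),
         pixel_size_um = pixel_size_um, frame_period = frame_period,
         exposure = exposure),
    class = "spt_camera")
}

#' Emission parameters
#'
#' @param photon_rate Fluorophore photon emission rate H in photons/s.
#' @param background_flux Ambient photon flux F in photons/(um^2 s).
#' @param n_emitters Number of emitters M (fixed at 1).
#' @return Object of class `spt_emission`.
#' @export
emission_params <- function(photon_rate = 1e4, background_flux = 1e5,
                            n_emitters = 1L) {
  check_scalar(photon_rate, "photon_rate", lower = 0)
  check_scalar(background_flux, "background_flux", lower = 0)
  if (n_emitters != 1L) stop_invalid("only single-emitter data (M = 1) is supported")
  structure(list(photon_rate = photon_rate,
                 background_flux = background_flux, n_emitters = 1L),
            class = "spt_emission")
}

# Lateral ROI side length in micrometres.
roi_extent <- function(camera) camera$pixels_per_side * camera$pixel_size_um

# Defocus-broadened lateral PSF width at axial position z.
psf_width_at <- function(z, sigma_xy, sigma_z) {
  sigma_xy * sqrt(1 + (z / sigma_z)^2)
}

#' Pixel-integrated PSF mass
#'
#' Fraction of a unit-intensity Gaussian PSF centred at `R = (X, Y, Z)`
#' captured by the rectangular pixel `[xlo, xhi] x [ylo, yhi]`, with the
#' lateral width broadened by defocus as
#' `sigma(Z) = sigma_xy * sqrt(1 + (Z / sigma_z)^2)`. Expressed through
#' Gaussian CDF (error-function) differences; sums to 1 over the infinite
#' plane.
#'
#' @param xlo,xhi,ylo,yhi Pixel edges in micrometres (vectorized).
#' @param R Emitter position 3-vector in micrometres.
#' @param sigma_xy,sigma_z PSF widths in micrometres.
#' @return Dimensionless capture fraction(s) in [0, 1].
#' @export
pixel_psf_integral <- function(xlo, xhi, ylo, yhi, R, sigma_xy, sigma_z) {
  if (any(xhi < xlo) || any(yhi < ylo)) {
    stop_invalid("invalid pixel rectangle: upper edge below lower edge")
  }
  s <- psf_width_at(R[3], sigma_xy, sigma_z)
  (pnorm(xhi, R[1], s) - pnorm(xlo, R[1], s)) *
    (pnorm(yhi, R[2], s) - pnorm(ylo, R[2], s))
}

#' Expected signal stack
#'
#' Expected photoelectron-generating photon count per pixel per frame:
#' `u[n, p] = F * A_p * tau + (H * tau / K) * sum_k PSF-mass(p, R[n, k])`,
#' the exposure-time emission integral discretized as a midpoint rule over
#' the K intraframe positions, plus the background floor `F * A_p * tau`
#' with `A_p` the pixel area and `tau` the exposure period.
#'
#' @param traj An `spt_trajectory` whose grid timing matches the camera.
#' @param optics,camera,emission Parameter records.
#' @return Object of class `spt_expected_signal` with field `u` (N x P,
#'   pixel index `p = (iy - 1) * npix + ix`, x fastest).
#' @export
expected_signal <- function(traj, optics, camera, emission) {
  stopifnot(inherits(traj, "spt_trajectory"), inherits(optics, "spt_optics"),
            inherits(camera, "spt_camera"), inherits(emission, "spt_emission"))
  grid <- traj$grid
  if (abs(grid$frame_period - camera$frame_period) > 1e-12 ||
      abs(grid$exposure - camera$exposure) > 1e-12) {
    stop_invalid("trajectory grid timing does not match camera timing")
  }
  npix <- camera$pixels_per_side
  ds <- camera$pixel_size_um
  tau <- camera$exposure
  K <- grid$k_interp
  edges <- (0:npix) * ds
  bg <- emission$background_flux * ds^2 * tau
  u <- matrix(bg, grid$n_frames, npix * npix)
  if (emission$photon_rate > 0) {
    hk <- emission$photon_rate * tau / K
    for (n in seq_len(grid$n_frames)) {
      x <- traj$positions[n, , 1]
      y <- traj$positions[n, , 2]
      s <- psf_width_at(traj$positions[n, , 3], optics$sigma_xy,
                        optics$sigma_z)
      # AX[k, ix]: mass of position k's PSF in pixel column ix (same for y)
      cx <- vapply(seq_len(K),
                   function(k) diff(pnorm(edges, x[k], s[k])), numeric(npix))
      cy <- vapply(seq_len(K),
                   function(k) diff(pnorm(edges, y[k], s[k])), numeric(npix))
      lat <- cx %*% t(cy)                    # [ix, iy], summed over k
      u[n, ] <- bg + hk * as.vector(lat)
    }
  }
  structure(list(u = u, npix = npix, pixel_size_um = ds, tau = tau,
                 background = bg),
            class = "spt_expected_signal")
}

#' Corrupt an expected-signal stack with EMCCD Gamma noise
#'
#' High-gain EMCCD measurement model: each pixel's ADU count is an
#' independent Gamma draw with shape `beta * u / 2` and scale
#' `2 * G / phi`. Pixels with `u = 0` emit exactly 0 ADU (degenerate
#' Gamma).
#'
#' @param expected An [expected_signal()] result.
#' @param camera A [camera_params()] record.
#' @param seed Integer RNG seed.
#' @return Object of class `spt_image_stack` with field `w` (N x P, ADU)
#'   and metadata.
#' @export
emccd_sample <- function(expected, camera, seed = NULL) {
  stopifnot(inherits(expected, "spt_expected_signal"),
            inherits(camera, "spt_camera"))
  u <- expected$u
  if (any(u < 0)) stop_invalid("expected signal must be non-negative")
  shape <- camera$quantum_efficiency * u / 2
  scl <- 2 * camera$gain / camera$conversion
  with_rng_seed(seed, {
    w <- u
    pos <- shape > 0
    w[pos] <- rgamma(sum(pos), shape = shape[pos], scale = scl)
    w[!pos] <- 0
    image_stack(w, camera, meta = list(seed = seed %||% NA_integer_))
  })
}

#' Image stack container
#'
#' @param w N x P matrix of measured counts in ADU (non-negative).
#' @param camera The generating [camera_params()].
#' @param meta Named list of provenance metadata.
#' @return Object of class `spt_image_stack`.
#' @export
image_stack <- function(w, camera, meta = list()) {
  npix <- camera$pixels_per_side
  if (!is.matrix(w) || ncol(w) != npix * npix) {
    stop_invalid("w must be N x P with P = pixels_per_side^2")
  }
  if (any(w < 0) || !all(is.finite(w))) {
    stop_invalid("ADU counts must be finite and non-negative")
  }
  structure(list(w = w, npix = npix, pixel_size_um = camera$pixel_size_um,
                 camera = camera, meta = meta),
            class = "spt_image_stack")
}

#' @export
print.spt_image_stack <- function(x, ...) {
  cat(sprintf("<spt_image_stack> %d frames of %d x %d px (%.0f nm/px)\n",
              nrow(x$w), x$npix, x$npix, 1000 * x$pixel_size_um))
  invisible(x)
}

#' Render a trajectory into a synthetic EMCCD image stack
#'
#' Composition of [expected_signal()] and [emccd_sample()]; the metadata
#' records every parameter set and the seed so a render is reproducible
#' bit-for-bit.
#'
#' @inheritParams expected_signal
#' @param seed Integer RNG seed for the measurement noise.
#' @return An `spt_image_stack`.
#' @export
render_stack <- function(traj, optics = optics_params(),
                         camera = camera_params(),
                         emission = emission_params(), seed = NULL) {
  u <- expected_signal(traj, optics, camera, emission)
  stack <- emccd_sample(u, camera, seed = seed)
  stack$meta <- list(seed = seed %||% NA_integer_, model = traj$model,
                     traj_seed = traj$seed, optics = unclass(optics),
                     camera = unclass(camera), emission = unclass(emission))
  stack
}
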