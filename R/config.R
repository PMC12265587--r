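#' Default run configuration
#'
#' The reference parameterization: background flux F = 1e5 /um^2 s, photon
#' rate H = 1e4 /s, NA = 1.45, n = 1.515, lambda = 665 nm, G = 350,
#' phi = 3.5 e-/ADU, beta = 0.95, 32 x 32 px of 133 nm, t_F = 33 ms,
#' t_E = 30 ms, with repo defaults N = 15 frames, K = 16, D = 1 um^2/s.
#'
#' @return Nested named list (a `RunConfig`).
#' @export
default_run_config <- function() {
  list(
    grid = list(n_frames = 15L, k_interp = 16L),
    motion = list(model = "BM", params = list(D = 1)),
    optics = list(na = 1.45, refractive_index = 1.515, wavelength_nm = 665,
                  magnification = 100, sigma_xy = NULL, sigma_z = NULL),
    camera = list(gain = 350, conversion = 3.5, quantum_efficiency = 0.95,
                  pixels_per_side = 32L, pixel_size_um = 0.133,
                  frame_period = 0.033, exposure = 0.030),
    emission = list(photon_rate = 1e4, background_flux = 1e5,
                    n_emitters = 1L),
    sampler = list(n_iter = 6000L, k_interp = 8L, sample_D = TRUE,
                   burn_in = c(2000L, 6000L), level = 0.98),
    seed = 1L)
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(defaults)) {
      stop_invalid("unknown config key '%s%s'", path, nm)
    }
    here <- paste0(path, nm, ".")
    free_form <- identical(here, "motion.params.")
    if (is.list(defaults[[nm]]) && !free_form) {
      if (!is.list(user[[nm]])) {
        stop_invalid("config key '%s%s' must be a section", path, nm)
      }
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], here)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load (and validate) a run configuration
#'
#' Reads a JSON configuration, fills unspecified fields from
#' [default_run_config()], rejects unknown keys, and validates every
#' section by constructing the corresponding parameter records (range
#' violations are reported with the offending field name). An empty file
#' yields the full reference defaults.
#'
#' @param path Path to a JSON file.
#' @return Validated `RunConfig` list.
#' @export
load_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (!nzchar(trimws(txt))) list() else {
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  }
  cfg <- merge_config(default_run_config(), user)
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg A `RunConfig` list.
#' @return The config, with integer-valued fields coerced, invisibly
#'   validated by constructing all parameter records.
#' @export
validate_config <- function(cfg) {
  cfg$grid$n_frames <- as.integer(cfg$grid$n_frames)
  cfg$grid$k_interp <- as.integer(cfg$grid$k_interp)
  cfg$camera$pixels_per_side <- as.integer(cfg$camera$pixels_per_side)
  cfg$emission$n_emitters <- as.integer(cfg$emission$n_emitters)
  cfg$sampler$n_iter <- as.integer(cfg$sampler$n_iter)
  cfg$sampler$k_interp <- as.integer(cfg$sampler$k_interp)
  cfg$sampler$burn_in <- as.integer(cfg$sampler$burn_in)
  cfg$motion$model <- match.arg(cfg$motion$model, motion_model_names())
  invisible(config_objects(cfg))
  cfg
}

#' Build parameter records from a configuration
#'
#' @param cfg A `RunConfig`.
#' @return List with `grid`, `optics`, `camera`, `emission` objects.
#' @export
config_objects <- function(cfg) {
  camera <- do.call(camera_params, cfg$camera)
  list(grid = time_grid(cfg$grid$n_frames, cfg$grid$k_interp,
                        camera$frame_period, camera$exposure),
       optics = do.call(optics_params, cfg$optics),
       camera = camera,
       emission = do.call(emission_params, cfg$emission))
}

#' Save a run configuration as JSON
#'
#' @param cfg A `RunConfig`.
#' @param path Output path.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
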