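#' Write / read an image stack (TIFF + JSON metadata sidecar)
#'
#' The pixel data go to `path` as a float32 multi-page TIFF and the full
#' provenance (camera parameters, metadata, seed) to `paste0(path,
#' ".json")`. The round-trip is lossless apart from float64 -> float32
#' quantization of the ADU values being avoided entirely: values are
#' stored as float32 and compared as float32 (the renderer can be asked to
#' produce float32-exact stacks via [stack_to_float32()]).
#'
#' @param stack An `spt_image_stack`.
#' @param path TIFF output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "spt_image_stack"))
  write_tiff(stack$w, path, stack$npix)
  meta <- list(npix = stack$npix, n_frames = nrow(stack$w),
               camera = unclass(stack$camera), meta = stack$meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_stack
#' @return `read_stack()` returns the reconstructed `spt_image_stack`.
#' @export
read_stack <- function(path) {
  dat <- read_tiff(path)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop_invalid("missing metadata sidecar %s", side)
  meta <- jsonlite::fromJSON(side, simplifyVector = TRUE)
  if (meta$npix != dat$npix || meta$n_frames != nrow(dat$w)) {
    stop_invalid("metadata sidecar does not match TIFF shape")
  }
  camera <- do.call(camera_params, meta$camera)
  image_stack(dat$w, camera, meta = meta$meta)
}

#' Round ADU values to float32 precision
#'
#' Apply before [write_stack()] when bit-identical round-trips through the
#' float32 TIFF container are required.
#'
#' @param stack An `spt_image_stack`.
#' @return The stack with `w` quantized to float32.
#' @export
stack_to_float32 <- function(stack) {
  stopifnot(inherits(stack, "spt_image_stack"))
  raw <- writeBin(as.numeric(stack$w), raw(), size = 4, endian = "little")
  q <- readBin(raw, "numeric", n = length(stack$w), size = 4,
               endian = "little")
  stack$w <- matrix(q, nrow(stack$w), ncol(stack$w))
  stack
}

#' Write / read a trajectory as CSV with a JSON sidecar
#'
#' Columns: `frame`, `interp` (both 1-based), `t_s`, `x_um`, `y_um`,
#' `z_um`, `model`, `seed`. Grid timing and generative parameters are
#' serialized to `paste0(path, ".json")`.
#'
#' @param traj An `spt_trajectory`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_traj <- function(traj, path) {
  stopifnot(inherits(traj, "spt_trajectory"))
  grid <- traj$grid
  flat <- traj_flat(traj)
  df <- data.frame(
    frame = rep(seq_len(grid$n_frames), each = grid$k_interp),
    interp = rep(seq_len(grid$k_interp), times = grid$n_frames),
    t_s = grid_times(grid), x_um = flat[, 1], y_um = flat[, 2],
    z_um = flat[, 3], model = traj$model, seed = traj$seed)
  write.csv(df, path, row.names = FALSE)
  side <- list(grid = list(n_frames = grid$n_frames,
                           k_interp = grid$k_interp,
                           frame_period = grid$frame_period,
                           exposure = grid$exposure),
               model = traj$model, params = traj$params, seed = traj$seed)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_traj
#' @return `read_traj()` returns the reconstructed `spt_trajectory`.
#' @export
read_traj <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) {
    stop_invalid("missing trajectory sidecar %s", side_path)
  }
  side <- jsonlite::fromJSON(side_path, simplifyVector = TRUE)
  grid <- time_grid(side$grid$n_frames, side$grid$k_interp,
                    side$grid$frame_period, side$grid$exposure)
  if (nrow(df) != grid$n_frames * grid$k_interp) {
    stop_invalid("trajectory CSV row count does not match sidecar grid")
  }
  ord <- order(df$frame, df$interp)
  df <- df[ord, , drop = FALSE]
  pos <- as.matrix(df[, c("x_um", "y_um", "z_um")])
  dimnames(pos) <- NULL
  trajectory(pos, grid, model = side$model,
             params = as.list(side$params),
             seed = side$seed %||% NA_integer_)
}

#' Write / read a posterior chain
#'
#' Chains are runtime artifacts stored in R's native serialized (RDS)
#' container, compressed.
#'
#' @param chain An `spt_chain`.
#' @param path Output path (conventionally `.rds`).
#' @return `path`, invisibly; `read_chain()` returns the `spt_chain`.
#' @export
write_chain <- function(chain, path) {
  stopifnot(inherits(chain, "spt_chain"))
  saveRDS(chain, path)
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  chain <- readRDS(path)
  if (!inherits(chain, "spt_chain")) stop_invalid("%s is not a chain", path)
  chain
}

#' Generate the deterministic miniature fixture set
#'
#' Writes, under `dir`: a 5-frame BM image stack (`bm_stack.tiff` +
#' sidecar), one 64-step trajectory CSV per motion model
#' (`traj_<model>.csv`), and a 500-sample toy chain (`toy_chain.rds`).
#' Identical seeds yield byte-identical fixtures.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Named list of file paths, invisibly.
#' @export
make_fixtures <- function(dir = tempfile("sptfixtures"), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  optics <- optics_params()
  camera <- camera_params()
  emission <- emission_params()
  paths <- list()
  grid5 <- time_grid(5, 4, camera$frame_period, camera$exposure)
  traj <- simulate_for_imaging("BM", grid5, optics, camera, list(D = 1),
                               seed = seed)
  stack <- stack_to_float32(render_stack(traj, optics, camera, emission,
                                         seed = seed + 1L))
  paths$stack <- file.path(dir, "bm_stack.tiff")
  write_stack(stack, paths$stack)
  paths$stack_traj <- file.path(dir, "bm_stack_traj.csv")
  write_traj(traj, paths$stack_traj)
  grid64 <- time_grid(64, 1, camera$frame_period, camera$exposure)
  for (m in motion_model_names()) {
    tr <- simulate_for_imaging(m, grid64, optics, camera,
                               default_motion_params(m),
                               seed = seed + match(m, motion_model_names()))
    p <- file.path(dir, sprintf("traj_%s.csv", tolower(m)))
    write_traj(tr, p)
    paths[[paste0("traj_", tolower(m))]] <- p
  }
  chain <- mcmc_track(stack, optics, camera, emission, k_interp = 2L,
                      n_iter = 1000L, seed = seed + 100L)
  chain$samples <- chain$samples[seq_len(500L), , , drop = FALSE]
  chain$logliks <- chain$logliks[seq_len(500L)]
  chain$sampled_D <- chain$sampled_D[seq_len(500L)]
  paths$chain <- file.path(dir, "toy_chain.rds")
  write_chain(chain, paths$chain)
  invisible(paths)
}
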