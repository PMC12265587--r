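test_that("initial-position log-density matches the trivariate Gaussian", {
  p <- initial_position_prior(c(0, 0, 0), 0.1, 0.4)
  # mode value: -ln[(2 pi)^{3/2} sigma_xy^2 sigma_z]
  expect_equal(log_initial(c(0, 0, 0), p),
               -log((2 * pi)^1.5 * 0.01 * 0.4), tolerance = 1e-12)
  expect_equal(log_initial(c(0, 0, 0), p), 2.7646453, tolerance = 1e-6)
  s <- 0.2
  ps <- initial_position_prior(c(0, 0, 0), s, s)
  expect_equal(log_initial(c(0, 0, 0), ps), -log((2 * pi)^1.5 * s^3),
               tolerance = 1e-12)
  # displaced point agrees with an independent dnorm-product oracle
  r <- c(0.05, -0.1, 0.3)
  expect_equal(log_initial(r, p),
               sum(dnorm(r, 0, c(0.1, 0.1, 0.4), log = TRUE)),
               tolerance = 1e-12)
})

test_that("initial-position density integrates to one", {
  p <- initial_position_prior(c(0, 0, 0), 0.1, 0.4)
  m <- 60L
  gx <- seq(-0.6, 0.6, length.out = m)
  gz <- seq(-2.4, 2.4, length.out = m)
  dx <- diff(gx)[1]; dz <- diff(gz)[1]
  dens <- exp(outer(dnorm(gx, 0, 0.1, log = TRUE),
                    dnorm(gx, 0, 0.1, log = TRUE), `+`))
  total <- sum(dens) * dx^2 * sum(dnorm(gz, 0, 0.4)) * dz
  expect_equal(total, 1, tolerance = 1e-3)
})

test_that("emission term reduces to the exponential density at shape one", {
  cam <- ref_camera
  beta <- cam$quantum_efficiency
  scl <- 2 * cam$gain / cam$conversion
  u <- matrix(2 / beta, 1, 1)     # shape = beta u / 2 = 1
  for (w in c(5, 200, 9500)) {
    expect_equal(as.numeric(log_emission(matrix(w, 1, 1), u, cam)),
                 log(1 / scl) - w / scl, tolerance = 1e-12)
  }
})

test_that("emission term matches the special-function Gamma oracle to 1e-8", {
  cam <- ref_camera
  beta <- cam$quantum_efficiency
  scl <- 2 * cam$gain / cam$conversion
  # the spec's reference point
  expect_equal(as.numeric(log_emission(matrix(9500, 1, 1),
                                       matrix(100, 1, 1), cam)),
               dgamma(9500, shape = beta * 100 / 2, scale = scl,
                      log = TRUE), tolerance = 1e-8)
  # 100-point grid over (shape, scale, w) via varying (u, w, G)
  set.seed(99)
  us <- runif(100, 0.5, 500)
  ws <- runif(100, 1, 5e4)
  for (i in seq_len(100)) {
    got <- as.numeric(log_emission(matrix(ws[i], 1, 1),
                                   matrix(us[i], 1, 1), cam))
    want <- dgamma(ws[i], shape = beta * us[i] / 2, scale = scl, log = TRUE)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("emission term clips tiny counts and rejects shape mismatches", {
  cam <- ref_camera
  ll <- log_emission(matrix(c(0, 5), 1, 2), matrix(c(10, 10), 1, 2), cam)
  expect_identical(attr(ll, "n_clipped"), 1L)
  expect_error(log_emission(matrix(0, 1, 1), matrix(0, 2, 1), cam),
               "shape")
  # degenerate pixel: u = 0 with w = 0 contributes nothing
  ll0 <- log_emission(matrix(c(0, 5), 1, 2), matrix(c(0, 10), 1, 2), cam)
  ll1 <- log_emission(matrix(5, 1, 1), matrix(10, 1, 1), cam)
  expect_equal(as.numeric(ll0), as.numeric(ll1), tolerance = 1e-12)
  expect_error(log_emission(matrix(1, 1, 1), matrix(0, 1, 1), cam),
               "zero expected signal")
})

test_that("BM motion term reproduces hand-evaluated step values", {
  g <- time_grid(2, 1, 0.033, 0.033)   # single step of dt = 0.033
  still <- trajectory(matrix(0, 2, 3), g, "BM")
  expect_equal(log_motion_bm(still, D = 1), -1.5 * log(4 * pi * 0.033),
               tolerance = 1e-12)
  expect_equal(log_motion_bm(still, D = 1), 1.3203, tolerance = 1e-4)
  # typical step |dR|^2 = 6 D dt: previous value minus 3/2
  step <- sqrt(6 * 1 * 0.033 / 3)
  typ <- trajectory(rbind(c(0, 0, 0), rep(step, 3)), g, "BM")
  expect_equal(log_motion_bm(typ, D = 1),
               -1.5 * log(4 * pi * 0.033) - 1.5, tolerance = 1e-12)
  expect_equal(log_motion_bm(typ, D = 1), -0.1797, tolerance = 5e-4)
  expect_error(log_motion_bm(still, D = 0), "'D'")
  g1 <- time_grid(1, 1)
  expect_error(log_motion_bm(trajectory(matrix(0, 1, 3), g1, "BM"), 1),
               "2 time points")
})

test_that("small diffusivity and lag make every step contribution positive", {
  dt <- 0.033 / 16
  g <- time_grid(2, 8, 0.033, 0.030)
  still <- trajectory(matrix(1, 16, 3), g, "BM")
  val <- log_motion_bm(still, D = 0.05)
  per_step <- 1.5 * log(1 / (4 * pi * 0.05 * sptaudit:::grid_dts(g)))
  expect_equal(val, sum(per_step), tolerance = 1e-12)
  expect_true(all(per_step > 0))
})

test_that("alternative motion likelihoods reduce to the BM term", {
  g <- small_grid(5, 4)
  tr <- simulate_bm(c(0, 0, 0), g, D = 1, seed = 51)
  expect_equal(log_motion_alt(tr, "DBM", list(D = 1, v = c(0, 0, 0))),
               log_motion_bm(tr, 1), tolerance = 1e-10)
  # SBM at alpha = 1: D_alpha = 1/2, but over elapsed (not absolute) time;
  # grids share uniform-within-frame lags so the laws coincide
  expect_equal(log_motion_alt(tr, "SBM", list(alpha = 1)),
               log_motion_bm(tr, 0.5), tolerance = 1e-10)
  g20 <- time_grid(20, 1, 0.033, 0.030)
  tr20 <- simulate_bm(c(0, 0, 0), g20, D = 1, seed = 52)
  expect_equal(log_motion_alt(tr20, "FBM", list(hurst = 0.5, D = 1)),
               log_motion_bm(tr20, 1), tolerance = 1e-6)
})

test_that("DBM alternative likelihood penalizes the drift correctly", {
  g <- small_grid(5, 4)
  tr <- simulate_dbm(c(0, 0, 0), g, D = 1, v = c(0.5, 0.5, 0), seed = 53)
  # oracle: independent per-step dnorm evaluation
  pos <- sptaudit:::traj_flat(tr)
  dts <- sptaudit:::grid_dts(tr$grid)
  want <- 0
  for (i in seq_along(dts)) {
    want <- want + sum(dnorm(pos[i + 1, ] - pos[i, ],
                             c(0.5, 0.5, 0) * dts[i],
                             sqrt(2 * dts[i]), log = TRUE))
  }
  expect_equal(log_motion_alt(tr, "DBM", list(D = 1, v = c(0.5, 0.5, 0))),
               want, tolerance = 1e-10)
})

test_that("motion term is maximized near the generating diffusivity", {
  g <- time_grid(400, 1, 0.033, 0.030)
  tr <- simulate_bm(c(0, 0, 0), g, D = 1, seed = 54)
  Ds <- exp(seq(log(0.2), log(5), length.out = 41))
  ll <- vapply(Ds, function(D) log_motion_bm(tr, D), numeric(1))
  expect_equal(Ds[which.max(ll)], 1, tolerance = 0.25)
})

test_that("decomposition is additive and its fraction follows the definition", {
  g <- small_grid(4, 4)
  tr <- sptaudit:::simulate_for_imaging("BM", g, ref_optics, ref_camera,
                                        list(D = 1), seed = 55)
  st <- render_stack(tr, ref_optics, ref_camera, ref_emission, seed = 56)
  d <- decompose(st, tr, ref_optics, ref_camera, ref_emission, D = 1)
  expect_equal(d$ln_total, d$ln_initial + d$ln_emission_pixels + d$ln_motion,
               tolerance = 1e-12)
  es <- d$ln_initial + d$ln_emission_pixels
  expect_equal(d$emission_fraction, abs(es) / (abs(es) + abs(d$ln_motion)),
               tolerance = 1e-12)
  expect_true(d$emission_fraction >= 0 && d$emission_fraction <= 1)
})

test_that("per-pixel emission log-likelihood approaches the Gamma entropy", {
  g <- small_grid(6, 4)
  tr <- sptaudit:::simulate_for_imaging("BM", g, ref_optics, ref_camera,
                                        list(D = 1), seed = 57)
  u <- expected_signal(tr, ref_optics, ref_camera, ref_emission)
  st <- emccd_sample(u, ref_camera, seed = 58)
  ll <- as.numeric(log_emission(st$w, u$u, ref_camera))
  shape <- ref_camera$quantum_efficiency * u$u / 2
  scl <- 2 * ref_camera$gain / ref_camera$conversion
  entropy <- shape + log(scl) + lgamma(shape) + (1 - shape) * digamma(shape)
  expect_equal(-ll / length(u$u), mean(entropy), tolerance = 0.02)
})
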