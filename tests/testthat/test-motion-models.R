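test_that("initial-position draws match the stated Gaussian", {
  p <- initial_position_prior(c(2.13, 2.13, 0), 0.1, 0.4)
  # near-degenerate widths collapse onto the mean
  p0 <- initial_position_prior(c(1, 2, 0), 1e-12, 1e-12)
  expect_equal(draw_initial_position(p0, seed = 1), c(1, 2, 0),
               tolerance = 1e-9)
  draws <- sptaudit:::with_rng_seed(11, {
    t(replicate(1e5, draw_initial_position(p)))
  })
  v <- apply(draws, 2, var)
  expect_equal(unname(v), c(0.01, 0.01, 0.16), tolerance = 0.05)
  se <- c(0.1, 0.1, 0.4) / sqrt(1e5)
  expect_true(all(abs(colMeans(draws) - p$mu) < 3 * se))
  expect_error(initial_position_prior(sigma_xy = -1), "sigma_xy")
  expect_error(initial_position_prior(mu = c(0, 0, 1)), "axial")
})

test_that("BM increments have the Wiener second moment and Gaussian shape", {
  g <- small_grid()
  expect_error(simulate_bm(c(0, 0, 0), g, D = 0), "'D'")
  expect_error(simulate_bm(c(0, 0, 0), g, D = -1), "'D'")
  # D -> 0 limit: constant path
  tr <- simulate_bm(c(1, 2, 0), g, D = 1e-30, seed = 1)
  expect_equal(max(abs(sweep(sptaudit:::traj_flat(tr), 2, c(1, 2, 0)))),
               0, tolerance = 1e-12)
  # 1e4 independent steps of dt = 0.033 from one long K = 1 path
  gl <- time_grid(10001, 1, 0.033, 0.033)
  tr <- simulate_bm(c(0, 0, 0), gl, D = 1, seed = 2)
  inc <- diff(sptaudit:::traj_flat(tr))
  expect_equal(mean(rowSums(inc^2)), 6 * 1 * 0.033, tolerance = 0.02)
  z <- inc / sqrt(2 * 1 * 0.033)
  skew <- mean(z^3)
  exkurt <- mean(z^4) - 3
  expect_lt(abs(skew), 4 * sqrt(6 / length(z)))
  expect_lt(abs(exkurt), 4 * sqrt(24 / length(z)))
})

test_that("DBM reduces exactly to BM at v = 0 and drifts as v * dt", {
  g <- small_grid()
  bm <- simulate_bm(c(0, 0, 0), g, D = 1, seed = 7)
  dbm <- simulate_dbm(c(0, 0, 0), g, D = 1, v = c(0, 0, 0), seed = 7)
  expect_identical(bm$positions, dbm$positions)
  gl <- time_grid(10001, 1, 0.033, 0.033)
  tr <- simulate_dbm(c(0, 0, 0), gl, D = 1, v = c(1, 1, 0), seed = 3)
  inc <- diff(sptaudit:::traj_flat(tr))
  se <- sqrt(2 * 1 * 0.033 / nrow(inc))
  expect_true(all(abs(colMeans(inc) - c(0.033, 0.033, 0)) < 3 * se))
  # drawn drift is always azimuthal (zero z component)
  for (s in 1:5) {
    tr <- simulate_dbm(c(0, 0, 0), g, D = 1, seed = s)
    expect_identical(tr$params$v[3], 0)
    expect_true(tr$params$v[1] > 0 && tr$params$v[1] <= 1)
  }
})

test_that("ATTM sojourns obey the deterministic power-law mapping", {
  g <- small_grid()
  expect_error(simulate_attm(c(0, 0, 0), g, 0.8, 2.0), "gamma_exp")
  expect_error(simulate_attm(c(0, 0, 0), g, 0.8, 0.5), "gamma_exp")
  tr <- simulate_attm(c(0, 0, 0), g, 0.8, 1.0, seed = 4)
  pat <- tr$params$patches
  expect_true(nrow(pat) >= 1)
  expect_equal(pat$sojourn,
               pat$diffusivity^(-1.0) * g$frame_period, tolerance = 1e-12)
  expect_true(all(pat$diffusivity >= 1e-3 & pat$diffusivity <= 1))
})

test_that("ATTM with collapsed diffusivity support is single-D Brownian", {
  gl <- time_grid(2001, 1, 0.033, 0.033)
  tr <- simulate_attm(c(0, 0, 0), gl, 0.8, 1.0, d_min = 0.5, d_max = 0.5,
                      seed = 5)
  inc <- diff(sptaudit:::traj_flat(tr))
  expect_equal(pat <- unique(tr$params$patches$diffusivity), 0.5)
  expect_equal(mean(rowSums(inc^2)), 6 * 0.5 * 0.033, tolerance = 0.05)
})

test_that("CTRW waits are Pareto and a short window leaves the walker trapped", {
  g <- small_grid()
  expect_error(simulate_ctrw(c(0, 0, 0), g, alpha = 1.2), "alpha")
  # first waiting time exceeds the window -> constant at R1
  tr <- simulate_ctrw(c(1, 1, 0), g, alpha = 0.5, tau_min = 100, seed = 6)
  expect_true(all(sweep(sptaudit:::traj_flat(tr), 2, c(1, 1, 0)) == 0))
  # survival-function tail exponent of the waiting-time sampler
  waits <- sptaudit:::with_rng_seed(8, sptaudit:::draw_pareto(1e5, 0.5, 0.01))
  qs <- quantile(waits, c(0.5, 0.99))
  xs <- exp(seq(log(qs[1]), log(qs[2]), length.out = 30))
  surv <- vapply(xs, function(x) mean(waits > x), numeric(1))
  slope <- unname(coef(lm(log(surv) ~ log(xs)))[2])
  expect_equal(slope, -0.5, tolerance = 0.02)
})

test_that("CTRW jumps carry the stated Gaussian second moment", {
  # tau_min equal to the grid step guarantees at most one jump per
  # interval, so nonzero grid steps are exactly the jump draws
  gl <- time_grid(400, 1, 0.05, 0.05)
  tau0 <- 0.033
  jumps <- do.call(rbind, lapply(1:200, function(i) {
    tr <- simulate_ctrw(c(0, 0, 0), gl, alpha = 0.5, D = 1, tau0 = tau0,
                        tau_min = 0.05, seed = 400 + i)
    inc <- diff(sptaudit:::traj_flat(tr))
    inc[rowSums(inc^2) > 0, , drop = FALSE]
  }))
  expect_gt(nrow(jumps), 2000)
  expect_equal(mean(rowSums(jumps^2)), 6 * 1 * tau0, tolerance = 0.05)
})

test_that("fGn autocovariance formula has its stated special values", {
  expect_equal(sptaudit:::fgn_autocov(1:10, 0.5), rep(0, 10))
  expect_equal(sptaudit:::fgn_autocov(0:10, 1.0), rep(1, 11))
  expect_equal(sptaudit:::fgn_autocov(1, 0.7), 2^0.4 - 1)
})

test_that("Davies-Harte fGn matches analytic and Cholesky-oracle covariance", {
  L <- 32L
  hurst <- 0.7
  G <- outer(seq_len(L), seq_len(L),
             function(i, j) sptaudit:::fgn_autocov(abs(i - j), hurst))
  n <- 4000L
  dh <- sptaudit:::with_rng_seed(21, {
    t(vapply(seq_len(n), function(i) sptaudit:::davies_harte_fgn(L, hurst),
             numeric(L)))
  })
  ch <- sptaudit:::with_rng_seed(22, {
    R <- chol(G)
    matrix(rnorm(n * L), n, L) %*% R
  })
  se <- sqrt((outer(diag(G), diag(G)) + G^2) / n)
  expect_lt(max(abs(cov(dh) - G) / se), 5)
  expect_lt(max(abs(cov(ch) - G) / se), 5)
  # lag-1 increment correlation at H = 0.7 across 1e4 paths of length 64
  x <- sptaudit:::with_rng_seed(23, {
    t(vapply(1:1e4, function(i) sptaudit:::davies_harte_fgn(64L, hurst),
             numeric(64)))
  })
  r1 <- mean(x[, -64] * x[, -1])
  expect_equal(r1, 2^0.4 - 1, tolerance = 3 / sqrt(1e4 * 63) / (2^0.4 - 1))
})

test_that("FBM trajectories are fGn cumulative sums with the stated scale", {
  g <- small_grid()
  expect_error(simulate_fbm(c(0, 0, 0), g, hurst = 1.2), "hurst")
  # H = 0.5 reduces to BM statistically: increment variance = 2 D dt
  gl <- time_grid(2001, 1, 0.033, 0.033)
  tr <- simulate_fbm(c(0, 0, 0), gl, hurst = 0.5, D = 1, seed = 9)
  inc <- diff(sptaudit:::traj_flat(tr))
  expect_equal(mean(rowSums(inc^2)), 6 * 0.033, tolerance = 0.05)
  lag1 <- mean(inc[-nrow(inc), ] * inc[-1, ])
  expect_lt(abs(lag1) / (2 * 0.033 / sqrt(3 * nrow(inc))), 4)
})

test_that("LW flights are ballistic at constant speed", {
  g <- small_grid()
  expect_error(simulate_lw(c(0, 0, 0), g, sigma_exp = 2.5), "sigma_exp")
  # one flight spanning the window: straight line, |dR|/dt = speed exactly
  tr <- simulate_lw(c(0, 0, 0), g, sigma_exp = 0.5, speed = 2,
                    tau_min = 100, seed = 10)
  flat <- sptaudit:::traj_flat(tr)
  dts <- sptaudit:::grid_dts(g)
  sp <- sqrt(rowSums(diff(flat)^2)) / dts
  expect_equal(sp, rep(2, length(sp)), tolerance = 1e-9)
  # multi-flight paths never exceed the flight speed, wherever they start
  tr2 <- simulate_lw(c(2, 2, 0), g, sigma_exp = 1.5, speed = 2, seed = 13)
  v <- sqrt(rowSums(diff(sptaudit:::traj_flat(tr2))^2)) /
    sptaudit:::grid_dts(g)
  expect_lte(max(v), 2 + 1e-9)
})

test_that("SBM matches BM exactly at alpha = 1 and enforces its range", {
  g <- small_grid()
  sbm <- simulate_sbm(c(0, 0, 0), g, alpha = 1, seed = 11)
  bm <- simulate_bm(c(0, 0, 0), g, D = 0.5, seed = 11)
  expect_equal(sbm$positions, bm$positions, tolerance = 1e-12)
  expect_silent(simulate_sbm(c(0, 0, 0), g, alpha = 2, seed = 1))
  expect_error(simulate_sbm(c(0, 0, 0), g, alpha = 2.01), "alpha")
  expect_error(simulate_sbm(c(0, 0, 0), g, alpha = 0), "alpha")
})

test_that("SBM ensemble MSD follows its closed form", {
  gl <- time_grid(50, 1, 0.033, 0.033)
  trs <- simulate_ensemble(1000, simulate_sbm, c(0, 0, 0), gl, alpha = 0.5,
                           seed_offset = 3000L)
  m <- msd_curve(trs)
  d_alpha <- 1 / (2 * gamma(1.5))
  expected <- 6 * d_alpha * m$table$lag_s^0.5
  # each lag within 4 relative standard errors of the closed form
  rel_se <- sqrt(2 / 3) / sqrt(1000)
  expect_true(all(abs(m$table$msd_um2 / expected - 1) < 4 * rel_se * 2))
})

test_that("trajectories are reproducible bit-for-bit from (model, params, seed)", {
  g <- small_grid()
  for (m in motion_model_names()) {
    a <- simulate_trajectory(m, c(1, 1, 0), g,
                             sptaudit:::default_motion_params(m), seed = 31)
    b <- simulate_trajectory(m, c(1, 1, 0), g,
                             sptaudit:::default_motion_params(m), seed = 31)
    expect_identical(a$positions, b$positions, label = m)
  }
})

test_that("centre-and-rescale obeys its span contract", {
  g <- time_grid(10, 1, 0.033, 0.030)
  ext <- 32 * 0.133
  # straight 100 um diagonal line -> lateral span ext * (1 - 2 * margin)
  s <- seq(0, 100 / sqrt(2), length.out = 10)
  line <- trajectory(cbind(s, s, 0), g, "LW")
  out <- center_and_rescale(line, ext, margin = 0.1)
  flat <- sptaudit:::traj_flat(out)
  expect_equal(max(apply(flat[, 1:2], 2, function(v) diff(range(v)))),
               ext * 0.8, tolerance = 1e-9)
  expect_equal(colMeans(flat)[1:2], rep(ext / 2, 2), tolerance = 1e-9,
               ignore_attr = TRUE)
  # already-inside trajectory: pure translation (shape preserved)
  tr <- simulate_bm(c(0, 0, 0), g, D = 0.1, seed = 12)
  out <- center_and_rescale(tr, ext, margin = 0.1)
  expect_equal(diff(sptaudit:::traj_flat(out)),
               diff(sptaudit:::traj_flat(tr)), tolerance = 1e-9)
  # constant trajectory -> constant at the ROI centre
  const <- trajectory(matrix(rep(c(9, 9, 0), each = 10), 10, 3), g, "BM")
  out <- center_and_rescale(const, ext)
  expect_equal(sptaudit:::traj_flat(out),
               matrix(rep(c(ext / 2, ext / 2, 0), each = 10), 10, 3),
               tolerance = 1e-9)
  expect_error(center_and_rescale(tr, ext, margin = 0.6), "margin")
})

test_that("Brownian-limit parameterizations match BM increment moments", {
  gl <- time_grid(1501, 1, 0.033, 0.033)
  ref_var <- 2 * 1 * 0.033
  lim <- list(
    fbm = simulate_fbm(c(0, 0, 0), gl, hurst = 0.5, D = 1, seed = 41),
    attm = simulate_attm(c(0, 0, 0), gl, 0.8, 1.0, d_min = 1, d_max = 1,
                         seed = 42))
  for (nm in names(lim)) {
    inc <- diff(sptaudit:::traj_flat(lim[[nm]]))
    expect_equal(mean(inc^2), ref_var, tolerance = 0.06, label = nm)
    expect_lt(abs(mean(inc)), 4 * sqrt(ref_var / length(inc)))
  }
})
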