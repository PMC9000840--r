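test_that("msd matches closed forms on deterministic motion", {
  # ballistic: msd(tau) = (v tau)^2
  co <- array(0, c(21, 1, 3)); co[, 1, 1] <- 0.1 * (0:20)
  tr <- trajectory(co, 0:20, box(1000))
  m <- msd(tr, lag_grid = c(2, 5, 10))
  expect_equal(m$msd, (0.1 * m$lag)^2, tolerance = 1e-12)

  # stationary particles
  co2 <- array(1, c(10, 3, 3))
  expect_true(all(msd(trajectory(co2, 0:9, box(10)))$msd == 0))

  # 3-frame hand case averaged over sliding origins
  co3 <- array(0, c(3, 1, 3)); co3[, 1, 1] <- c(0, 0.3, 0.4)
  m3 <- msd(trajectory(co3, 0:2, box(100)), lag_grid = c(1, 2))
  expect_equal(m3$msd, c(0.05, 0.16))
})

test_that("msd equals the brute-force all-origins computation", {
  g <- brownian_trajectory(5, 40, 1.5, seed = 21)
  lags <- c(1, 3, 7, 12, 20)
  m <- msd(g$unwrapped, lag_grid = lags)
  expect_equal(m$msd, brute_msd(g$unwrapped$coords, lags),
               tolerance = 1e-12)
})

test_that("wrapped trajectories are refused by the jump heuristic", {
  g <- brownian_trajectory(50, 300, 5, box = box(1), seed = 4)
  expect_error(msd(g$wrapped), "unwrap")
})

test_that("diffusion_pbc inverts exact Einstein lines and clamps noise artefacts", {
  lag <- 1:50
  ms <- data.frame(lag = lag, msd = 6 * (2.0 / 1000) * lag)
  expect_equal(diffusion_pbc(ms)$D_pbc, 2.0, tolerance = 1e-9)

  # stationary: zero slope
  ms0 <- data.frame(lag = lag, msd = rep(0, 50))
  expect_equal(diffusion_pbc(ms0)$D_pbc, 0)

  # decreasing msd: clamp with a warning, not an error
  msn <- data.frame(lag = lag, msd = -0.01 * lag)
  expect_warning(est <- diffusion_pbc(msn), "negative")
  expect_equal(est$D_pbc, 0)
  expect_true(est$negative_slope)

  expect_error(diffusion_pbc(ms, fit_window = c(0.48, 0.5)), "5 lag points")
})

test_that("Brownian ground truth is recovered across a diffusion grid", {
  for (D in c(0.5, 2)) {
    g <- brownian_trajectory(400, 600, D, seed = 100 + round(10 * D))
    est <- diffusion_pbc(msd(g$unwrapped))
    expect_lt(abs(est$D_pbc / D - 1), 0.1)
  }
})

test_that("periodic-image diffusion correction follows the closed form", {
  # huge viscosity: correction vanishes
  expect_equal(yeh_hummer_correction(1.0, 298.15, 1e9, 4), 1.0,
               tolerance = 1e-9)
  # hand-evaluated correction at water-like viscosity
  expect_equal(yeh_hummer_correction(0, 298.15, 0.31, 4), 0.50,
               tolerance = 1e-2)
  # exact 1/L scaling
  c4 <- yeh_hummer_correction(0, 300, 1, 4)
  c8 <- yeh_hummer_correction(0, 300, 1, 8)
  expect_equal(c4 / c8, 2, tolerance = 1e-12)
  expect_error(yeh_hummer_correction(1, 300, 0, 4), "eta")
  expect_error(yeh_hummer_correction(1, 300, 1, -1), "L")
})

test_that("solute-size correction reduces to the point-particle form and shrinks with R", {
  expect_equal(solute_size_correction(0.3, 300, 1, 6, 0),
               yeh_hummer_correction(0.3, 300, 1, 6), tolerance = 1e-12)
  # bracket value for a 1.87 nm solute in a 6 nm box
  base <- crowd_constants$kB * 298.15 /
    (6 * pi * 1e-3 * 6e-9) * 1e9
  got <- solute_size_correction(0, 298.15, 1, 6, 1.87)
  expect_equal(got / base, 2.4304, tolerance = 1e-4)
  # monotone decreasing in R
  rs <- seq(0, 2.9, by = 0.4)
  vals <- vapply(rs, function(r) solute_size_correction(0, 300, 1, 6, r),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(solute_size_correction(0, 300, 1, 6, 3), "L/2")
})

test_that("hard-sphere decline ratio matches brute-force evaluation and is monotone", {
  phis <- seq(0, 0.99, length.out = 100)
  expect_equal(enskog_ratio(phis), (1 - phis)^3 / (1 - 0.5 * phis),
               tolerance = 1e-15)
  expect_identical(enskog_ratio(0), 1)
  expect_equal(enskog_ratio(0.4), 0.27, tolerance = 1e-12)
  expect_true(all(diff(enskog_ratio(phis)) < 0))
  expect_error(enskog_ratio(1), "phi")
  expect_error(enskog_ratio(-0.1), "phi")
})

test_that("normalization maps the reference to one and is idempotent", {
  conc <- c(0, 35); vals <- c(6.13, 3.0)
  norm <- normalize_series(conc, vals, 0)
  expect_equal(norm, c(1, 0.489), tolerance = 1e-3)
  expect_identical(norm[1], 1)
  expect_equal(normalize_series(conc, norm, 0), norm)
  expect_identical(normalize_series(5, 42, 5), 1)
  expect_error(normalize_series(conc, vals, 10), "reference")
  expect_error(normalize_series(conc, c(0, 1), 0), "nonzero")
})

test_that("exponential decline fit recovers constructed and noisy rates", {
  cgrid <- seq(0, 100, by = 10)
  fit <- exponential_decline_fit(cgrid, exp(-0.02 * cgrid))
  expect_equal(fit$k, 0.02, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  expect_warning(flat <- exponential_decline_fit(cgrid, rep(1, 11)),
                 "constant")
  expect_identical(flat$k, 0)
  expect_identical(flat$r_squared, 0)

  set.seed(31)
  c10 <- seq(5, 95, by = 10)
  y <- exp(-0.05 * c10) * (1 + stats::rnorm(10, 0, 0.01))
  expect_lt(abs(exponential_decline_fit(c10, y)$k - 0.05), 0.005)

  expect_error(exponential_decline_fit(c(0, 1), c(1, 0.9)), "3 points")
  expect_error(exponential_decline_fit(cgrid, rep(-1, 11)), "positive")
})

test_that("block statistics follow the contiguous-equal-blocks rule", {
  b <- block_statistics(rep(7, 25), 5)
  expect_equal(b$mean, 7); expect_equal(b$sd, 0)

  b2 <- block_statistics(c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5), 5)
  expect_equal(b2$block_means, 1:5 + 0)
  expect_equal(b2$mean, 3)
  expect_equal(b2$sd, sqrt(2.5), tolerance = 1e-12)

  # remainder dropped from the end
  b3 <- block_statistics(1:11, 5)
  expect_equal(b3$block_means, c(1.5, 3.5, 5.5, 7.5, 9.5))

  expect_error(block_statistics(1:3, 5), "shorter")
})
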