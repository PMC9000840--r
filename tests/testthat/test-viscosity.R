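test_that("velocity-profile amplitudes recover exact cosine fields", {
  g <- cosine_flow_trajectory(10000, 1.0, seed = 3)
  prof <- bin_velocity_profile(g$trajectory, 20)
  # atom-level fit is exact on noiseless data
  expect_equal(prof$amplitude_lsq, g$metadata$V_amplitude,
               tolerance = 1e-12)
  # binned cosine projection agrees within its discretisation error
  expect_lt(abs(prof$amplitude - g$metadata$V_amplitude), 1e-3)
})

test_that("cosine projection is orthogonal to a uniform drift", {
  g <- cosine_flow_trajectory(10000, 1.0, seed = 13)
  drifted <- g$trajectory
  drifted$velocities[, , 1] <- drifted$velocities[, , 1] + 0.5
  p0 <- bin_velocity_profile(g$trajectory, 20)
  p1 <- bin_velocity_profile(drifted, 20)
  expect_equal(p1$amplitude, p0$amplitude, tolerance = 1e-12)
})

test_that("zero velocities give a zero amplitude and no viscosity", {
  g <- cosine_flow_trajectory(500, 1.0, seed = 2)
  tr <- g$trajectory
  tr$velocities[] <- 0
  prof <- bin_velocity_profile(tr, 10)
  expect_equal(prof$amplitude, 0)
  expect_error(periodic_perturbation_viscosity(prof, density = 1),
               "amplitude")
})

test_that("periodic-perturbation viscosity matches the hand-evaluated response", {
  # rho = 1 g/mL, A = 0.05 nm/ps^2, l_z = 4 nm, v = 20.265 m/s -> 1 mPa*s
  prof <- structure(list(amplitude_lsq = 20.265 / 1000,
                         amplitude = 20.265 / 1000,
                         amplitude_se = NA_real_, l_z = 4),
                    class = "crowd_velocity_profile")
  est <- periodic_perturbation_viscosity(prof, density = 1.0)
  expect_equal(est$eta, 1.00, tolerance = 1e-3)

  # halving the response doubles the viscosity exactly
  prof2 <- prof; prof2$amplitude_lsq <- prof$amplitude_lsq / 2
  est2 <- periodic_perturbation_viscosity(prof2, density = 1.0)
  expect_equal(est2$eta / est$eta, 2, tolerance = 1e-12)
})

test_that("generator inversion: viscosity recovered exactly without noise, within 2% at 10% noise", {
  g <- cosine_flow_trajectory(10000, 1.0, seed = 3)
  est <- periodic_perturbation_viscosity(bin_velocity_profile(g$trajectory, 20),
                                         density = 1.0)
  expect_lt(abs(est$eta - 1.0), 1e-6)

  gn <- cosine_flow_trajectory(10000, 1.0, noise_sd = 0.10, seed = 4)
  en <- periodic_perturbation_viscosity(bin_velocity_profile(gn$trajectory, 20),
                                        density = 1.0)
  expect_lt(abs(en$eta - 1.0), 0.02)
})

test_that("periodic-perturbation estimator is exact over random parameter triples", {
  set.seed(77)
  for (i in 1:5) {
    rho <- stats::runif(1, 0.5, 2)
    A <- stats::runif(1, 0.01, 0.2)
    lz <- stats::runif(1, 3, 8)
    eta <- stats::runif(1, 0.2, 5)
    g <- cosine_flow_trajectory(2000, eta, amplitude = A, density = rho,
                                box = box(4, 4, lz), seed = 1000 + i)
    est <- periodic_perturbation_viscosity(
      bin_velocity_profile(g$trajectory, 16), density = rho,
      spec = perturbation_spec(A, lz))
    expect_lt(abs(est$eta / eta - 1), 1e-9)
  }
})

test_that("cosine amplitudes scale inversely with the target viscosity", {
  a <- cosine_flow_trajectory(100, 0.31, seed = 5)$metadata$V_amplitude
  b <- cosine_flow_trajectory(100, 1.01, seed = 5)$metadata$V_amplitude
  expect_equal(a / b, 1.01 / 0.31, tolerance = 1e-12)
})

test_that("Einstein-Helfand viscosity vanishes for a silent pressure tensor", {
  quiet <- pressure_series(seq(0, 99.9, by = 0.1), matrix(0, 1000, 6),
                           64, 298.15)
  est <- einstein_helfand_viscosity(quiet, n_blocks = 0)
  expect_equal(est$eta, 0)
})

test_that("Einstein-Helfand recovers the closed-form viscosity of an exponentially correlated process", {
  o <- ou_pressure_series(200000, seed = 5)
  est <- einstein_helfand_viscosity(o$series)
  expect_lt(abs(est$eta / o$metadata$eta_closed_form - 1), 0.15)
  expect_true(is.finite(est$uncertainty))
  rep_ <- viscosity_convergence_report(est)
  expect_true(attr(rep_, "converged"))
})

test_that("Einstein-Helfand slope agrees with the brute-force Green-Kubo sum", {
  o <- ou_pressure_series(10000, seed = 1)
  est <- einstein_helfand_viscosity(o$series, max_lag_fraction = 0.02,
                                    origin_stride = 1L, n_blocks = 0)
  gk <- gk_brute_viscosity(o$series, 100)
  expect_lt(abs(est$eta / gk - 1), 0.05)
})

test_that("white-noise pressure matches the discrete-sum oracle within its tolerance", {
  o <- ou_pressure_series(10000, dt = 0.2, tau = 0.2, seed = 2)
  est <- einstein_helfand_viscosity(o$series, max_lag_fraction = 0.02,
                                    origin_stride = 1L, n_blocks = 0)
  gk <- gk_brute_viscosity(o$series, 50)
  expect_lt(abs(est$eta / gk - 1), 0.20)
})

test_that("the estimator is symmetric under permutations of the six components", {
  o <- ou_pressure_series(5000, seed = 9)
  est1 <- einstein_helfand_viscosity(o$series, n_blocks = 0)
  perm <- o$series
  perm$components <- perm$components[, c(4, 6, 2, 1, 3, 5)]
  est2 <- einstein_helfand_viscosity(perm, n_blocks = 0)
  expect_equal(est2$eta, est1$eta, tolerance = 1e-12)
})

test_that("convergence report flags drifting running estimates", {
  flat <- structure(list(eta = 1, convergence = data.frame(
    time = 1:100, eta_running = rep(1, 100))), class = "crowd_viscosity")
  rf <- viscosity_convergence_report(flat)
  expect_true(attr(rf, "converged"))
  expect_true(all(rf$rel_change[-1] == 0))

  rising <- structure(list(eta = 1, convergence = data.frame(
    time = 1:100, eta_running = seq(1, 3, length.out = 100))),
    class = "crowd_viscosity")
  rr <- viscosity_convergence_report(rising)
  expect_false(attr(rr, "converged"))
})
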