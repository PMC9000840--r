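#' Periodic-perturbation specification
#'
#' Parameters of the non-equilibrium cosine-acceleration experiment: an
#' acceleration field `a_x(z) = A cos(2 pi z / l_z)` applied along x with
#' one period across the box height.
#'
#' @param amplitude Acceleration amplitude `A` (nm/ps^2); default 0.05,
#'   the amplitude used in the solution study this package analyses.
#' @param l_z Box height (nm).
#' @return A list of class `"crowd_perturbation"`.
#' @export
perturbation_spec <- function(amplitude = 0.05, l_z) {
  if (amplitude <= 0) stop("amplitude must be positive")
  if (l_z <= 0) stop("l_z must be positive")
  structure(list(amplitude = amplitude, l_z = l_z),
            class = "crowd_perturbation")
}

#' Bin the steady velocity profile of a cosine shear flow
#'
#' Assigns atoms to z-bins by wrapped coordinate and computes the
#' mass-weighted mean x-velocity per bin. The cosine amplitude `v` is
#' extracted two ways: a mass-weighted least-squares fit of
#' `v cos(2 pi z / l_z)` at atom level (exact on noiseless cosine fields,
#' used by the viscosity estimator), and a discrete cosine projection
#' `v = 2/N_bins * sum v_x(z_c) cos(2 pi z_c / l_z)` over bin centres,
#' which is insensitive to a uniform drift by orthogonality and serves as
#' the cross-check. Empty bins are excluded with a warning.
#'
#' @param traj A [trajectory()] with velocities.
#' @param n_bins Number of z-bins (>= 4).
#' @return A list of class `"crowd_velocity_profile"`: `bin_centers`,
#'   `mean_velocity`, `counts`, `amplitude_lsq` (atom-level fit),
#'   `amplitude` (bin projection), `amplitude_se`, `l_z`.
#' @export
bin_velocity_profile <- function(traj, n_bins = 20L) {
  if (is.null(traj$velocities)) stop("trajectory has no velocities")
  if (n_bins < 4L) stop("need at least 4 bins")
  l_z <- traj$boxes[1, 3]
  masses <- if (is.null(traj$topology)) rep(1, n_atoms(traj)) else traj$topology$mass
  nf <- n_frames(traj)
  z <- as.vector(traj$coords[, , 3])
  vx <- as.vector(traj$velocities[, , 1])
  w <- rep(masses, each = nf)
  z <- z - l_z * floor(z / l_z)
  bin <- pmin(n_bins, 1L + floor(z / (l_z / n_bins)))
  wsum <- tapply(w, bin, sum)
  vsum <- tapply(w * vx, bin, sum)
  centers <- (seq_len(n_bins) - 0.5) * l_z / n_bins
  mean_v <- rep(NA_real_, n_bins)
  counts <- rep(0, n_bins)
  idx <- as.integer(names(wsum))
  counts[idx] <- as.vector(table(factor(bin, levels = seq_len(n_bins))))
  mean_v[idx] <- as.numeric(vsum / wsum)
  used <- which(counts > 0)
  if (length(used) < n_bins) {
    warning(sprintf("%d empty z-bin(s) excluded from the fit",
                    n_bins - length(used)))
  }
  cosz <- cos(2 * pi * centers / l_z)
  amplitude <- 2 / length(used) * sum(mean_v[used] * cosz[used])
  ca <- cos(2 * pi * z / l_z)
  fit <- stats::lm(vx ~ 0 + ca, weights = w)
  amplitude_lsq <- unname(stats::coef(fit))
  amplitude_se <- tryCatch(
    suppressWarnings(unname(summary(fit)$coefficients[1, "Std. Error"])),
    error = function(e) NA_real_)
  structure(list(bin_centers = centers, mean_velocity = mean_v,
                 counts = counts, amplitude = amplitude,
                 amplitude_lsq = amplitude_lsq,
                 amplitude_se = amplitude_se, l_z = l_z),
            class = "crowd_velocity_profile")
}

#' Shear viscosity from the periodic-perturbation method
#'
#' Inverts the steady-state response of a cosine acceleration field:
#' `eta = rho * A / v * (l_z / 2 pi)^2`, with `rho` the solution density,
#' `A` the acceleration amplitude, and `v` the fitted velocity-profile
#' amplitude.
#'
#' @param profile A [bin_velocity_profile()] result.
#' @param density Solution density (g/mL). When `NULL` and `topology` is
#'   supplied, computed from total mass over box volume.
#' @param spec A [perturbation_spec()]; defaults to amplitude 0.05 nm/ps^2
#'   with the profile's box height.
#' @param topology Optional topology for the density default.
#' @param box_volume Box volume (nm^3), needed only for the density
#'   default.
#' @return A list of class `"crowd_viscosity"` with `eta` (mPa*s),
#'   `uncertainty` (propagated from the profile fit), and
#'   `method = "periodic_perturbation"`.
#' @export
periodic_perturbation_viscosity <- function(profile, density = NULL,
                                            spec = NULL, topology = NULL,
                                            box_volume = NULL) {
  if (is.null(spec)) spec <- perturbation_spec(l_z = profile$l_z)
  if (is.null(density)) {
    if (is.null(topology) || is.null(box_volume)) {
      stop("supply density, or topology + box_volume to derive it")
    }
    mass_g <- sum(topology$mass) / crowd_constants$N_A
    density <- mass_g / (box_volume * crowd_constants$nm3_to_mL)
  }
  if (density <= 0) stop("density must be positive")
  v <- profile$amplitude_lsq
  if (!is.finite(v) || v <= 0) {
    stop("fitted velocity amplitude must be positive; ",
         "profile inconsistent with the cosine forcing")
  }
  rho_SI <- density * 1000                                   # kg/m^3
  A_SI <- spec$amplitude * crowd_constants$nm_to_m /
    crowd_constants$ps_to_s^2                                # m/s^2
  v_SI <- v * crowd_constants$nmps_to_ms                     # m/s
  lz_SI <- spec$l_z * crowd_constants$nm_to_m
  eta_Pa <- rho_SI * A_SI / v_SI * (lz_SI / (2 * pi))^2
  eta <- eta_Pa * 1e3                                        # mPa*s
  unc <- if (is.finite(profile$amplitude_se)) {
    eta * profile$amplitude_se / abs(profile$amplitude_lsq)
  } else NA_real_
  structure(list(eta = eta, uncertainty = unc,
                 method = "periodic_perturbation",
                 convergence = NULL),
            class = "crowd_viscosity")
}

#' @export
print.crowd_viscosity <- function(x, ...) {
  cat(sprintf("shear viscosity (%s): %.6g mPa*s%s\n", x$method, x$eta,
              if (is.finite(x$uncertainty))
                sprintf(" +/- %.3g", x$uncertainty) else ""))
  invisible(x)
}

#' Shear viscosity from the Einstein-Helfand relation
#'
#' Equilibrium estimator from the off-diagonal pressure tensor:
#' `eta = V/(2 kB T) * d/dt (1/6) sum_ij <[int_t0^{t0+t} P_ij dt']^2>`,
#' averaged over time origins. The running integral is a trapezoidal
#' cumulative sum; origins are taken at a configurable stride
#' (non-overlapping increments in the displacement sense); the limiting
#' slope is a least-squares fit over a late-time lag window. The running
#' estimator `V/(2 kB T) * H(t)/t` is recorded as the convergence series.
#'
#' @param series A [pressure_series()].
#' @param fit_window Fractions of the maximum lag delimiting the slope
#'   fit (default 0.2-0.8).
#' @param origin_stride Samples between successive time origins
#'   (default 10).
#' @param n_lags Number of lags in the grid (default 100).
#' @param max_lag_fraction Maximum lag as a fraction of the series length
#'   (default 0.01). Short relative to the span so that many effectively
#'   independent origins average each lag - the statistical error of the
#'   Helfand displacement grows roughly as sqrt(lag / span); the lag
#'   window must still sit far beyond the pressure correlation time.
#' @param n_blocks Blocks for the uncertainty estimate (default 5; 0
#'   disables it).
#' @return A `"crowd_viscosity"` list with `eta` (mPa*s), `uncertainty`
#'   (sd of block means, `NA` when disabled), `method`, and
#'   `convergence` (data.frame `time` ps, `eta_running` mPa*s).
#' @export
einstein_helfand_viscosity <- function(series, fit_window = c(0.2, 0.8),
                                       origin_stride = 10L, n_lags = 100L,
                                       max_lag_fraction = 0.01,
                                       n_blocks = 5L) {
  n <- length(series$times)
  if (n < 100L) stop("need at least 100 pressure samples")
  hel <- helfand_curve(series, origin_stride, n_lags, max_lag_fraction)
  scale <- helfand_prefactor(series)            # converts slope (Pa^2 s^2 / s) to Pa*s
  lag_s <- hel$lag * crowd_constants$ps_to_s
  lag_max <- max(hel$lag)
  sel <- hel$lag >= fit_window[1] * lag_max & hel$lag <= fit_window[2] * lag_max
  if (sum(sel) < 5L) stop("fewer than 5 lag points inside the fit window")
  fit <- stats::lm(hel$H[sel] ~ lag_s[sel])
  slope <- unname(stats::coef(fit)[2])
  eta <- scale * slope * 1e3                    # Pa*s -> mPa*s
  conv <- data.frame(time = hel$lag,
                     eta_running = scale * hel$H / lag_s * 1e3)
  unc <- NA_real_
  if (n_blocks > 0L) {
    bs <- floor(n / n_blocks)
    if (bs >= 100L) {
      etas <- vapply(seq_len(n_blocks), function(b) {
        idx <- ((b - 1L) * bs + 1L):(b * bs)
        sub <- pressure_series(series$times[idx],
                               series$components[idx, , drop = FALSE],
                               series$volume, series$temperature)
        h <- helfand_curve(sub, origin_stride, n_lags, max_lag_fraction)
        lmax <- max(h$lag)
        s <- h$lag >= fit_window[1] * lmax & h$lag <= fit_window[2] * lmax
        f <- stats::lm(h$H[s] ~ I(h$lag[s] * crowd_constants$ps_to_s))
        scale * unname(stats::coef(f)[2]) * 1e3
      }, numeric(1))
      unc <- stats::sd(etas)
    }
  }
  structure(list(eta = eta, uncertainty = unc,
                 method = "einstein_helfand", convergence = conv),
            class = "crowd_viscosity")
}

#' @keywords internal
helfand_prefactor <- function(series) {
  V_m3 <- series$volume * crowd_constants$nm_to_m^3
  V_m3 / (2 * crowd_constants$kB * series$temperature)
}

#' @keywords internal
#' Mean-squared Helfand displacement H(lag) = (1/6) sum_components
#' <(C(t0+lag)-C(t0))^2> over origins; C is the trapezoidal cumulative
#' integral of P (Pa) over time (s).
helfand_curve <- function(series, origin_stride, n_lags, max_lag_fraction) {
  n <- length(series$times)
  t_s <- series$times * crowd_constants$ps_to_s
  P <- series$components * crowd_constants$bar_to_Pa
  dt <- diff(t_s)
  C <- apply(P, 2, function(p) {
    c(0, cumsum((p[-1] + p[-n]) / 2 * dt))
  })
  max_lag <- max(5L, floor(n * max_lag_fraction))
  lags <- unique(round(seq(1L, max_lag, length.out = min(n_lags, max_lag))))
  H <- numeric(length(lags))
  for (k in seq_along(lags)) {
    l <- lags[k]
    origins <- seq(1L, n - l, by = origin_stride)
    d <- C[origins + l, , drop = FALSE] - C[origins, , drop = FALSE]
    H[k] <- sum(d * d) / (6 * length(origins))
  }
  list(lag = lags * (series$times[2] - series$times[1]), H = H)
}

#' Convergence report for a viscosity estimate
#'
#' Tabulates the running viscosity against the accumulated lag window and
#' flags non-convergence when the estimate still drifts by more than a
#' threshold across the tail of the series.
#'
#' @param estimate A `"crowd_viscosity"` with a convergence series.
#' @param threshold Relative tail change flagged as non-converged
#'   (default 0.10).
#' @param tail_fraction Fraction of the window treated as the tail
#'   (default 0.2).
#' @return A data.frame with columns `window_end`, `eta`, `rel_change`,
#'   plus attribute `converged` (logical).
#' @export
viscosity_convergence_report <- function(estimate, threshold = 0.10,
                                         tail_fraction = 0.2) {
  conv <- estimate$convergence
  if (is.null(conv)) stop("estimate has no convergence series")
  eta <- conv$eta_running
  rel_change <- c(NA_real_, abs(diff(eta)) / pmax(abs(eta[-length(eta)]), .Machine$double.eps))
  i0 <- max(1L, floor((1 - tail_fraction) * length(eta)))
  eta_end <- eta[length(eta)]
  drift <- if (eta_end == 0 && eta[i0] == 0) 0 else {
    abs(eta_end - eta[i0]) / max(abs(eta_end), .Machine$double.eps)
  }
  out <- data.frame(window_end = conv$time, eta = eta,
                    rel_change = rel_change)
  attr(out, "converged") <- drift <= threshold
  attr(out, "tail_drift") <- drift
  out
}
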