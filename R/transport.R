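#' Mean-squared displacement with full time-origin averaging
#'
#' Computes the MSD of a set of diffusing sites from an unwrapped
#' trajectory, averaging over every sliding time origin at each lag.
#' Multi-atom molecules diffuse as their mass-weighted centre of mass:
#' pass `groups` (from [molecule_groups()]) to collapse atoms to molecular
#' sites first.
#'
#' @param traj An unwrapped [trajectory()] (equally spaced frames). A
#'   heuristic guards against wrapped input: any single-lag jump larger
#'   than half a box length raises an error advising [unwrap()].
#' @param lag_grid Lags in ps; defaults to up to 60 evenly spaced lags
#'   spanning half the trajectory.
#' @param groups Optional list of atom-index vectors defining molecules;
#'   `NULL` treats every atom as its own site.
#' @param origin_stride Use every `origin_stride`-th time origin
#'   (default 1 = all origins).
#' @return An object of class `"crowd_msd"`: data.frame with columns
#'   `lag` (ps) and `msd` (nm^2) plus attributes `n_particles` and
#'   `n_origins`.
#' @export
msd <- function(traj, lag_grid = NULL, groups = NULL, origin_stride = 1L) {
  nf <- n_frames(traj)
  if (nf < 2L) stop("need at least two frames")
  dt <- diff(traj$times)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
    stop("msd requires equally spaced frames")
  }
  dt <- dt[1]
  co <- if (is.null(groups)) traj$coords else com_coords(traj, groups)
  np <- dim(co)[2]
  if (np == 0L) stop("empty selection")
  # wrapped-input heuristic on raw sites
  half_min_box <- min(traj$boxes) / 2
  jump <- max(abs(co[-1L, , , drop = FALSE] - co[-nf, , , drop = FALSE]))
  if (nf > 1L && jump > half_min_box) {
    stop("single-step displacement exceeds half a box length; ",
         "trajectory looks wrapped - call unwrap() first")
  }
  if (is.null(lag_grid)) {
    max_lag_frames <- max(1L, floor((nf - 1L) / 2))
    lag_frames <- unique(round(seq(1L, max_lag_frames,
                                   length.out = min(60L, max_lag_frames))))
  } else {
    lag_frames <- unique(round(sort(lag_grid) / dt))
    lag_frames <- lag_frames[lag_frames >= 1L & lag_frames <= nf - 1L]
    if (length(lag_frames) == 0L) stop("no lags inside the trajectory span")
  }
  ms <- numeric(length(lag_frames))
  n_orig <- integer(length(lag_frames))
  for (k in seq_along(lag_frames)) {
    l <- lag_frames[k]
    origins <- seq(1L, nf - l, by = origin_stride)
    d <- co[origins + l, , , drop = FALSE] - co[origins, , , drop = FALSE]
    ms[k] <- sum(d * d) / (length(origins) * np)
    n_orig[k] <- length(origins)
  }
  out <- data.frame(lag = lag_frames * dt, msd = ms)
  attr(out, "n_particles") <- np
  attr(out, "n_origins") <- n_orig
  class(out) <- c("crowd_msd", "data.frame")
  out
}

#' Diffusion constant under periodic boundary conditions
#'
#' Einstein relation: the long-time slope of the MSD is `6 D`. An
#' ordinary least-squares line (free intercept) is fitted to the MSD over
#' a lag window; `D_pbc = slope / 6`, reported in 1e-5 cm^2/s
#' (1 nm^2/ps = 1000 in those units).
#'
#' @param msd_series A [msd()] result.
#' @param fit_window Fractions of the maximum lag delimiting the fit
#'   window (default 0.1-0.5, skipping the short-time regime).
#' @return A list of class `"crowd_diffusion"`: `D_pbc` (1e-5 cm^2/s),
#'   `slope_se`-derived `uncertainty`, `fit_window` (ps), `n_points`.
#'   A negative fitted slope is clamped to `D_pbc = 0` with a warning.
#' @export
diffusion_pbc <- function(msd_series, fit_window = c(0.1, 0.5)) {
  stopifnot(length(fit_window) == 2L, fit_window[1] < fit_window[2])
  lag_max <- max(msd_series$lag)
  lo <- fit_window[1] * lag_max
  hi <- fit_window[2] * lag_max
  sel <- msd_series$lag >= lo & msd_series$lag <= hi
  if (sum(sel) < 5L) stop("need at least 5 lag points inside the fit window")
  fit <- stats::lm(msd ~ lag, data = msd_series[sel, ])
  slope <- unname(stats::coef(fit)["lag"])              # nm^2/ps
  se <- suppressWarnings(
    unname(summary(fit)$coefficients["lag", "Std. Error"]))
  conv <- crowd_constants$nm2ps_to_1e5cm2s
  flagged <- FALSE
  if (slope < 0) {
    warning("negative fitted MSD slope; clamping D_pbc to 0")
    slope <- 0
    flagged <- TRUE
  }
  structure(list(D_pbc = slope / 6 * conv,
                 uncertainty = se / 6 * conv,
                 fit_window = c(lo, hi), n_points = sum(sel),
                 negative_slope = flagged),
            class = "crowd_diffusion")
}

#' Finite-size (periodic-image) diffusion correction
#'
#' Adds the hydrodynamic self-interaction term `kB T xi / (6 pi eta L)`
#' (xi = 2.837297 for a cubic box) to a PBC diffusion constant, giving
#' the infinite-dilution estimate `D_0`.
#'
#' @param D_pbc Diffusion constant in 1e-5 cm^2/s.
#' @param temperature Temperature (K).
#' @param eta Shear viscosity (mPa*s).
#' @param L Box edge length (nm).
#' @return `D_0` in 1e-5 cm^2/s.
#' @examples
#' yeh_hummer_correction(0, 298.15, 0.31, 4)  # correction alone, ~0.50
#' @export
yeh_hummer_correction <- function(D_pbc, temperature, eta, L) {
  if (eta <= 0) stop("eta must be positive")
  if (L <= 0) stop("L must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  D_pbc + finite_size_term(temperature, eta, L, crowd_constants$xi_cubic)
}

#' Size-dependent finite-size correction for a large solute
#'
#' For a solute of hydrodynamic radius `R` comparable to the box, the
#' periodic-image correction acquires a size term:
#' `D_0 = D_pbc + kB T/(6 pi eta L) * (xi - 4 pi R^2 / (3 L^2))`.
#'
#' @inheritParams yeh_hummer_correction
#' @param R Solute hydrodynamic radius (nm); must satisfy `0 < R < L/2`.
#' @return `D_0` in 1e-5 cm^2/s.
#' @export
solute_size_correction <- function(D_pbc, temperature, eta, L, R) {
  if (eta <= 0) stop("eta must be positive")
  if (L <= 0) stop("L must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  if (R < 0) stop("R must be non-negative")
  if (R >= L / 2) stop("R must be smaller than L/2 for the correction to apply")
  bracket <- crowd_constants$xi_cubic - 4 * pi * R^2 / (3 * L^2)
  D_pbc + finite_size_term(temperature, eta, L, bracket)
}

#' @keywords internal
finite_size_term <- function(temperature, eta, L, bracket) {
  kB <- crowd_constants$kB
  eta_Pa <- eta * 1e-3
  L_m <- L * crowd_constants$nm_to_m
  term_m2s <- kB * temperature * bracket / (6 * pi * eta_Pa * L_m)
  term_m2s * 1e4 / 1e-5  # m^2/s -> 1e-5 cm^2/s
}

#' Enskog hard-sphere diffusion decline
#'
#' Ratio of the hard-sphere self-diffusion constant at crowder volume
#' fraction `phi` to its dilute-limit value:
#' `D_HS/D_HS0 = (1 - phi)^3 / (1 - 0.5 phi)`. Purely excluded-volume
#' reference against which simulated diffusion declines are compared.
#'
#' @param phi Volume fraction(s) in `[0, 1)`.
#' @return Ratio(s) in `(0, 1]`.
#' @examples
#' enskog_ratio(c(0, 0.4))  # 1 and 0.27
#' @export
enskog_ratio <- function(phi) {
  if (any(phi < 0 | phi >= 1)) stop("phi must lie in [0, 1)")
  (1 - phi)^3 / (1 - 0.5 * phi)
}

#' Normalize a concentration series to a reference point
#'
#' Divides every value by the value at the reference concentration so the
#' reference maps to exactly 1 (the convention used when comparing
#' diffusion declines across solvent models of very different absolute
#' diffusivity).
#'
#' @param concentrations Concentration grid.
#' @param values Values at those concentrations (positive at the
#'   reference).
#' @param reference Reference concentration; must be present in
#'   `concentrations`.
#' @return Numeric vector of normalized values.
#' @export
normalize_series <- function(concentrations, values, reference) {
  stopifnot(length(concentrations) == length(values))
  i <- which(concentrations == reference)
  if (length(i) != 1L) stop("reference concentration not found (exactly once) in series")
  if (!is.finite(values[i]) || values[i] == 0) {
    stop("value at the reference concentration must be nonzero")
  }
  values / values[i]
}

#' Exponential decline fit for normalized diffusion
#'
#' Fits `y = exp(-k c)` (constrained through (0, 1), the normalization
#' convention) to a normalized concentration series by nonlinear least
#' squares. R^2 is computed on the linear scale; for degenerate constant
#' data (`SS_tot = 0`) `k = 0` and `R^2 = 0` are reported with a warning.
#'
#' @param concentrations Concentration grid (>= 3 points).
#' @param values Positive normalized values.
#' @return A list with `k` (per concentration unit), `r_squared`, and
#'   `fitted` values.
#' @export
exponential_decline_fit <- function(concentrations, values) {
  if (length(concentrations) < 3L) stop("need at least 3 points")
  if (any(values <= 0)) stop("values must be positive")
  ss_tot <- sum((values - mean(values))^2)
  if (ss_tot == 0) {
    warning("constant series: reporting k = 0 and R^2 = 0")
    return(list(k = 0, r_squared = 0, fitted = values))
  }
  k0 <- -unname(stats::coef(stats::lm(log(values) ~ 0 + concentrations)))
  ss <- function(k) sum((values - exp(-k * concentrations))^2)
  opt <- stats::optimize(ss, interval = k0 + c(-1, 1) * (5 * abs(k0) + 1),
                         tol = 1e-12)
  if (!is.finite(opt$objective)) {
    stop("exponential fit did not converge (last iterate k = ",
         signif(opt$minimum, 6), ")")
  }
  k <- opt$minimum
  fitted <- exp(-k * concentrations)
  ss_res <- sum((values - fitted)^2)
  list(k = k, r_squared = 1 - ss_res / ss_tot, fitted = fitted)
}

#' Block-averaged mean and uncertainty
#'
#' Splits a series into `n_blocks` contiguous equal blocks (remainder
#' values at the end are dropped) and returns the mean of the block means
#' and their sample standard deviation, the standard uncertainty recipe
#' for correlated MD series.
#'
#' @param x Numeric series.
#' @param n_blocks Number of blocks (default 5).
#' @return A list with `mean`, `sd` (sd of block means), and
#'   `block_means`.
#' @export
block_statistics <- function(x, n_blocks = 5L) {
  n <- length(x)
  if (n < n_blocks) stop("series shorter than the number of blocks")
  bs <- floor(n / n_blocks)
  m <- matrix(x[seq_len(bs * n_blocks)], nrow = bs)
  bm <- colMeans(m)
  list(mean = mean(bm), sd = stats::sd(bm), block_means = bm)
}
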