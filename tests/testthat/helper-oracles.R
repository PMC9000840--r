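# Independent oracles used across the test files. Each is a deliberately
# naive implementation (brute-force loops, closed forms) kept separate
# from the package code paths it checks.

# O(n^2) all-origins MSD for a [frame, site, 3] coordinate array.
brute_msd <- function(co, lag_frames) {
  nf <- dim(co)[1]; np <- dim(co)[2]
  vapply(lag_frames, function(l) {
    tot <- 0; cnt <- 0
    for (t0 in seq_len(nf - l)) {
      for (p in seq_len(np)) {
        d <- co[t0 + l, p, ] - co[t0, p, ]
        tot <- tot + sum(d^2); cnt <- cnt + 1
      }
    }
    tot / cnt
  }, numeric(1))
}

# Quaternion-eigenvalue (Horn) minimum RMSD between two weighted point
# sets; independent of the SVD-based Kabsch route.
quaternion_rmsd <- function(X, Y, w = NULL) {
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  w <- w / sum(w)
  xc <- sweep(X, 2, colSums(X * w))
  yc <- sweep(Y, 2, colSums(Y * w))
  Sxx <- sum(w * xc[, 1] * yc[, 1]); Sxy <- sum(w * xc[, 1] * yc[, 2])
  Sxz <- sum(w * xc[, 1] * yc[, 3]); Syx <- sum(w * xc[, 2] * yc[, 1])
  Syy <- sum(w * xc[, 2] * yc[, 2]); Syz <- sum(w * xc[, 2] * yc[, 3])
  Szx <- sum(w * xc[, 3] * yc[, 1]); Szy <- sum(w * xc[, 3] * yc[, 2])
  Szz <- sum(w * xc[, 3] * yc[, 3])
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd0 <- sum(w * rowSums(xc^2)) + sum(w * rowSums(yc^2)) - 2 * lam
  sqrt(max(0, msd0))
}

# Brute-force discrete Green-Kubo viscosity (mPa*s) from a pressure
# series: trapezoid-weighted sum of the sample autocovariance.
gk_brute_viscosity <- function(series, max_lag) {
  P <- series$components * crowd_constants$bar_to_Pa
  n <- nrow(P)
  dt <- (series$times[2] - series$times[1]) * crowd_constants$ps_to_s
  acf_sum <- 0
  for (c6 in 1:6) {
    p <- P[, c6]
    ac <- vapply(0:max_lag, function(k) {
      mean(p[1:(n - k)] * p[(1 + k):n])
    }, numeric(1))
    acf_sum <- acf_sum + sum(ac * c(0.5, rep(1, max_lag))) * dt
  }
  series$volume * crowd_constants$nm_to_m^3 /
    (crowd_constants$kB * series$temperature) * acf_sum / 6 * 1e3
}

# Single-frame trajectory wrapper used by the observable tests.
one_frame_traj <- function(positions, topology, b) {
  trajectory(array(positions, c(1, nrow(positions), 3)),
             times = 0, boxes = b, topology = topology)
}

# Random proper rotation matrix.
random_proper_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Minimal donor-hydrogen-acceptor configuration at a given
# donor-acceptor distance (nm) and hydrogen-donor-acceptor angle (deg).
hb_fixture <- function(d_oa, angle_deg, L = 10) {
  ang <- angle_deg * pi / 180
  pos <- rbind(c(1, 1, 1),
               c(1 + 0.1 * cos(ang), 1 + 0.1 * sin(ang), 1),
               c(1 + d_oa, 1, 1))
  top <- atom_table(c("OW", "HW1", "OW"), rep("SOL", 3), c(1, 1, 2),
                    mass = c(15.999, 1.008, 15.999))
  one_frame_traj(pos, top, box(L))
}

# Two-site charge/LJ pair at separation r (nm) in a large box.
coulomb_pair <- function(q1 = 1, q2 = 1, r = 1, sigma = 0.3, eps = 0,
                         cutoff = 1.0) {
  top <- atom_table(c("NA", "NA"), c("NA", "NA"), c(1, 2), mass = 23,
                    charge = c(q1, q2), lj_sigma = sigma, lj_epsilon = eps)
  pos <- rbind(c(1, 1, 1), c(1 + r, 1, 1))
  tr <- one_frame_traj(pos, top, box(10))
  interaction_energy(tr, 1, 2, cutoff = cutoff, n_blocks = 0)$series
}

# Table of the printed eleven-row composition series used by the
# composition tests (concentration, v%, wt%, N_crowder, N_water).
printed_composition_table <- function() {
  data.frame(
    wv = c(0, 15, 25, 35, 45, 55, 65, 75, 85, 95, 112),
    v_pct = c(0, 13, 22, 31, 40, 49, 57, 66, 75, 84, 100),
    wt_pct = c(0, 14, 24, 33, 42, 51, 60, 69, 77, 86, 100),
    n_peg = c(0, 29, 49, 69, 89, 109, 128, 148, 168, 188, 222),
    n_water = c(2139, 1859, 1666, 1474, 1281, 1088, 905, 713, 520, 327, 0))
}
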