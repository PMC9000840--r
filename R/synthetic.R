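#' Brownian-particle trajectory with known diffusion constant
#'
#' Overdamped Brownian dynamics: per-axis Gaussian increments with
#' variance `2 D dt`, so the ensemble MSD is linear in lag from the first
#' step (no ballistic regime). Returns both the continuous (unwrapped)
#' trajectory and its wrapped image, with the ground-truth target
#' recorded in the metadata attribute.
#'
#' @param n_particles,n_steps Counts.
#' @param D_target Diffusion constant in 1e-5 cm^2/s.
#' @param dt Time step (ps), default 1.
#' @param box A [box()], default 4 nm cubic.
#' @param seed RNG seed (recorded in the metadata).
#' @return A list with `unwrapped` and `wrapped` trajectories and
#'   `metadata` (`D_target`, `seed`, `dt`).
#' @export
brownian_trajectory <- function(n_particles, n_steps, D_target, dt = 1,
                                box = crowdsolv::box(4), seed = 1L) {
  if (D_target < 0) stop("D_target must be non-negative")
  box <- as_box(box)
  set.seed(seed)
  D_nm2ps <- D_target / crowd_constants$nm2ps_to_1e5cm2s
  sdev <- sqrt(2 * D_nm2ps * dt)
  nf <- n_steps + 1L
  coords <- array(NA_real_, c(nf, n_particles, 3))
  for (ax in 1:3) {
    start <- stats::runif(n_particles, 0, box$lengths[ax])
    steps <- if (sdev > 0) {
      matrix(stats::rnorm(n_steps * n_particles, sd = sdev), n_steps)
    } else matrix(0, n_steps, n_particles)
    coords[, , ax] <- rbind(start, sweep(apply(steps, 2, cumsum), 2,
                                         start, "+"))
  }
  top <- atom_table(rep("P", n_particles), rep("SOL", n_particles),
                    seq_len(n_particles), mass = 18.015)
  traj <- trajectory(coords, times = (seq_len(nf) - 1) * dt, boxes = box,
                     topology = top)
  out <- list(unwrapped = traj, wrapped = wrap(traj),
              metadata = list(kind = "brownian", D_target = D_target,
                              seed = seed, dt = dt,
                              n_particles = n_particles,
                              n_steps = n_steps))
  out
}

#' Steady cosine shear flow with known viscosity
#'
#' Atoms uniform in the box carry x-velocities
#' `v_x = V cos(2 pi z / l_z) + noise`, with the amplitude `V` chosen as
#' the exact steady-state response of a fluid of viscosity `eta_target`
#' to a cosine acceleration of amplitude `A`:
#' `V = rho A (l_z/2 pi)^2 / eta_target`. Atom masses are set so the
#' system density equals `density`.
#'
#' @param n_atoms Atom count.
#' @param eta_target Viscosity (mPa*s).
#' @param amplitude Acceleration amplitude (nm/ps^2), default 0.05.
#' @param density Solution density (g/mL), default 1.0.
#' @param noise_sd Gaussian velocity noise, as a fraction of `V`
#'   (default 0).
#' @param n_frames Frames generated (identical positions, fresh noise),
#'   default 1.
#' @param box A [box()], default 4 nm cubic.
#' @param seed RNG seed.
#' @return A list with `trajectory` (with velocities) and `metadata`
#'   (including the exact amplitude `V_amplitude` in nm/ps).
#' @export
cosine_flow_trajectory <- function(n_atoms, eta_target, amplitude = 0.05,
                                   density = 1.0, noise_sd = 0,
                                   n_frames = 1L, box = crowdsolv::box(4),
                                   seed = 1L) {
  if (eta_target <= 0) stop("eta_target must be positive")
  box <- as_box(box)
  set.seed(seed)
  l_z <- box$lengths[3]
  rho_SI <- density * 1000
  A_SI <- amplitude * crowd_constants$nm_to_m / crowd_constants$ps_to_s^2
  lz_SI <- l_z * crowd_constants$nm_to_m
  V_SI <- rho_SI * A_SI * (lz_SI / (2 * pi))^2 / (eta_target * 1e-3)
  V_amp <- V_SI / crowd_constants$nmps_to_ms     # nm/ps
  pos <- cbind(stats::runif(n_atoms, 0, box$lengths[1]),
               stats::runif(n_atoms, 0, box$lengths[2]),
               stats::runif(n_atoms, 0, l_z))
  mass <- density * box$volume * crowd_constants$nm3_to_mL *
    crowd_constants$N_A / n_atoms
  coords <- array(NA_real_, c(n_frames, n_atoms, 3))
  vels <- array(0, c(n_frames, n_atoms, 3))
  for (i in seq_len(n_frames)) {
    coords[i, , ] <- pos
    noise <- if (noise_sd > 0) {
      stats::rnorm(n_atoms, sd = noise_sd * abs(V_amp))
    } else 0
    vels[i, , 1] <- V_amp * cos(2 * pi * pos[, 3] / l_z) + noise
  }
  top <- atom_table(rep("P", n_atoms), rep("SOL", n_atoms),
                    seq_len(n_atoms), mass = mass)
  traj <- trajectory(coords, times = seq_len(n_frames) - 1, boxes = box,
                     topology = top, velocities = vels)
  list(trajectory = traj,
       metadata = list(kind = "cosine_flow", eta_target = eta_target,
                       amplitude = amplitude, density = density,
                       V_amplitude = V_amp, noise_sd = noise_sd,
                       seed = seed))
}

#' Stationary stochastic pressure-tensor series with closed-form
#' viscosity
#'
#' Six independent Gaussian first-order autoregressive (discretised
#' Ornstein-Uhlenbeck) series with stationary standard deviation
#' `sigma_P` and correlation time `tau`. The Green-Kubo integral of the
#' exponential autocorrelation is closed-form, giving the ground-truth
#' viscosity `eta = V sigma_P^2 tau / (kB T)` recorded in the metadata.
#'
#' @param n_samples Sample count.
#' @param dt Sampling interval (ps); must not exceed `tau`.
#' @param sigma_P Stationary standard deviation (bar).
#' @param tau Correlation time (ps).
#' @param volume Box volume (nm^3).
#' @param temperature Temperature (K).
#' @param seed RNG seed.
#' @return A list with `series` (a [pressure_series()]) and `metadata`
#'   (including `eta_closed_form` in mPa*s).
#' @export
ou_pressure_series <- function(n_samples, dt = 0.2, sigma_P = 80,
                               tau = 2, volume = 64, temperature = 298.15,
                               seed = 1L) {
  if (sigma_P < 0) stop("sigma_P must be non-negative")
  if (tau < dt) stop("tau must be at least the sampling interval dt")
  set.seed(seed)
  phi <- exp(-dt / tau)
  innov_sd <- sigma_P * sqrt(1 - phi^2)
  P <- matrix(0, n_samples, 6)
  if (sigma_P > 0) {
    for (c6 in 1:6) {
      x1 <- stats::rnorm(1, sd = sigma_P)
      eps <- stats::rnorm(n_samples - 1, sd = innov_sd)
      P[, c6] <- c(x1, as.numeric(
        stats::filter(eps, phi, method = "recursive", init = x1)))
    }
  }
  eta_Pa <- volume * crowd_constants$nm_to_m^3 *
    (sigma_P * crowd_constants$bar_to_Pa)^2 *
    tau * crowd_constants$ps_to_s /
    (crowd_constants$kB * temperature)
  list(series = pressure_series((seq_len(n_samples) - 1) * dt, P,
                                volume, temperature),
       metadata = list(kind = "ou_pressure", sigma_P = sigma_P, tau = tau,
                       dt = dt, volume = volume,
                       temperature = temperature,
                       eta_closed_form = eta_Pa * 1e3, seed = seed))
}

#' Toy solvated configuration for structural observables
#'
#' Builds a mixed configuration with known bookkeeping: a compact cluster
#' of protein beads whose charges straddle the 0.2 e hydrophobicity
#' threshold, three-site waters with conventional partial charges
#' (O -0.834 e, H +0.417 e), and 15-bead PEG-4 chains (8 C, 5 O, 2
#' hydroxyl H) with small charges on carbons and larger ones on the
#' hydroxyl group. Molecules are inserted by rejection sampling with a
#' minimum inter-molecular site distance.
#'
#' @param n_water,n_peg Molecule counts.
#' @param n_protein_beads Protein bead count (0 for none).
#' @param box A [box()], default 4 nm cubic.
#' @param seed RNG seed.
#' @param min_dist Minimum inter-molecular site distance (nm), default
#'   0.15.
#' @param max_attempts Insertion attempts per molecule before giving up.
#' @return A list with `topology`, `frame`, and `metadata`.
#' @export
toy_solution <- function(n_water, n_peg = 0L, n_protein_beads = 0L,
                         box = crowdsolv::box(4), seed = 1L,
                         min_dist = 0.15, max_attempts = 2000L) {
  box <- as_box(box)
  set.seed(seed)
  L <- box$lengths
  placed <- matrix(0, 0, 3)
  name <- resn <- character(0)
  resi <- integer(0)
  mass <- charge <- sig <- eps <- numeric(0)
  res_counter <- 0L

  too_close <- function(pts) {
    if (nrow(placed) == 0L) return(FALSE)
    for (k in seq_len(nrow(pts))) {
      if (any(min_image_dist_vec(placed, pts[k, ], L) < min_dist)) {
        return(TRUE)
      }
    }
    FALSE
  }
  add_mol <- function(pts, nm, rn, ms, q, s, e) {
    res_counter <<- res_counter + 1L
    placed <<- rbind(placed, pts)
    name <<- c(name, nm); resn <<- c(resn, rep(rn, length(nm)))
    resi <<- c(resi, rep(res_counter, length(nm)))
    mass <<- c(mass, ms); charge <<- c(charge, q)
    sig <<- c(sig, s); eps <<- c(eps, e)
  }

  if (n_protein_beads > 0L) {
    # compact cluster on a jittered cubic lattice at the box centre
    side <- ceiling(n_protein_beads^(1 / 3))
    g <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                               z = seq_len(side)))[seq_len(n_protein_beads), , drop = FALSE]
    pts <- (g - (side + 1) / 2) * 0.35 +
      matrix(L / 2, n_protein_beads, 3, byrow = TRUE) +
      matrix(stats::runif(3 * n_protein_beads, -0.03, 0.03),
             n_protein_beads)
    elements <- rep(c("C", "N", "O", "S"), length.out = n_protein_beads)
    charges <- rep(c(0.10, -0.45, 0.45, -0.10), length.out = n_protein_beads)
    add_mol(pts, elements, "PRO",
            unname(element_masses[elements]), charges,
            rep(0.34, n_protein_beads), rep(0.40, n_protein_beads))
  }

  water_geom <- function(center) {
    # rigid 3-site water: O-H 0.09572 nm, H-O-H 104.52 deg, random
    # orientation
    b <- 0.09572; half <- 104.52 / 2 * pi / 180
    local_h <- rbind(c(sin(half), 0, cos(half)) * b,
                     c(-sin(half), 0, cos(half)) * b)
    R <- random_rotation()
    rbind(center, sweep(local_h %*% t(R), 2, center, "+"))
  }
  for (i in seq_len(n_water)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      ctr <- stats::runif(3) * L
      pts <- water_geom(ctr)
      if (!too_close(pts)) { ok <- TRUE; break }
    }
    if (!ok) stop("failed to place water molecule ", i,
                  " after ", max_attempts, " attempts; use a larger box")
    add_mol(pts, c("OW", "HW1", "HW2"), "SOL",
            c(15.999, 1.008, 1.008), c(-0.834, 0.417, 0.417),
            c(0.315, 0.04, 0.04), c(0.636, 0.0, 0.0))
  }

  peg_geom <- function() {
    # 15-site chain: HO-C-C-O-C-C-O-C-C-O-C-C-O? pattern below; bond
    # 0.15 nm self-avoiding random walk in local frame
    n_sites <- 13L   # 8 C + 5 O backbone
    pts <- matrix(0, n_sites, 3)
    for (k in 2:n_sites) {
      repeat {
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        cand <- pts[k - 1, ] + 0.15 * dir
        if (k < 3 || min(sqrt(rowSums(sweep(pts[1:(k - 2), , drop = FALSE],
                                            2, cand)^2))) > 0.13) break
      }
      pts[k, ] <- cand
    }
    pts
  }
  for (i in seq_len(n_peg)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      ctr <- stats::runif(3) * L
      backbone <- sweep(peg_geom(), 2, ctr, "+")
      # hydroxyl hydrogens on the two terminal oxygens
      h1 <- backbone[1, ] + c(0.098, 0, 0)
      h2 <- backbone[13, ] + c(-0.098, 0, 0)
      pts <- rbind(backbone, h1, h2)
      if (!too_close(pts)) { ok <- TRUE; break }
    }
    if (!ok) stop("failed to place PEG-4 molecule ", i,
                  " after ", max_attempts, " attempts; use a larger box")
    # backbone order: O C C O C C O C C O C C O (terminal O at 1 and 13)
    bb_el <- c("O", rep(c("C", "C", "O"), 4))
    bb_nm <- paste0(bb_el, seq_along(bb_el))
    bb_q <- ifelse(bb_el == "O", -0.15, 0.10)
    bb_q[c(1, 13)] <- -0.60
    add_mol(pts, c(bb_nm, "HO1", "HO2"), "PEG",
            c(unname(element_masses[bb_el]), 1.008, 1.008),
            c(bb_q, 0.40, 0.40),
            c(ifelse(bb_el == "O", 0.30, 0.34), 0.05, 0.05),
            c(ifelse(bb_el == "O", 0.65, 0.45), 0.10, 0.10))
  }

  top <- atom_table(name, resn, resi, mass = mass, charge = charge,
                    lj_sigma = sig, lj_epsilon = eps)
  list(topology = top, frame = frame(placed, box),
       metadata = list(kind = "toy_solution", n_water = n_water,
                       n_peg = n_peg, n_protein_beads = n_protein_beads,
                       seed = seed, min_dist = min_dist))
}

#' @keywords internal
random_rotation <- function() {
  # uniform random rotation via QR of a Gaussian matrix
  M <- matrix(stats::rnorm(9), 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
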