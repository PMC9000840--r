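#' Group-group nonbonded interaction energy
#'
#' Pairwise Coulomb and Lennard-Jones energies between two disjoint atom
#' groups within a plain distance cutoff under minimum-image periodicity:
#' `E_coul = f q_i q_j / r` with `f = 138.935458 kJ mol^-1 nm e^-2`, and
#' `E_vdw = 4 eps_ij [(sig_ij/r)^12 - (sig_ij/r)^6]` with
#' Lorentz-Berthelot combination rules. No reciprocal-space (Ewald) term
#' is included, so against engine energies computed with full
#' electrostatics only trends are comparable.
#'
#' @param traj A [trajectory()] (or a [frame()] plus `topology`).
#' @param group_a,group_b Disjoint integer vectors of 1-based atom
#'   indices.
#' @param cutoff Distance cutoff (nm), default 1.0.
#' @param topology Needed when `traj` is a frame.
#' @param n_blocks Blocks for the uncertainty (default 5; 0 disables).
#' @return A list with per-frame data.frame `series` (columns `coulomb`,
#'   `vdw`, `total`, kJ/mol) and block statistics `mean`/`sd` for the
#'   total.
#' @export
interaction_energy <- function(traj, group_a, group_b, cutoff = 1.0,
                               topology = NULL, n_blocks = 5L) {
  if (inherits(traj, "crowd_frame")) {
    if (is.null(topology)) stop("topology required with a single frame")
    traj <- trajectory(array(traj$positions, c(1, nrow(traj$positions), 3)),
                       times = traj$time, boxes = traj$box,
                       topology = topology)
  }
  top <- traj$topology
  if (is.null(top)) stop("trajectory needs a topology")
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("groups must be disjoint")
  }
  qa <- top$charge[group_a]; qb <- top$charge[group_b]
  sa <- top$lj_sigma[group_a]; sb <- top$lj_sigma[group_b]
  ea <- top$lj_epsilon[group_a]; eb <- top$lj_epsilon[group_b]
  need_lj <- unique(c(group_a[is.na(sa) | is.na(ea)],
                      group_b[is.na(sb) | is.na(eb)]))
  if (length(need_lj) > 0L) {
    stop("missing Lennard-Jones parameters for atom(s): ",
         paste(top$name[need_lj], collapse = ", "))
  }
  f <- crowd_constants$f_coulomb
  qq <- outer(qa, qb)
  sig <- outer(sa, sb, function(x, y) (x + y) / 2)
  eps <- sqrt(outer(ea, eb))
  nf <- n_frames(traj)
  coul <- vdw <- numeric(nf)
  for (i in seq_len(nf)) {
    L <- traj$boxes[i, ]
    d2 <- 0
    for (ax in 1:3) {
      dx <- abs(outer(traj$coords[i, group_a, ax],
                      traj$coords[i, group_b, ax], "-"))
      dx <- pmin(dx, L[ax] - dx)
      d2 <- d2 + dx * dx
    }
    r <- sqrt(d2)
    inside <- r <= cutoff
    if (!any(inside)) next
    ri <- r[inside]
    coul[i] <- sum(f * qq[inside] / ri)
    sr6 <- (sig[inside] / ri)^6
    vdw[i] <- sum(4 * eps[inside] * (sr6^2 - sr6))
  }
  series <- data.frame(coulomb = coul, vdw = vdw, total = coul + vdw)
  sd_ <- NA_real_
  if (n_blocks > 0L && nf >= n_blocks) {
    sd_ <- block_statistics(series$total, n_blocks)$sd
  }
  list(series = series, mean = mean(series$total), sd = sd_)
}
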