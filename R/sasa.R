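#' Van der Waals radii (Bondi) in nm
#'
#' @return Named numeric vector of element radii.
#' @export
vdw_radii_bondi <- function() {
  c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180, P = 0.180,
    F = 0.147, CL = 0.175, `NA` = 0.227, K = 0.275)
}

#' @keywords internal
#' Deterministic quasi-uniform points on the unit sphere (golden-spiral
#' construction).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the van der Waals surface by testing, for
#' each atom, quasi-uniform points on its probe-inflated sphere against
#' the inflated spheres of its neighbours. The per-atom accessible area
#' is `(exposed points / total points) * 4 pi (r_i + probe)^2`. The total
#' is decomposed by partial charge: atoms with `|q| < charge_threshold`
#' count as hydrophobic, the rest as hydrophilic.
#'
#' @param fr A [frame()] (periodicity is not applied; supply a compact,
#'   whole molecule).
#' @param topology Topology table for the frame.
#' @param atoms Atom indices to include (default: protein atoms, or all
#'   atoms when no protein is present).
#' @param probe Probe radius (nm), default 0.14 (water).
#' @param n_sphere_points Test points per atom, default 960.
#' @param radii Named element-radius map (nm); default [vdw_radii_bondi()].
#'   Unknown elements are an error.
#' @param charge_threshold Hydrophobic |charge| threshold (e), default
#'   0.2.
#' @return A list of class `"crowd_sasa"`: `total`, `hydrophilic`,
#'   `hydrophobic` (nm^2), `per_atom` (nm^2), `atoms`.
#' @export
sasa <- function(fr, topology, atoms = NULL, probe = 0.14,
                 n_sphere_points = 960L, radii = vdw_radii_bondi(),
                 charge_threshold = 0.2) {
  if (is.null(atoms)) {
    atoms <- which(topology$molecule_class == "protein")
    if (length(atoms) == 0L) atoms <- seq_len(nrow(topology))
  }
  el <- element_from_name(topology$name[atoms])
  r_atom <- unname(radii[el])
  if (anyNA(r_atom)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(el[is.na(r_atom)]), collapse = ", "))
  }
  pos <- fr$positions[atoms, , drop = FALSE]
  R <- r_atom + probe
  pts <- sphere_points(n_sphere_points)
  n <- length(atoms)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    test <- pts * R[i] + matrix(pos[i, ], n_sphere_points, 3, byrow = TRUE)
    d_i <- sqrt(rowSums(sweep(pos, 2, pos[i, ])^2))
    nb <- which(d_i < R[i] + R & seq_len(n) != i)
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      dj2 <- (test[, 1] - pos[j, 1])^2 + (test[, 2] - pos[j, 2])^2 +
        (test[, 3] - pos[j, 3])^2
      exposed <- exposed & dj2 > R[j]^2
      if (!any(exposed)) break
    }
    per_atom[i] <- sum(exposed) / n_sphere_points * 4 * pi * R[i]^2
  }
  q <- topology$charge[atoms]
  hydrophobic <- sum(per_atom[abs(q) < charge_threshold])
  hydrophilic <- sum(per_atom[abs(q) >= charge_threshold])
  structure(list(total = sum(per_atom), hydrophilic = hydrophilic,
                 hydrophobic = hydrophobic, per_atom = per_atom,
                 atoms = atoms),
            class = "crowd_sasa")
}

#' @export
print.crowd_sasa <- function(x, ...) {
  cat(sprintf("SASA: total %.4f nm^2 (hydrophilic %.4f, hydrophobic %.4f)\n",
              x$total, x$hydrophilic, x$hydrophobic))
  invisible(x)
}
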