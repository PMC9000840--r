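#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the
#' (mass-)weighted squared deviation between a mobile and a reference
#' structure, via SVD of the weighted covariance with reflection
#' correction.
#'
#' @param reference,mobile `n x 3` coordinate matrices (nm), equal atom
#'   counts, `n >= 3`, non-collinear reference.
#' @param weights Non-negative weights (e.g. masses); default uniform.
#' @return A list of class `"crowd_superposition"`: `rotation` (3x3,
#'   `det = +1`), `translation` (applied after rotation), `rmsd` (nm),
#'   and `transformed` (mobile coordinates after superposition).
#' @export
kabsch_superpose <- function(reference, mobile, weights = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  n <- nrow(reference)
  if (n < 3L || nrow(mobile) != n) {
    stop("need equal atom counts >= 3 in reference and mobile")
  }
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  c_ref <- colSums(reference * w)
  c_mob <- colSums(mobile * w)
  X <- sweep(mobile, 2, c_mob)     # mobile, centred
  Y <- sweep(reference, 2, c_ref)  # reference, centred
  # collinearity check on the reference
  sv_ref <- svd(Y * sqrt(w))$d
  if (sv_ref[2] < 1e-10 * max(sv_ref[1], 1e-300)) {
    stop("reference structure is degenerate (collinear atoms)")
  }
  H <- t(X * w) %*% Y
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  transformed <- X %*% t(R) + matrix(c_ref, n, 3, byrow = TRUE)
  dev <- transformed - reference
  rmsd <- sqrt(sum(w * rowSums(dev^2)))
  structure(list(rotation = R, translation = c_ref - as.vector(R %*% c_mob),
                 rmsd = rmsd, transformed = transformed),
            class = "crowd_superposition")
}

#' Per-frame backbone RMSD series
#'
#' Superposes every frame of a trajectory onto a reference configuration
#' on a selection (default: protein backbone N/CA/C) and records the
#' mass-weighted RMSD.
#'
#' @param traj A [trajectory()] with a topology (unless `selection` and
#'   `weights` are given).
#' @param reference A [frame()] or `n x 3` matrix with the same atom
#'   count as the trajectory.
#' @param selection Integer atom indices; default [backbone_selection()]
#'   of the trajectory topology.
#' @param n_blocks Blocks for the equilibrated-window statistics
#'   (default 5; 0 disables).
#' @return Numeric vector of per-frame RMSD (nm) with attribute `blocks`
#'   (a [block_statistics()] result) when enabled.
#' @export
rmsd_series <- function(traj, reference, selection = NULL, n_blocks = 5L) {
  ref <- if (inherits(reference, "crowd_frame")) reference$positions else as.matrix(reference)
  if (is.null(selection)) {
    if (is.null(traj$topology)) stop("selection required when trajectory has no topology")
    selection <- backbone_selection(traj$topology)
  }
  if (length(selection) == 0L) stop("empty selection")
  w <- if (is.null(traj$topology)) rep(1, length(selection)) else
    traj$topology$mass[selection]
  refs <- ref[selection, , drop = FALSE]
  out <- vapply(seq_len(n_frames(traj)), function(i) {
    kabsch_superpose(refs, traj$coords[i, selection, , drop = TRUE], w)$rmsd
  }, numeric(1))
  if (n_blocks > 0L && length(out) >= n_blocks) {
    attr(out, "blocks") <- block_statistics(out, n_blocks)
  }
  out
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed onto the time-average structure (one refinement
#' pass: superpose onto the first frame, average, re-superpose onto that
#' average, re-average); the per-atom RMSF about the refined mean is then
#' averaged (mass-weighted) within each residue of the selection.
#'
#' @param traj A [trajectory()] with >= 2 frames.
#' @param selection Integer atom indices; default protein backbone.
#' @param superpose Superpose frames before measuring (default `TRUE`).
#'   With `FALSE` fluctuations are measured in the lab frame.
#' @return A data.frame with `residue_index` and `rmsf` (nm); attribute
#'   `per_atom` carries the atomic values.
#' @export
rmsf <- function(traj, selection = NULL, superpose = TRUE) {
  if (n_frames(traj) < 2L) stop("need at least 2 frames")
  if (is.null(selection)) {
    if (is.null(traj$topology)) stop("selection required when trajectory has no topology")
    selection <- backbone_selection(traj$topology)
  }
  if (length(selection) == 0L) stop("empty selection")
  w <- if (is.null(traj$topology)) rep(1, length(selection)) else
    traj$topology$mass[selection]
  nf <- n_frames(traj)
  co <- traj$coords[, selection, , drop = FALSE]
  frames3 <- function(arr, i) {
    m <- arr[i, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 3)
    m
  }
  if (superpose) {
    ref <- frames3(co, 1)
    for (pass in 1:2) {
      aligned <- array(NA_real_, dim(co))
      for (i in seq_len(nf)) {
        aligned[i, , ] <- kabsch_superpose(ref, frames3(co, i), w)$transformed
      }
      ref <- apply(aligned, c(2, 3), mean)
      co <- aligned
    }
  }
  mean_pos <- apply(co, c(2, 3), mean)
  msf <- numeric(length(selection))
  for (i in seq_len(nf)) {
    d <- frames3(co, i) - mean_pos
    msf <- msf + rowSums(d^2)
  }
  per_atom <- sqrt(msf / nf)
  resid <- if (is.null(traj$topology)) rep(1L, length(selection)) else
    traj$topology$residue_index[selection]
  agg <- tapply(seq_along(per_atom), resid, function(ii) {
    sum(w[ii] * per_atom[ii]) / sum(w[ii])
  })
  out <- data.frame(residue_index = as.integer(names(agg)),
                    rmsf = as.numeric(agg))
  attr(out, "per_atom") <- per_atom
  out
}
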