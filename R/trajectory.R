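#' Trajectory and frame containers
#'
#' A trajectory stores coordinates as a dense `[frame, atom, xyz]` array in
#' nm together with frame times (ps), per-frame box lengths (nm), optional
#' velocities (nm/ps), and an optional topology table. A frame is a single
#' configuration with its box.
#'
#' @param coords Numeric array `n_frames x n_atoms x 3` (nm).
#' @param times Numeric vector of frame times (ps), strictly increasing.
#' @param boxes Either a single [box()] applied to all frames or an
#'   `n_frames x 3` matrix of box lengths (nm).
#' @param topology Optional topology table ([atom_table()]); its atom count
#'   must match the coordinate array.
#' @param velocities Optional array with the same shape as `coords` (nm/ps).
#' @return An object of class `"crowd_trajectory"`.
#' @export
trajectory <- function(coords, times, boxes, topology = NULL,
                       velocities = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("coords must be an n_frames x n_atoms x 3 array")
  }
  n_frames <- dim(coords)[1]
  n_atoms <- dim(coords)[2]
  if (length(times) != n_frames) stop("times length must equal frame count")
  if (n_frames > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (is_box(boxes)) {
    boxes <- matrix(boxes$lengths, nrow = n_frames, ncol = 3, byrow = TRUE)
  }
  boxes <- as.matrix(boxes)
  if (nrow(boxes) == 1L && n_frames > 1L) {
    boxes <- boxes[rep(1L, n_frames), , drop = FALSE]
  }
  if (nrow(boxes) != n_frames || ncol(boxes) != 3L) {
    stop("boxes must be a box or an n_frames x 3 matrix")
  }
  if (any(boxes <= 0)) stop("box lengths must be positive")
  if (!is.null(topology) && nrow(topology) != n_atoms) {
    stop(sprintf("topology has %d atoms but trajectory has %d",
                 nrow(topology), n_atoms))
  }
  if (!is.null(velocities) && !identical(dim(velocities), dim(coords))) {
    stop("velocities must have the same shape as coords")
  }
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  structure(list(coords = coords, times = as.numeric(times), boxes = boxes,
                 topology = topology, velocities = velocities),
            class = "crowd_trajectory")
}

#' @rdname trajectory
#' @param positions `n_atoms x 3` matrix (nm).
#' @param time Frame time (ps).
#' @param .box A [box()].
#' @export
frame <- function(positions, .box, time = 0, velocities = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an n x 3 matrix")
  if (any(!is.finite(positions))) stop("positions must be finite")
  structure(list(time = time, positions = positions,
                 velocities = velocities, box = as_box(.box)),
            class = "crowd_frame")
}

#' @export
print.crowd_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, t = %.6g..%.6g ps%s\n",
              n_frames(x), n_atoms(x), x$times[1], x$times[n_frames(x)],
              if (is.null(x$velocities)) "" else ", with velocities"))
  invisible(x)
}

#' @rdname trajectory
#' @param traj A trajectory.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' Extract one frame from a trajectory
#'
#' @param traj A trajectory.
#' @param i Frame index (1-based).
#' @return A `"crowd_frame"`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  frame(traj$coords[i, , , drop = TRUE],
        box(traj$boxes[i, 1], traj$boxes[i, 2], traj$boxes[i, 3]),
        time = traj$times[i],
        velocities = if (is.null(traj$velocities)) NULL else
          traj$velocities[i, , , drop = TRUE])
}

#' Build a trajectory from a list of frames
#'
#' @param frames List of `"crowd_frame"` objects with a constant atom count.
#' @param topology Optional topology table.
#' @export
trajectory_from_frames <- function(frames, topology = NULL) {
  n <- length(frames)
  if (n == 0L) stop("no frames")
  na <- nrow(frames[[1]]$positions)
  coords <- array(NA_real_, c(n, na, 3))
  boxes <- matrix(NA_real_, n, 3)
  times <- numeric(n)
  has_vel <- !is.null(frames[[1]]$velocities)
  velocities <- if (has_vel) array(NA_real_, c(n, na, 3)) else NULL
  for (i in seq_len(n)) {
    f <- frames[[i]]
    if (nrow(f$positions) != na) {
      stop(sprintf("frame %d has %d atoms, expected %d", i,
                   nrow(f$positions), na))
    }
    coords[i, , ] <- f$positions
    boxes[i, ] <- f$box$lengths
    times[i] <- f$time
    if (has_vel) velocities[i, , ] <- f$velocities
  }
  trajectory(coords, times, boxes, topology, velocities)
}

#' Wrap coordinates into the primary box
#'
#' Maps every coordinate into `[0, L)` per axis using the frame's box.
#'
#' @param traj A trajectory.
#' @return A trajectory with wrapped coordinates.
#' @export
wrap <- function(traj) {
  co <- traj$coords
  for (ax in 1:3) {
    L <- traj$boxes[, ax]
    co[, , ax] <- co[, , ax] - L * floor(co[, , ax] / L)
  }
  traj$coords <- co
  traj
}

#' Unwrap periodic trajectories
#'
#' Reconstructs continuous coordinates from wrapped ones by accumulating
#' minimum-image displacements between consecutive frames. The first frame
#' is unchanged. Requires sampling fine enough that no atom moves half a
#' box length between frames; ambiguous displacements (at or beyond L/2
#' after minimum-imaging) trigger a warning naming the atom and frame.
#'
#' @param traj A trajectory (typically wrapped).
#' @return A trajectory with continuous coordinates.
#' @export
unwrap <- function(traj) {
  co <- traj$coords
  nf <- n_frames(traj)
  if (nf < 2L) return(traj)
  out <- co
  for (ax in 1:3) {
    x <- co[, , ax, drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = nf)
    L <- traj$boxes[, ax]
    d <- x[-1L, , drop = FALSE] - x[-nf, , drop = FALSE]
    Lm <- matrix(L[-1L], nrow = nf - 1L, ncol = ncol(x))
    d_mi <- d - Lm * round(d / Lm)
    amb <- abs(d_mi) >= Lm / 2 - 1e-12
    if (any(amb)) {
      idx <- which(amb, arr.ind = TRUE)[1, ]
      warning(sprintf(
        "ambiguous unwrap: atom %d moves >= L/2 between frames %d and %d on axis %d",
        idx[2], idx[1], idx[1] + 1L, ax))
    }
    out[, , ax] <- rbind(x[1L, , drop = FALSE],
                         matrix(x[1L, ], nrow = nf - 1L, ncol = ncol(x),
                                byrow = TRUE) +
                           apply(d_mi, 2, cumsum))
  }
  traj$coords <- out
  traj
}

#' Mass-weighted molecular centre-of-mass trajectory
#'
#' Collapses an (unwrapped) trajectory to one centre-of-mass site per
#' group. Groups default to the molecules of the topology.
#'
#' @param traj A trajectory with a topology (unless `groups` and `masses`
#'   are given).
#' @param groups List of integer vectors of 1-based atom indices.
#' @param masses Atom masses; defaults to the topology masses.
#' @return Array `n_frames x n_groups x 3`.
#' @export
com_coords <- function(traj, groups = NULL, masses = NULL) {
  if (is.null(groups)) {
    if (is.null(traj$topology)) stop("groups required when trajectory has no topology")
    groups <- split(seq_len(n_atoms(traj)), traj$topology$molecule_index)
  }
  if (is.null(masses)) {
    masses <- if (is.null(traj$topology)) rep(1, n_atoms(traj)) else traj$topology$mass
  }
  nf <- n_frames(traj)
  out <- array(NA_real_, c(nf, length(groups), 3))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    w <- masses[idx] / sum(masses[idx])
    for (ax in 1:3) {
      xs <- traj$coords[, idx, ax, drop = FALSE]
      dim(xs) <- c(nf, length(idx))
      out[, g, ax] <- xs %*% w
    }
  }
  out
}
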