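#' Geometric hydrogen-bond criteria
#'
#' A hydrogen bond is counted when the donor-acceptor distance does not
#' exceed `donor_acceptor_cutoff` and the hydrogen-donor-acceptor angle
#' does not exceed `angle_cutoff`. The defaults (0.35 nm, 30 degrees) are
#' the convention of the GROMACS hydrogen-bond tool.
#'
#' @param donor_acceptor_cutoff Distance cutoff (nm).
#' @param angle_cutoff Hydrogen-donor-acceptor angle cutoff (degrees).
#' @return A list of class `"crowd_hbond_criteria"`.
#' @export
hbond_criteria <- function(donor_acceptor_cutoff = 0.35, angle_cutoff = 30) {
  if (donor_acceptor_cutoff <= 0 || angle_cutoff <= 0) {
    stop("cutoffs must be positive")
  }
  structure(list(donor_acceptor_cutoff = donor_acceptor_cutoff,
                 angle_cutoff = angle_cutoff),
            class = "crowd_hbond_criteria")
}

#' @keywords internal
#' Donor table: one row per (donor heavy atom, attached hydrogen) pair.
#' Hydrogens are attached to the nearest N/O of the same residue within
#' 0.12 nm in the given configuration.
find_donors <- function(topology, positions, box_lengths) {
  el <- element_from_name(topology$name)
  h_idx <- which(el == "H")
  heavy <- which(el %in% c("N", "O"))
  if (length(h_idx) == 0L || length(heavy) == 0L) {
    return(data.frame(donor = integer(0), hydrogen = integer(0)))
  }
  donors <- integer(0); hydros <- integer(0)
  for (h in h_idx) {
    cand <- heavy[topology$residue_index[heavy] == topology$residue_index[h]]
    if (length(cand) == 0L) next
    d <- min_image_dist_vec(positions[cand, , drop = FALSE],
                            positions[h, ], box_lengths)
    j <- which.min(d)
    if (d[j] > 0.12) {
      stop(sprintf("hydrogen atom %d (%s, residue %d) has no bonded N/O donor within 0.12 nm",
                   h, topology$name[h], topology$residue_index[h]))
    }
    donors <- c(donors, cand[j]); hydros <- c(hydros, h)
  }
  data.frame(donor = donors, hydrogen = hydros)
}

#' @keywords internal
min_image_dist_vec <- function(mat, point, L) {
  d2 <- 0
  for (ax in 1:3) {
    dx <- abs(mat[, ax] - point[ax])
    dx <- pmin(dx, L[ax] - dx)
    d2 <- d2 + dx * dx
  }
  sqrt(d2)
}

#' @keywords internal
min_image_disp <- function(a, b, L) {
  # displacement b - a, minimum image, both plain 3-vectors
  d <- b - a
  d - L * round(d / L)
}

#' Count hydrogen bonds between molecular classes
#'
#' Counts geometric hydrogen bonds per frame between a donor class and an
#' acceptor class, using the distance + angle criterion of
#' [hbond_criteria()]. Donors are N/O atoms with an attached hydrogen
#' (resolved from geometry within each residue); acceptors are all N/O
#' atoms of the acceptor class. Both directions are counted for
#' inter-class pairs; for the intra-class pair each donor-acceptor atom
#' pair is considered once per attached hydrogen, excluding the donor
#' itself.
#'
#' @param traj A [trajectory()] (or a single [frame()] plus `topology`).
#' @param class_pair Length-2 character vector of molecule classes, e.g.
#'   `c("protein", "protein")`, `c("protein", "water")`,
#'   `c("protein", "peg4")`.
#' @param criteria A [hbond_criteria()].
#' @param topology Needed when `traj` is a frame.
#' @param n_blocks Blocks for the uncertainty (default 5; 0 disables).
#' @return A list with `counts` (per frame), `mean`, `sd` (block sd or
#'   `NA`).
#' @export
hydrogen_bonds <- function(traj, class_pair, criteria = hbond_criteria(),
                           topology = NULL, n_blocks = 5L) {
  if (inherits(traj, "crowd_frame")) {
    if (is.null(topology)) stop("topology required with a single frame")
    traj <- trajectory(array(traj$positions,
                             c(1, nrow(traj$positions), 3)),
                       times = traj$time, boxes = traj$box,
                       topology = topology)
  }
  top <- traj$topology
  if (is.null(top)) stop("trajectory needs a topology")
  stopifnot(length(class_pair) == 2L)
  el <- element_from_name(top$name)
  nf <- n_frames(traj)
  counts <- numeric(nf)
  cos_cut <- cos(criteria$angle_cutoff * pi / 180)
  for (i in seq_len(nf)) {
    pos <- traj$coords[i, , , drop = TRUE]
    if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3)
    L <- traj$boxes[i, ]
    dtab <- find_donors(top, pos, L)
    n_hb <- 0L
    directions <- if (class_pair[1] == class_pair[2]) {
      list(class_pair)
    } else {
      list(class_pair, rev(class_pair))
    }
    for (dir in directions) {
      dsel <- dtab[top$molecule_class[dtab$donor] == dir[1], , drop = FALSE]
      acc <- which(el %in% c("N", "O") & top$molecule_class == dir[2])
      if (nrow(dsel) == 0L || length(acc) == 0L) next
      for (r in seq_len(nrow(dsel))) {
        don <- dsel$donor[r]; hyd <- dsel$hydrogen[r]
        a_idx <- acc[acc != don]
        if (length(a_idx) == 0L) next
        dda <- min_image_dist_vec(pos[a_idx, , drop = FALSE], pos[don, ], L)
        ok <- which(dda <= criteria$donor_acceptor_cutoff)
        if (length(ok) == 0L) next
        vh <- min_image_disp(pos[don, ], pos[hyd, ], L)
        for (a in ok) {
          va <- min_image_disp(pos[don, ], pos[a_idx[a], ], L)
          cosang <- sum(vh * va) / sqrt(sum(vh^2) * sum(va^2))
          if (cosang >= cos_cut) n_hb <- n_hb + 1L
        }
      }
    }
    counts[i] <- n_hb
  }
  sd_ <- NA_real_
  if (n_blocks > 0L && nf >= n_blocks) {
    sd_ <- block_statistics(counts, n_blocks)$sd
  }
  list(counts = counts, mean = mean(counts), sd = sd_)
}
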