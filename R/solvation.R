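#' @keywords internal
#' Minimum-image distances from each row of `sites` to the nearest row of
#' `centers` under an orthorhombic box (lengths `L`).
min_dist_to_group <- function(sites, centers, L) {
  ns <- nrow(sites); nc <- nrow(centers)
  d2 <- matrix(0, ns, nc)
  for (ax in 1:3) {
    dx <- abs(outer(sites[, ax], centers[, ax], "-"))
    dx <- pmin(dx, L[ax] - dx)
    d2 <- d2 + dx * dx
  }
  sqrt(apply(d2, 1, min))
}

#' @keywords internal
#' Per-frame reference-site coordinates for a shell class: water is
#' represented by its oxygen atom, PEG-4 by its molecular centre of mass,
#' other classes by per-molecule centre of mass.
shell_site_coords <- function(traj, shell_class) {
  top <- traj$topology
  if (is.null(top)) stop("trajectory needs a topology to resolve shell sites")
  if (shell_class == "water") {
    idx <- which(top$molecule_class == "water" &
                   element_from_name(top$name) == "O")
    if (length(idx) == 0L) stop("no water oxygen atoms found")
    lapply(seq_len(n_frames(traj)), function(i) {
      m <- traj$coords[i, idx, , drop = TRUE]
      if (is.null(dim(m))) m <- matrix(m, ncol = 3)
      m
    })
  } else {
    groups <- molecule_groups(top, shell_class)
    if (length(groups) == 0L) {
      return(lapply(seq_len(n_frames(traj)), function(i) matrix(0, 0, 3)))
    }
    com <- com_coords(traj, groups)
    lapply(seq_len(n_frames(traj)), function(i) {
      m <- com[i, , , drop = TRUE]
      if (is.null(dim(m))) m <- matrix(m, ncol = 3)
      m
    })
  }
}

#' Non-normalized radial distribution function around a group
#'
#' Local number density `n(r)` of solvent reference sites (water oxygen,
#' crowder centre of mass) at minimum distance `r` from a centre group,
#' together with the cumulative count `N(<r)`. Unlike a conventional RDF
#' the density is not divided by the bulk value, so the large-`r` plateau
#' reads off the bulk number density directly (33.3 nm^-3 for pure
#' water).
#'
#' The distance convention is the minimum over centre-group atoms of the
#' minimum-image distance to the shell site.
#'
#' @param traj A [trajectory()] with topology.
#' @param shell_class `"water"` or `"peg4"`.
#' @param center_class Class whose atoms form the centre group
#'   (default `"protein"`).
#' @param center_coords Optional explicit `n x 3` matrix (or list of
#'   per-frame matrices) overriding `center_class` - e.g. a single point.
#' @param bin_width Bin width (nm).
#' @param r_max Maximum radius (nm); must not exceed half the smallest
#'   box length.
#' @return A data.frame of class `"crowd_rdf"` with `r_lo`, `r_hi`, `r`
#'   (bin centre), `density` (nm^-3), `cum_count`.
#' @export
density_rdf <- function(traj, shell_class, center_class = "protein",
                        center_coords = NULL, bin_width = 0.02,
                        r_max = NULL) {
  L <- traj$boxes[1, ]
  if (is.null(r_max)) r_max <- min(L) / 2
  if (r_max > min(L) / 2 + 1e-9) {
    stop("r_max exceeds half the smallest box length")
  }
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  nf <- n_frames(traj)
  centers_list <- resolve_centers(traj, center_class, center_coords, nf)
  sites_list <- shell_site_coords(traj, shell_class)
  for (i in seq_len(nf)) {
    sites <- sites_list[[i]]
    if (nrow(sites) == 0L) next
    d <- min_dist_to_group(sites, centers_list[[i]], traj$boxes[i, ])
    h <- graphics::hist(d[d < r_max], breaks = edges, plot = FALSE)
    counts <- counts + h$counts
  }
  counts <- counts / nf
  mid <- (edges[-1] + edges[-(nb + 1L)]) / 2
  vol <- 4 * pi * mid^2 * diff(edges)
  out <- data.frame(r_lo = edges[-(nb + 1L)], r_hi = edges[-1], r = mid,
                    density = counts / vol, cum_count = cumsum(counts))
  class(out) <- c("crowd_rdf", "data.frame")
  out
}

#' @keywords internal
resolve_centers <- function(traj, center_class, center_coords, nf) {
  if (!is.null(center_coords)) {
    if (is.list(center_coords)) return(center_coords)
    m <- as.matrix(center_coords)
    if (ncol(m) != 3L) m <- matrix(m, ncol = 3)
    return(rep(list(m), nf))
  }
  if (is.null(traj$topology)) stop("trajectory needs a topology to resolve the centre group")
  idx <- which(traj$topology$molecule_class == center_class)
  if (length(idx) == 0L) stop("no atoms of class ", center_class)
  lapply(seq_len(nf), function(i) {
    m <- traj$coords[i, idx, , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 3)
    m
  })
}

#' Coordination number within a shell radius
#'
#' Time-averaged number of shell molecules whose reference-site distance
#' to the centre group (same convention as [density_rdf()]) does not
#' exceed `radius`. The default radius is the 1.87 nm hydrodynamic radius
#' of lysozyme, defining its coordination shell.
#'
#' @inheritParams density_rdf
#' @param radius Shell radius (nm), default 1.87.
#' @param n_blocks Blocks for the uncertainty (default 5; 0 disables).
#' @return A list with `cn` (mean count), `sd` (block sd or `NA`), and
#'   `per_frame` counts.
#' @export
coordination_number <- function(traj, shell_class, center_class = "protein",
                                center_coords = NULL, radius = 1.87,
                                n_blocks = 5L) {
  if (radius < 0) stop("radius must be non-negative")
  nf <- n_frames(traj)
  centers_list <- resolve_centers(traj, center_class, center_coords, nf)
  sites_list <- shell_site_coords(traj, shell_class)
  per_frame <- vapply(seq_len(nf), function(i) {
    sites <- sites_list[[i]]
    if (nrow(sites) == 0L) return(0)
    d <- min_dist_to_group(sites, centers_list[[i]], traj$boxes[i, ])
    sum(d <= radius)
  }, numeric(1))
  sd_ <- NA_real_
  if (n_blocks > 0L && nf >= n_blocks) {
    sd_ <- block_statistics(per_frame, n_blocks)$sd
  }
  list(cn = mean(per_frame), sd = sd_, per_frame = per_frame)
}
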