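#' Read a trajectory file
#'
#' Reads an ordered multi-frame trajectory. The supported interchange
#' format is a plain-text frame format (`frames_text`): per frame, one
#' header line `natoms time Lx Ly Lz` followed by `natoms` lines
#' `x y z [vx vy vz]` (whitespace-delimited, nm and nm/ps). Binary XTC is
#' not decoded by this package; requesting it raises an informative error
#' so callers can convert to the text format first.
#'
#' @param path File path.
#' @param topology A topology table whose atom count must match the file.
#' @param format `"frames_text"` or `"xtc"`.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, topology,
                            format = c("frames_text", "xtc")) {
  format <- match.arg(format)
  if (format == "xtc") {
    stop("XTC decoding is not supported; convert the trajectory to the ",
         "frames_text format (header 'natoms time Lx Ly Lz' plus one ",
         "'x y z [vx vy vz]' line per atom) and re-read")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(hdr) < 5 || anyNA(hdr)) {
      stop(sprintf("%s: malformed frame header on line %d", path, i))
    }
    na <- as.integer(hdr[1])
    if (!is.null(topology) && na != nrow(topology)) {
      stop(sprintf("atom-count mismatch: trajectory frame has %d atoms, topology has %d",
                   na, nrow(topology)))
    }
    if (i + na > length(lines)) {
      stop(sprintf("%s: truncated frame starting at line %d", path, i))
    }
    block <- lines[(i + 1L):(i + na)]
    vals <- strsplit(trimws(block), "\\s+")
    ncols <- lengths(vals)
    if (!all(ncols %in% c(3L, 6L)) || length(unique(ncols)) != 1L) {
      bad <- which(!(ncols %in% c(3L, 6L)))[1]
      if (is.na(bad)) bad <- 1L
      stop(sprintf("%s: malformed coordinate line %d", path, i + bad))
    }
    m <- matrix(suppressWarnings(as.numeric(unlist(vals))),
                nrow = na, byrow = TRUE)
    if (anyNA(m)) stop(sprintf("%s: non-numeric coordinates in frame at line %d", path, i))
    frames[[length(frames) + 1L]] <- frame(
      m[, 1:3, drop = FALSE], box(hdr[3], hdr[4], hdr[5]), time = hdr[2],
      velocities = if (ncols[1] == 6L) m[, 4:6, drop = FALSE] else NULL)
    i <- i + na + 1L
  }
  trajectory_from_frames(frames, topology)
}

#' Write a trajectory in the plain-text frame format
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @param digits Significant digits written (default 10, well beyond the
#'   precision of any MD trajectory format).
#' @export
write_frames_text <- function(traj, path, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  has_vel <- !is.null(traj$velocities)
  for (i in seq_len(n_frames(traj))) {
    writeLines(paste(n_atoms(traj), fmt(traj$times[i]),
                     fmt(traj$boxes[i, 1]), fmt(traj$boxes[i, 2]),
                     fmt(traj$boxes[i, 3])), con)
    m <- traj$coords[i, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 3)
    if (has_vel) {
      v <- traj$velocities[i, , , drop = TRUE]
      if (is.null(dim(v))) v <- matrix(v, ncol = 3)
      m <- cbind(m, v)
    }
    writeLines(apply(m, 1, function(r) paste(fmt(r), collapse = " ")), con)
  }
  invisible(path)
}
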