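#' Read a coordinate file (GRO or PDB)
#'
#' Parses a single-configuration coordinate file into a topology table and
#' a frame. Coordinates are stored in nm (PDB Angstrom values are
#' converted). The box comes from the final GRO box line or the PDB CRYST1
#' record; only orthorhombic boxes are supported, and a missing box is an
#' error asking for an explicit override.
#'
#' @param path File path.
#' @param format `"gro"` or `"pdb"`; default guessed from the extension.
#' @param class_map Residue-class map, see [default_class_map()].
#' @param box_override Optional [box()] used when the file carries none.
#' @return A list with elements `topology` ([atom_table()]) and `frame`
#'   ([frame()]).
#' @export
read_configuration <- function(path, format = c("gro", "pdb"),
                               class_map = default_class_map(),
                               box_override = NULL) {
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gro", "pdb")) ext else "gro"
  }
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "gro") read_gro(lines, path, class_map, box_override)
  else read_pdb(lines, path, class_map, box_override)
}

#' @keywords internal
num_or_fail <- function(s, path, lineno, what) {
  x <- suppressWarnings(as.numeric(s))
  if (anyNA(x)) {
    stop(sprintf("%s: malformed %s on line %d", path, what, lineno))
  }
  x
}

#' @keywords internal
read_gro <- function(lines, path, class_map, box_override) {
  if (length(lines) < 3L) stop(path, ": truncated GRO file")
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms) || natoms < 1L) {
    stop(path, ": malformed atom count on line 2")
  }
  if (length(lines) < 2L + natoms) {
    stop(sprintf("%s: expected %d atom lines, found %d", path, natoms,
                 length(lines) - 2L))
  }
  al <- lines[3:(2 + natoms)]
  has_vel <- all(nchar(al) >= 68)
  resid <- integer(natoms); resnm <- character(natoms)
  atnm <- character(natoms)
  pos <- matrix(NA_real_, natoms, 3)
  vel <- if (has_vel) matrix(NA_real_, natoms, 3) else NULL
  for (i in seq_len(natoms)) {
    ln <- al[i]; lineno <- i + 2L
    if (nchar(ln) < 44) {
      stop(sprintf("%s: truncated coordinate line %d", path, lineno))
    }
    resid[i] <- as.integer(num_or_fail(substr(ln, 1, 5), path, lineno, "residue number"))
    resnm[i] <- trimws(substr(ln, 6, 10))
    atnm[i] <- trimws(substr(ln, 11, 15))
    pos[i, ] <- num_or_fail(c(substr(ln, 21, 28), substr(ln, 29, 36),
                              substr(ln, 37, 44)), path, lineno, "coordinate")
    if (has_vel) {
      vel[i, ] <- num_or_fail(c(substr(ln, 45, 52), substr(ln, 53, 60),
                                substr(ln, 61, 68)), path, lineno, "velocity")
    }
  }
  boxline <- trimws(lines[3L + natoms])
  if (is.na(boxline) || !nzchar(boxline)) {
    if (is.null(box_override)) {
      stop(path, ": no box line; supply box_override = box(...)")
    }
    b <- as_box(box_override)
  } else {
    v <- num_or_fail(strsplit(boxline, "\\s+")[[1]], path, 3L + natoms, "box")
    if (length(v) >= 9 && any(abs(v[4:9]) > 1e-9)) {
      stop(path, ": triclinic boxes are not supported")
    }
    b <- box(v[1], v[2], v[3])
  }
  top <- atom_table(atnm, resnm, resid, class_map = class_map)
  list(topology = top, frame = frame(pos, b, velocities = vel))
}

#' @keywords internal
read_pdb <- function(lines, path, class_map, box_override) {
  ang <- crowd_constants$ang_to_nm
  b <- NULL
  cr <- grep("^CRYST1", lines)
  if (length(cr) >= 1L) {
    ln <- lines[cr[1]]
    abc <- num_or_fail(c(substr(ln, 7, 15), substr(ln, 16, 24),
                         substr(ln, 25, 33)), path, cr[1], "CRYST1 length")
    angles <- num_or_fail(c(substr(ln, 34, 40), substr(ln, 41, 47),
                            substr(ln, 48, 54)), path, cr[1], "CRYST1 angle")
    if (any(abs(angles - 90) > 1e-6)) {
      stop(path, ": triclinic boxes are not supported (CRYST1 angles != 90)")
    }
    b <- box(abc[1] * ang, abc[2] * ang, abc[3] * ang)
  } else if (!is.null(box_override)) {
    b <- as_box(box_override)
  } else {
    stop(path, ": no CRYST1 record; supply box_override = box(...)")
  }
  at <- grep("^(ATOM  |HETATM)", lines)
  if (length(at) == 0L) stop(path, ": no ATOM/HETATM records")
  natoms <- length(at)
  resid <- integer(natoms); resnm <- character(natoms)
  atnm <- character(natoms)
  pos <- matrix(NA_real_, natoms, 3)
  for (i in seq_len(natoms)) {
    ln <- lines[at[i]]; lineno <- at[i]
    if (nchar(ln) < 54) {
      stop(sprintf("%s: truncated ATOM record on line %d", path, lineno))
    }
    atnm[i] <- trimws(substr(ln, 13, 16))
    resnm[i] <- trimws(substr(ln, 18, 21))
    resid[i] <- as.integer(num_or_fail(substr(ln, 23, 26), path, lineno,
                                       "residue number"))
    pos[i, ] <- num_or_fail(c(substr(ln, 31, 38), substr(ln, 39, 46),
                              substr(ln, 47, 54)), path, lineno,
                            "coordinate") * ang
  }
  top <- atom_table(atnm, resnm, resid, class_map = class_map)
  list(topology = top, frame = frame(pos, b))
}

#' Write a configuration as GRO or PDB
#'
#' @param topology A topology table.
#' @param fr A [frame()].
#' @param path Output path.
#' @param format `"gro"` or `"pdb"`.
#' @param title Title line.
#' @export
write_configuration <- function(topology, fr, path,
                                format = c("gro", "pdb"),
                                title = "written by crowdsolv") {
  format <- match.arg(format)
  n <- nrow(topology)
  stopifnot(nrow(fr$positions) == n)
  if (format == "gro") {
    has_vel <- !is.null(fr$velocities)
    body <- vapply(seq_len(n), function(i) {
      base <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                      topology$residue_index[i] %% 100000L,
                      substr(topology$residue_name[i], 1, 5),
                      substr(topology$name[i], 1, 5),
                      i %% 100000L,
                      fr$positions[i, 1], fr$positions[i, 2],
                      fr$positions[i, 3])
      if (has_vel) {
        base <- paste0(base, sprintf("%8.4f%8.4f%8.4f",
                                     fr$velocities[i, 1], fr$velocities[i, 2],
                                     fr$velocities[i, 3]))
      }
      base
    }, character(1))
    lines <- c(title, sprintf("%5d", n), body,
               sprintf("%10.5f%10.5f%10.5f", fr$box$lengths[1],
                       fr$box$lengths[2], fr$box$lengths[3]))
  } else {
    ang <- 1 / crowd_constants$ang_to_nm
    lines <- c(
      sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
              fr$box$lengths[1] * ang, fr$box$lengths[2] * ang,
              fr$box$lengths[3] * ang, 90, 90, 90),
      vapply(seq_len(n), function(i) {
        sprintf("ATOM  %5d %-4s %-3s  %4d    %8.3f%8.3f%8.3f  1.00  0.00",
                i %% 100000L, substr(topology$name[i], 1, 4),
                substr(topology$residue_name[i], 1, 3),
                topology$residue_index[i] %% 10000L,
                fr$positions[i, 1] * ang, fr$positions[i, 2] * ang,
                fr$positions[i, 3] * ang)
      }, character(1)),
      "END")
  }
  writeLines(lines, path)
  invisible(path)
}
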