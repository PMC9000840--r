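#' Off-diagonal pressure-tensor time series
#'
#' Container for the six off-diagonal components of the pressure tensor
#' sampled along an equilibrium run, as consumed by the Einstein-Helfand
#' viscosity estimator. Components are stored in bar, times in ps, with
#' the system volume (nm^3) and temperature (K) attached.
#'
#' @param times Strictly increasing times (ps).
#' @param components Matrix `n x 6` (bar), columns in the order
#'   Pxy, Pxz, Pyz, Pyx, Pzx, Pzy. A 3-column matrix is mirrored
#'   (Pyx = Pxy, ...), the convention of engines that report only three
#'   independent components.
#' @param volume Box volume (nm^3).
#' @param temperature Temperature (K).
#' @return An object of class `"crowd_pressure_series"`.
#' @export
pressure_series <- function(times, components, volume, temperature) {
  components <- as.matrix(components)
  if (ncol(components) == 3L) {
    components <- cbind(components, components)
  }
  if (ncol(components) != 6L) {
    stop("components must have 3 (mirrored) or 6 columns")
  }
  if (nrow(components) != length(times)) {
    stop("times and components must have equal length")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  colnames(components) <- c("Pxy", "Pxz", "Pyz", "Pyx", "Pzx", "Pzy")
  structure(list(times = as.numeric(times), components = components,
                 volume = volume, temperature = temperature),
            class = "crowd_pressure_series")
}

#' @export
print.crowd_pressure_series <- function(x, ...) {
  cat(sprintf("pressure series: %d samples, t = %.6g..%.6g ps, V = %.4g nm^3, T = %.4g K\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              x$volume, x$temperature))
  invisible(x)
}

#' Read a pressure-tensor series (XVG or CSV)
#'
#' XVG follows the GROMACS dialect: `#` comment and `@` directive lines
#' are skipped; data rows hold time plus three or six off-diagonal
#' components. CSV needs a header with a `time` column and either three
#' (`Pxy, Pxz, Pyz`, mirrored) or six component columns.
#'
#' @param path File path.
#' @param format `"xvg"` or `"csv"`; guessed from the extension when
#'   missing.
#' @param volume Box volume (nm^3).
#' @param temperature Temperature (K).
#' @return A [pressure_series()].
#' @export
read_pressure_series <- function(path, format = c("xvg", "csv"),
                                 volume, temperature) {
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xvg", "csv")) ext else "csv"
  }
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "xvg") {
    lines <- readLines(path, warn = FALSE)
    keep <- lines[!grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))]
    if (length(keep) == 0L) stop(path, ": no data rows in XVG file")
    vals <- strsplit(trimws(keep), "\\s+")
    ncols <- unique(lengths(vals))
    if (length(ncols) != 1L || !(ncols %in% c(4L, 7L))) {
      stop(path, ": XVG rows must have time plus 3 or 6 pressure columns")
    }
    m <- matrix(suppressWarnings(as.numeric(unlist(vals))),
                ncol = ncols, byrow = TRUE)
    if (anyNA(m)) stop(path, ": non-numeric XVG data")
    pressure_series(m[, 1], m[, -1, drop = FALSE], volume, temperature)
  } else {
    df <- utils::read.csv(path)
    if (!"time" %in% names(df)) stop(path, ": CSV needs a 'time' column")
    comp_cols <- setdiff(names(df), "time")
    if (!length(comp_cols) %in% c(3L, 6L)) {
      stop(path, ": CSV needs 3 or 6 pressure component columns, found ",
           length(comp_cols))
    }
    pressure_series(df$time, as.matrix(df[comp_cols]), volume, temperature)
  }
}

#' Write a pressure-tensor series as CSV
#'
#' Numeric values are written with 17 significant digits so that a
#' write-then-read round trip reproduces the arrays bit-identically.
#'
#' @param series A [pressure_series()].
#' @param path Output path.
#' @export
write_pressure_csv <- function(series, path) {
  df <- data.frame(time = sprintf("%.17g", series$times),
                   apply(series$components, 2,
                         function(x) sprintf("%.17g", x)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
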