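#' Orthorhombic simulation box
#'
#' Construct a periodic orthorhombic box from its edge lengths. Triclinic
#' boxes are rejected explicitly: the solutions studied here use cubic
#' boxes and all minimum-image arithmetic in the package assumes
#' orthorhombic periodicity.
#'
#' @param lx,ly,lz Edge lengths in nm. `ly` and `lz` default to `lx`
#'   (cubic box).
#' @return An object of class `"crowd_box"`: a list with `lengths`
#'   (numeric 3-vector, nm) and `volume` (nm^3).
#' @examples
#' b <- box(4)        # 4 x 4 x 4 nm cubic box
#' b$volume           # 64 nm^3
#' @export
box <- function(lx, ly = lx, lz = lx) {
  lengths <- c(lx, ly, lz)
  if (!is.numeric(lengths) || length(lengths) != 3L || any(!is.finite(lengths))) {
    stop("box lengths must be three finite numbers")
  }
  if (any(lengths <= 0)) stop("box lengths must be positive")
  structure(list(lengths = lengths, volume = prod(lengths)),
            class = "crowd_box")
}

#' @export
print.crowd_box <- function(x, ...) {
  cat(sprintf("orthorhombic box %.4f x %.4f x %.4f nm (V = %.4f nm^3)\n",
              x$lengths[1], x$lengths[2], x$lengths[3], x$volume))
  invisible(x)
}

is_box <- function(x) inherits(x, "crowd_box")

as_box <- function(x) {
  if (is_box(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(box(x))
  if (is.numeric(x) && length(x) == 3L) return(box(x[1], x[2], x[3]))
  stop("cannot interpret object as a box")
}
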