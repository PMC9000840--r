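#' @keywords internal
amino_acids3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HID", "HIE", "HIP", "CYX", "ASH", "GLH", "LYN"
)

#' Default residue-name to molecule-class map
#'
#' Maps residue names to one of the four molecule classes used throughout
#' the package: `"protein"`, `"water"`, `"peg4"`, `"ion"`. Unmapped residue
#' names are an error, never a silent guess.
#'
#' @return Named character vector (names = residue names, values = classes).
#' @export
default_class_map <- function() {
  m <- c(
    SOL = "water", WAT = "water", HOH = "water", TIP3 = "water",
    PEG = "peg4", TEG = "peg4", PG4 = "peg4",
    CL = "ion", NA. = "ion", `NA` = "ion", `CL-` = "ion", `NA+` = "ion",
    K = "ion", `K+` = "ion",
    PRO = "protein", PRT = "protein", BEA = "protein"
  )
  aa <- rep("protein", length(amino_acids3))
  names(aa) <- amino_acids3
  c(m, aa)
}

#' Infer molecule classes from residue names
#'
#' @param residue_name Character vector of residue names.
#' @param class_map Named character vector mapping residue names to
#'   classes; see [default_class_map()].
#' @return Character vector of molecule classes.
#' @export
infer_molecule_class <- function(residue_name, class_map = default_class_map()) {
  key <- toupper(trimws(residue_name))
  cls <- unname(class_map[key])
  if (anyNA(cls)) {
    bad <- unique(key[is.na(cls)])
    stop("unmapped residue name(s): ", paste(bad, collapse = ", "),
         "; extend class_map to classify them")
  }
  cls
}

#' Guess a chemical element from an atom name
#'
#' Two-letter elements present in the supported systems (Cl, Na) are
#' recognised first; otherwise the first alphabetic character is used.
#'
#' @param name Character vector of atom names.
#' @return Character vector of element symbols.
#' @export
element_from_name <- function(name) {
  nm <- toupper(trimws(name))
  el <- substr(gsub("^[0-9]+", "", nm), 1, 1)
  el[grepl("^CL", nm)] <- "CL"
  el[grepl("^NA", nm)] <- "NA"
  el
}

#' @keywords internal
element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  CL = 35.45, `NA` = 22.99, K = 39.098, F = 18.998
)

#' Build an atom topology table
#'
#' The topology is a plain `data.frame` with one row per atom and the
#' columns every analysis consumes: `index` (0-based), `name`,
#' `residue_name`, `residue_index`, `molecule_class`, `mass` (g/mol),
#' `charge` (e), `lj_sigma` (nm), `lj_epsilon` (kJ/mol), and
#' `molecule_index` (integer molecule id: one per residue for solvent and
#' ions, one shared id for all protein atoms).
#'
#' @param name,residue_name Character vectors.
#' @param residue_index Integer vector.
#' @param mass Masses in g/mol; defaults to element masses inferred from
#'   atom names.
#' @param charge Partial charges in e (default 0).
#' @param lj_sigma,lj_epsilon Lennard-Jones parameters (nm, kJ/mol);
#'   default `NA` (required only by interaction-energy calculations).
#' @param molecule_class Classes; inferred from residue names when `NULL`.
#' @param class_map Passed to [infer_molecule_class()].
#' @return A `data.frame` of class `"crowd_topology"`.
#' @export
atom_table <- function(name, residue_name, residue_index,
                       mass = NULL, charge = 0,
                       lj_sigma = NA_real_, lj_epsilon = NA_real_,
                       molecule_class = NULL,
                       class_map = default_class_map()) {
  n <- length(name)
  stopifnot(length(residue_name) == n, length(residue_index) == n)
  if (is.null(molecule_class)) {
    molecule_class <- infer_molecule_class(residue_name, class_map)
  }
  if (is.null(mass)) {
    el <- element_from_name(name)
    mass <- unname(element_masses[el])
    if (anyNA(mass)) {
      stop("cannot infer mass for element(s): ",
           paste(unique(el[is.na(mass)]), collapse = ", "))
    }
  }
  mass <- rep_len(mass, n)
  charge <- rep_len(charge, n)
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("atom masses must be positive and finite")
  if (any(!is.finite(charge))) stop("atom charges must be finite")
  top <- data.frame(
    index = seq_len(n) - 1L,
    name = as.character(name),
    residue_name = as.character(residue_name),
    residue_index = as.integer(residue_index),
    molecule_class = molecule_class,
    mass = mass,
    charge = charge,
    lj_sigma = rep_len(lj_sigma, n),
    lj_epsilon = rep_len(lj_epsilon, n),
    stringsAsFactors = FALSE
  )
  top$molecule_index <- assign_molecules(top)
  class(top) <- c("crowd_topology", "data.frame")
  top
}

#' @keywords internal
assign_molecules <- function(top) {
  key <- ifelse(top$molecule_class == "protein",
                "protein",
                paste(top$molecule_class, top$residue_index, sep = ":"))
  as.integer(factor(key, levels = unique(key)))
}

#' Atom index groups for the molecules of one class
#'
#' @param topology A topology table.
#' @param class One of `"protein"`, `"water"`, `"peg4"`, `"ion"`.
#' @return A list of integer vectors of 1-based row indices, one per
#'   molecule.
#' @export
molecule_groups <- function(topology, class) {
  keep <- which(topology$molecule_class == class)
  if (length(keep) == 0L) return(list())
  split(keep, topology$molecule_index[keep])
}

#' Backbone atom selection
#'
#' Selects protein backbone atoms (N, CA, C) from a topology, the standard
#' selection for backbone RMSD.
#'
#' @param topology A topology table.
#' @return Integer vector of 1-based atom row indices.
#' @export
backbone_selection <- function(topology) {
  which(topology$molecule_class == "protein" &
          toupper(topology$name) %in% c("N", "CA", "C"))
}

#' Read / write a topology table as CSV
#'
#' Plain-text round trip for topology tables so trajectories stored in the
#' text frame format can travel with their atom metadata.
#'
#' @param path File path.
#' @param topology A topology table (for writing).
#' @return `read_topology_csv` returns a topology table.
#' @export
read_topology_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "residue_name", "residue_index")
  if (!all(need %in% names(df))) {
    stop("topology CSV must contain columns: ", paste(need, collapse = ", "))
  }
  atom_table(df$name, df$residue_name, df$residue_index,
             mass = if ("mass" %in% names(df)) df$mass else NULL,
             charge = if ("charge" %in% names(df)) df$charge else 0,
             lj_sigma = if ("lj_sigma" %in% names(df)) df$lj_sigma else NA_real_,
             lj_epsilon = if ("lj_epsilon" %in% names(df)) df$lj_epsilon else NA_real_,
             molecule_class = if ("molecule_class" %in% names(df)) df$molecule_class else NULL)
}

#' @rdname read_topology_csv
#' @export
write_topology_csv <- function(topology, path) {
  utils::write.csv(as.data.frame(topology), path, row.names = FALSE)
  invisible(path)
}
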