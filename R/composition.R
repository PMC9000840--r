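#' Solution component specification
#'
#' @param name Component name.
#' @param molar_mass Molar mass, g/mol.
#' @param pure_density Density of the pure liquid, g/mL.
#' @return A list of class `"crowd_component"`.
#' @export
component_spec <- function(name, molar_mass, pure_density) {
  if (molar_mass <= 0) stop("molar_mass must be positive")
  if (pure_density <= 0) stop("pure_density must be positive")
  structure(list(name = name, molar_mass = molar_mass,
                 pure_density = pure_density),
            class = "crowd_component")
}

#' @rdname component_spec
#' @details `peg4_component()` and `water_component()` return the defaults
#'   used throughout: tetraethylene glycol (C8H18O5, 194.23 g/mol,
#'   1.12 g/mL) and water (18.015 g/mol, 1.00 g/mL).
#' @export
peg4_component <- function() component_spec("PEG-4", 194.23, 1.12)

#' @rdname component_spec
#' @export
water_component <- function() component_spec("water", 18.015, 1.00)

#' Molecule counts for a target crowder concentration
#'
#' Computes the number of crowder and water molecules filling a periodic
#' box at a target concentration in % w/v (g of crowder per 100 mL of
#' solution). The crowder count is the floor of the exact value; water
#' then fills the residual volume at its pure density (ideal mixing),
#' again floored. At the pure-liquid boundary (c = 100 * pure density,
#' 112 for PEG-4) the solution contains no water by definition.
#'
#' @param concentration_wv Concentration in % w/v.
#' @param box A [box()].
#' @param peg,water [component_spec()]s for the crowder and water.
#' @return A list with integer `n_peg` and `n_water`.
#' @examples
#' solvent_counts(0, box(4))    # 2139 waters in a 4 nm cubic box
#' solvent_counts(65, box(4))   # 128 PEG-4, floor of 128.98
#' @export
solvent_counts <- function(concentration_wv, box,
                           peg = peg4_component(),
                           water = water_component()) {
  box <- as_box(box)
  cmax <- 100 * peg$pure_density
  if (concentration_wv < 0 || concentration_wv > cmax + 1e-9) {
    stop(sprintf("concentration must lie in [0, %g] %% w/v", cmax))
  }
  NA_ <- crowd_constants$N_A
  V_mL <- box$volume * crowd_constants$nm3_to_mL
  mass_peg_target <- concentration_wv / 100 * V_mL           # g
  n_peg <- floor(mass_peg_target * NA_ / peg$molar_mass)
  if (abs(concentration_wv - cmax) < 1e-9) {
    n_water <- 0
  } else {
    V_peg <- n_peg * peg$molar_mass / (NA_ * peg$pure_density) # mL
    n_water <- floor(water$pure_density * (V_mL - V_peg) * NA_ /
                       water$molar_mass)
    n_water <- max(0, n_water)
  }
  list(n_peg = as.integer(n_peg), n_water = as.integer(n_water))
}

#' Concentration of a realized composition in three unit systems
#'
#' Given realized molecule counts, returns the concentration as % w/v
#' (crowder mass per box volume), volume percent (crowder volume over
#' total component volume at pure-component densities, ideal mixing), and
#' weight percent. Exact values and the floored integers that match
#' printed composition tables are both returned.
#'
#' @inheritParams solvent_counts
#' @param n_peg,n_water Molecule counts.
#' @return A list with `exact` and `floored` numeric 3-vectors named
#'   `wv`, `v_pct`, `wt_pct`.
#' @export
concentration_units <- function(n_peg, n_water, box,
                                peg = peg4_component(),
                                water = water_component()) {
  box <- as_box(box)
  if (box$volume <= 0) stop("box volume must be positive")
  if (n_peg == 0 && n_water == 0) stop("at least one component count must be positive")
  NA_ <- crowd_constants$N_A
  V_mL <- box$volume * crowd_constants$nm3_to_mL
  m_peg <- n_peg * peg$molar_mass / NA_       # g
  m_water <- n_water * water$molar_mass / NA_ # g
  V_peg <- m_peg / peg$pure_density           # mL
  V_water <- m_water / water$pure_density     # mL
  wv <- 100 * m_peg / V_mL
  v_pct <- 100 * V_peg / (V_peg + V_water)
  wt_pct <- 100 * m_peg / (m_peg + m_water)
  exact <- c(wv = wv, v_pct = v_pct, wt_pct = wt_pct)
  list(exact = exact, floored = floor(exact))
}

#' Crowder volume fraction
#'
#' Volume fraction of the crowder in the box from its pure-component molar
#' volume (ideal mixing), the quantity entering the Enskog hard-sphere
#' reference.
#'
#' @inheritParams solvent_counts
#' @param n_peg Crowder molecule count.
#' @return Volume fraction in `[0, 1]`.
#' @export
volume_fraction <- function(n_peg, box, peg = peg4_component()) {
  if (n_peg < 0) stop("n_peg must be non-negative")
  box <- as_box(box)
  V_mL <- box$volume * crowd_constants$nm3_to_mL
  V_peg <- n_peg * peg$molar_mass / (crowd_constants$N_A * peg$pure_density)
  min(1, max(0, V_peg / V_mL))
}

#' Composition table over a concentration grid
#'
#' Reconstructs the full composition table of a crowder concentration
#' series: molecule counts and the three concentration unit columns
#' (floored, as printed) plus the exact volume fraction.
#'
#' @param concentrations Concentration grid in % w/v; the default is the
#'   eleven-point series 0, 15, 25, ..., 95, 112 (pure liquid). The `wv`
#'   column reports the nominal grid value; `v_pct`/`wt_pct` are floored
#'   from the realized counts.
#' @inheritParams solvent_counts
#' @return A `data.frame` with columns `wv`, `v_pct`, `wt_pct`, `n_peg`,
#'   `n_water`, `phi`.
#' @export
composition_table <- function(concentrations = c(0, seq(15, 95, by = 10), 112),
                              box = crowdsolv::box(4),
                              peg = peg4_component(),
                              water = water_component()) {
  concentrations <- sort(unique(concentrations))
  rows <- lapply(concentrations, function(cc) {
    cnt <- solvent_counts(cc, box, peg, water)
    if (cnt$n_peg == 0 && cnt$n_water == 0) {
      units <- list(floored = c(wv = 0, v_pct = 0, wt_pct = 0))
    } else {
      units <- concentration_units(cnt$n_peg, cnt$n_water, box, peg, water)
    }
    data.frame(wv = cc,
               v_pct = unname(units$floored["v_pct"]),
               wt_pct = unname(units$floored["wt_pct"]),
               n_peg = cnt$n_peg, n_water = cnt$n_water,
               phi = volume_fraction(cnt$n_peg, box, peg))
  })
  do.call(rbind, rows)
}
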