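#' Physical constants and unit conversions
#'
#' Single source of truth for every physical constant and unit conversion
#' used in the package. Internal units are nm, ps, K, elementary charge e,
#' and kJ/mol; reported units follow MD convention (mPa*s for viscosity,
#' 1e-5 cm^2/s for diffusion constants).
#'
#' @format A named list:
#' \describe{
#'   \item{kB}{Boltzmann constant, J/K.}
#'   \item{N_A}{Avogadro constant, 1/mol.}
#'   \item{f_coulomb}{Electric conversion factor, kJ mol^-1 nm e^-2.}
#'   \item{xi_cubic}{Self-interaction constant of the periodic-boundary
#'     hydrodynamic correction for a cubic box, 2.837297.}
#'   \item{bar_to_Pa}{Pressure conversion.}
#'   \item{nm_to_m, ps_to_s, ang_to_nm}{Length/time conversions.}
#'   \item{nm3_to_mL}{1 nm^3 in mL.}
#'   \item{nm2ps_to_1e5cm2s}{1 nm^2/ps expressed in units of 1e-5 cm^2/s.}
#'   \item{nmps_to_ms}{1 nm/ps in m/s.}
#' }
#' @export
crowd_constants <- list(
  kB          = 1.380649e-23,
  N_A         = 6.02214076e23,
  f_coulomb   = 138.935458,
  xi_cubic    = 2.837297,
  bar_to_Pa   = 1e5,
  nm_to_m     = 1e-9,
  ps_to_s     = 1e-12,
  ang_to_nm   = 0.1,
  nm3_to_mL   = 1e-21,
  nm2ps_to_1e5cm2s = 1000,
  nmps_to_ms  = 1000
)
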