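#' Physical constants used throughout aquaflux
#'
#' All internal computation is done in CGS units (cm, s, g, erg, dyn) because
#' unitary permeabilities are conventionally reported in cm^3/s, membrane
#' permeabilities in cm/s, and diffusion coefficients in cm^2/s.  Energies at
#' the molar scale are handled in kcal/mol.
#'
#' @format A named list with components:
#' \describe{
#'   \item{kB_erg}{Boltzmann constant, erg/K.}
#'   \item{R_erg}{Gas constant, erg/(mol K).}
#'   \item{R_kcal}{Gas constant, kcal/(mol K).}
#'   \item{N_A}{Avogadro constant, 1/mol.}
#'   \item{v_w}{Volume of one water molecule, cm^3 (18 cm^3/mol / N_A).}
#'   \item{V_w_molar}{Partial molar volume of water, cm^3/mol.}
#'   \item{z_water}{Default water-water spacing in a single file, cm
#'     (one water diameter, 2.8 Angstrom).}
#'   \item{nu0}{Transition-state-theory attempt frequency, 1/s.}
#'   \item{T_default}{Default absolute temperature, K.}
#' }
#' @export
af_constants <- list(
  kB_erg    = 1.380649e-16,
  R_erg     = 8.31446e7,
  R_kcal    = 1.98720e-3,
  N_A       = 6.02214076e23,
  v_w       = 3.0e-23,
  V_w_molar = 18,
  z_water   = 2.8e-8,
  nu0       = 1e13,
  T_default = 298.15
)

#' Unit conversions at the data boundary
#'
#' File formats carry human-scale units (mM, micrometres, nm); everything
#' internal is CGS.  These helpers are the only place the conversion factors
#' live.
#'
#' @param c_mM concentration in mmol/L.
#' @param c molar concentration in mol/cm^3.
#' @param x_um distance in micrometres.
#' @param r_nm length in nanometres.
#' @return The converted numeric value.
#' @examples
#' mM_to_molcm3(100)  # 1e-4 mol/cm^3
#' @name af_units
NULL

#' @rdname af_units
#' @export
mM_to_molcm3 <- function(c_mM) c_mM * 1e-6

#' @rdname af_units
#' @export
molcm3_to_mM <- function(c) c * 1e6

#' @rdname af_units
#' @export
um_to_cm <- function(x_um) x_um * 1e-4

#' @rdname af_units
#' @export
cm_to_um <- function(x) x * 1e4

#' @rdname af_units
#' @export
nm_to_cm <- function(r_nm) r_nm * 1e-7

#' Ideal (van 't Hoff) osmotic pressure
#'
#' Converts an osmolyte concentration difference to an osmotic pressure
#' difference, \eqn{\Delta\Pi = RT\,\Delta c}, the substitution used when the
#' driving force of a water flux is expressed per osmolyte molecule
#' (\eqn{\Delta\Pi = kT\,\Delta n_s}).
#'
#' @param delta_c concentration difference, mol/cm^3.
#' @param T_K absolute temperature, K.
#' @return Osmotic pressure difference, dyn/cm^2.
#' @examples
#' osmotic_pressure(mM_to_molcm3(100), 298)  # about 2.48e6 dyn/cm^2
#' @export
osmotic_pressure <- function(delta_c, T_K = af_constants$T_default) {
  stopifnot(T_K > 0)
  af_constants$R_erg * T_K * delta_c
}

# internal: positive-scalar argument check shared by the theory layer
.check_positive <- function(...) {
  vals <- list(...)
  nm <- names(vals)
  for (i in seq_along(vals)) {
    if (!is.numeric(vals[[i]]) || any(!is.finite(vals[[i]])) || any(vals[[i]] <= 0)) {
      stop(sprintf("'%s' must be a positive finite number", nm[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}
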