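#' Synthetic stopped-flow deflation trace
#'
#' Generates a scattered-light (or volume) trace from the Lambert-W forward
#' model for a single vesicle population or a mixture, applies the noise
#' model, and attaches the ground truth so recovery can be scored.
#' Deterministic under the noise seed.
#'
#' @param spec a \code{\link{vesicle_spec}} or \code{\link{mixture_spec}}.
#' @param t_grid times, s, starting at 0 (default 500 points over 0.5 s).
#' @param calib a \code{\link{scatter_calibration}}; \code{NULL} returns a
#'   volume trace instead of an intensity trace.
#' @param noise a \code{\link{noise_spec}}.
#' @return An \code{\link{intensity_trace}} (or \code{\link{volume_trace}}
#'   when \code{calib} is NULL) whose \code{meta} attribute carries
#'   \code{truth} (P_f, r0, weights) and the \code{noise} used.
#' @examples
#' sp <- vesicle_spec(nm_to_cm(100), mM_to_molcm3(290), mM_to_molcm3(300), 0.01)
#' tr <- gen_deflation(sp, noise = noise_spec(sigma = 0.01, seed = 1))
#' @export
gen_deflation <- function(spec, t_grid = seq(0, 0.5, length.out = 500),
                          calib = NULL, noise = noise_spec(sigma = 0)) {
  .check_times(t_grid)
  if (inherits(spec, "vesicle_spec")) {
    truth <- list(P_f = spec$P_f, r0 = spec$r0, weights = 1,
                  c_in0 = spec$c_in0, c_out = spec$c_out)
    V <- deflate_analytic(spec, t_grid)
    if (is.null(calib)) {
      y <- .apply_noise(V, noise)
      return(volume_trace(t_grid, y, meta = list(truth = truth, noise = noise)))
    }
    I <- intensity_from_volume(V, calib)
  } else if (inherits(spec, "mixture_spec")) {
    truth <- list(P_f = vapply(spec$populations, `[[`, numeric(1), "P_f"),
                  r0 = vapply(spec$populations, `[[`, numeric(1), "r0"),
                  weights = spec$weights)
    if (is.null(calib)) {
      stop("a mixture observable is scattering intensity: supply a calibration",
           call. = FALSE)
    }
    I <- mixture_trace(spec, calib, t_grid)$y
  } else {
    stop("spec must be a vesicle_spec or mixture_spec", call. = FALSE)
  }
  intensity_trace(t_grid, .apply_noise(I, noise),
                  meta = list(truth = truth, noise = noise, calib = calib))
}

#' Synthetic unstirred-layer microelectrode scan
#'
#' Evaluates the steady-state profile model on a distance grid and applies
#' the noise model; ground truth travels in \code{meta}.
#'
#' @param C_s near-membrane concentration, mol/cm^3.
#' @param v_t transmembrane flow velocity, cm/s.
#' @param D solute diffusion coefficient, cm^2/s.
#' @param a_stir stirring parameter.
#' @param x_grid distances, cm (default 30 points over 0-200 um).
#' @param noise a \code{\link{noise_spec}}.
#' @return A \code{\link{concentration_profile}} with \code{truth} in meta.
#' @export
gen_profile <- function(C_s, v_t, D, a_stir = 0,
                        x_grid = seq(0, 200e-4, length.out = 30),
                        noise = noise_spec(sigma = 0)) {
  C <- ul_profile(x_grid, C_s, v_t, D, a_stir)
  C_noisy <- .apply_noise(C, noise)
  if (any(C_noisy <= 0)) {
    stop("noise drove concentrations non-positive; lower sigma", call. = FALSE)
  }
  concentration_profile(x_grid, C_noisy, D,
                        meta = list(truth = list(C_s = C_s, v_t = v_t,
                                                 a_stir = a_stir),
                                    noise = noise))
}

#' Synthetic Arrhenius temperature series
#'
#' Generates permeabilities \eqn{P_f(T) = A_0 \exp(-E_a/RT)} on a
#' temperature grid with multiplicative noise.
#'
#' @param E_a activation energy, kcal/mol.
#' @param prefactor Arrhenius prefactor A_0 (same units as the output P_f).
#' @param T_grid temperatures, K (default 6 points, 278-308 K).
#' @param noise a \code{\link{noise_spec}}.
#' @return An \code{\link{arrhenius_series}} with \code{truth} in meta.
#' @export
gen_arrhenius <- function(E_a, prefactor,
                          T_grid = seq(278, 308, length.out = 6),
                          noise = noise_spec(sigma = 0)) {
  P <- prefactor * exp(-E_a / (af_constants$R_kcal * T_grid))
  P_noisy <- .apply_noise(P, noise)
  if (any(P_noisy <= 0)) {
    stop("noise drove permeabilities non-positive; lower sigma", call. = FALSE)
  }
  arrhenius_series(T_grid, P_noisy,
                   meta = list(truth = list(E_a = E_a, prefactor = prefactor),
                               noise = noise))
}

#' Synthetic channel catalog on an exponential structure-function line
#'
#' Places channels on \eqn{\ln p_f = intercept + slope \cdot N_H} with
#' lognormal scatter of width \code{sigma_ln}.
#'
#' @param slope decay per hydrogen-bonding residue (negative expected).
#' @param intercept ln p_f at N_H = 0.
#' @param N_H_values predictor values, one channel each.
#' @param sigma_ln standard deviation of the log-scale scatter.
#' @param seed integer seed (required when sigma_ln > 0).
#' @return A catalog data frame (columns \code{name}, \code{N},
#'   \code{N_H}, \code{pf_cm3_s}, \code{dG_kcal_mol}, \code{quality}) with
#'   a \code{truth} attribute.
#' @export
gen_catalog <- function(slope, intercept, N_H_values = c(0, 4, 8, 12, 16, 20),
                        sigma_ln = 0, seed = NULL) {
  if (sigma_ln < 0) stop("sigma_ln must be >= 0", call. = FALSE)
  ln_pf <- intercept + slope * N_H_values
  if (sigma_ln > 0) {
    if (is.null(seed)) stop("a seed is required for sigma_ln > 0", call. = FALSE)
    ln_pf <- local_seed(seed, ln_pf + stats::rnorm(length(ln_pf), sd = sigma_ln))
  }
  cat_df <- data.frame(
    name = sprintf("synthetic_channel_%02d", seq_along(N_H_values)),
    N = NA_real_,
    N_H = N_H_values,
    pf_cm3_s = exp(ln_pf),
    dG_kcal_mol = NA_real_,
    quality = "direct_count",
    stringsAsFactors = FALSE)
  attr(cat_df, "truth") <- list(slope = slope, intercept = intercept,
                                sigma_ln = sigma_ln, seed = seed)
  cat_df
}

#' Synthetic slope-census data set
#'
#' Generates ensemble permeabilities \eqn{P_f = p_f \cdot density +
#' P_{f,lipid}} over a set of channel surface densities (or the electrical
#' analogue over conductances, with a silent-channel fraction reducing the
#' observed conductance), with multiplicative noise on P_f.
#'
#' @param p_f unitary permeability, cm^3/s.
#' @param densities channel surface densities, channels/cm^2 (density
#'   kind), or channel counts n (conductance kind).
#' @param lipid_Pf channel-free background permeability, cm/s.
#' @param kind \code{"density"} or \code{"conductance"}.
#' @param A,g membrane area (cm^2) and single-channel conductance (S), used
#'   for the conductance kind.
#' @param silent_fraction fraction of channels invisible to the electrical
#'   census (conductance kind only).
#' @param noise a \code{\link{noise_spec}} applied to P_f.
#' @return A \code{\link{slope_census}} with \code{truth} in an attribute.
#' @export
gen_slope_census <- function(p_f, densities, lipid_Pf = 0,
                             kind = c("density", "conductance"),
                             A = 1e-2, g = 2e-12, silent_fraction = 0,
                             noise = noise_spec(sigma = 0)) {
  kind <- match.arg(kind)
  if (kind == "density") {
    P_f <- p_f * densities + lipid_Pf
    x <- densities
  } else {
    n <- densities
    P_f <- p_f * n / A + lipid_Pf
    x <- (1 - silent_fraction) * n * g   # observed conductance
  }
  census <- slope_census(x, .apply_noise(P_f, noise), kind = kind)
  attr(census, "truth") <- list(p_f = p_f, lipid_Pf = lipid_Pf,
                                silent_fraction = silent_fraction,
                                A = A, g = g)
  census
}
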