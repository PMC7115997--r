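#' Transition-state barrier model for single-channel water transport
#'
#' Links the unitary permeability to a Gibbs activation energy barrier
#' through the hopping picture: the water column advances with rate
#' \eqn{r = \nu_0 \exp(-\Delta G^\ddagger / k_B T)} and each hop moves one
#' water volume, so \eqn{p_f = r\, v_w}.
#'
#' @param dG Gibbs activation energy barrier, kcal/mol.
#' @param nu0 attempt frequency, 1/s (universal TST value 1e13).
#' @param T_K absolute temperature, K.
#' @param v_w volume of one water molecule, cm^3.
#' @return Object of class \code{barrier_model} with the inputs plus the
#'   derived hopping rate \code{r} (1/s) and \code{defaults_used}.
#' @export
barrier_model <- function(dG, nu0 = af_constants$nu0,
                          T_K = af_constants$T_default,
                          v_w = af_constants$v_w) {
  stopifnot(is.numeric(dG), length(dG) == 1)
  .check_positive(nu0 = nu0, T_K = T_K, v_w = v_w)
  defaults_used <- character()
  if (missing(nu0)) defaults_used <- c(defaults_used, "nu0 = 1e13 1/s")
  if (missing(T_K)) defaults_used <- c(defaults_used, "T = 298.15 K")
  if (missing(v_w)) defaults_used <- c(defaults_used, "v_w = 3.0e-23 cm^3")
  r <- nu0 * exp(-dG / (af_constants$R_kcal * T_K))
  structure(list(dG = dG, nu0 = nu0, T_K = T_K, v_w = v_w, r = r,
                 defaults_used = defaults_used),
            class = "barrier_model")
}

#' @export
print.barrier_model <- function(x, ...) {
  cat(sprintf("Barrier model: dG = %.4g kcal/mol at T = %.4g K\n", x$dG, x$T_K))
  cat(sprintf("  hopping rate r = %.4g 1/s, p_f = %.4g cm^3/s\n",
              x$r, pf_from_barrier(x)))
  invisible(x)
}

#' Hopping rate of the water column
#'
#' \deqn{r = p_f / v_w}: the forward/backward stepping rate implied by a
#' unitary permeability, i.e. how many water volumes the channel moves per
#' second and per unit osmotic number fraction.
#'
#' @param p_f unitary osmotic permeability, cm^3/s.
#' @param v_w volume of one water molecule, cm^3.
#' @return Hopping rate, 1/s.
#' @examples
#' hopping_rate(1e-13)  # ~3.3e9 1/s
#' @export
hopping_rate <- function(p_f, v_w = af_constants$v_w) {
  .check_positive(v_w = v_w)
  p_f / v_w
}

#' Unitary permeability predicted by transition-state theory
#'
#' \deqn{p_f = \nu_0 v_w \exp(-\Delta G^\ddagger / RT).}  A barrier of
#' 24.1 kcal/mol at 298 K yields p_f of order 1e-28 cm^3/s -- immeasurably
#' small -- which is the thermodynamic argument against claims of fast water
#' transport across high-barrier pores.
#'
#' @param model a \code{\link{barrier_model}}, or a numeric dG (kcal/mol)
#'   combined with the remaining arguments.
#' @param nu0,T_K,v_w used only when \code{model} is numeric.
#' @return p_f, cm^3/s.
#' @examples
#' pf_from_barrier(barrier_model(24.1, T_K = 298))  # ~6.3e-28
#' @export
pf_from_barrier <- function(model, nu0 = af_constants$nu0,
                            T_K = af_constants$T_default,
                            v_w = af_constants$v_w) {
  if (is.numeric(model)) model <- barrier_model(model, nu0, T_K, v_w)
  stopifnot(inherits(model, "barrier_model"))
  model$r * model$v_w
}

#' Activation barrier implied by a unitary permeability
#'
#' Inverts the transition-state relation:
#' \deqn{\Delta G^\ddagger = -RT \ln\!\left(p_f / (\nu_0 v_w)\right).}
#' A p_f above \eqn{\nu_0 v_w} would imply a hopping rate above the attempt
#' frequency and is rejected.  Together with \code{\link{pf_from_barrier}}
#' this provides a consistency check: a claimed (p_f, dG) pair is
#' thermodynamically impossible when the implied barrier differs grossly
#' from the measured one (see \code{\link{barrier_consistency}}).
#'
#' @param p_f unitary osmotic permeability, cm^3/s.
#' @param T_K absolute temperature, K.
#' @param nu0 attempt frequency, 1/s.
#' @param v_w volume of one water molecule, cm^3.
#' @return dG, kcal/mol.
#' @export
barrier_from_pf <- function(p_f, T_K = af_constants$T_default,
                            nu0 = af_constants$nu0,
                            v_w = af_constants$v_w) {
  .check_positive(p_f = p_f, T_K = T_K, nu0 = nu0, v_w = v_w)
  if (p_f > nu0 * v_w * (1 + 1e-12)) {
    stop(sprintf("p_f = %.3g cm^3/s exceeds nu0*v_w = %.3g: hopping rate above the attempt frequency",
                 p_f, nu0 * v_w), call. = FALSE)
  }
  -af_constants$R_kcal * T_K * log(p_f / (nu0 * v_w))
}

#' Consistency check between a claimed p_f and a claimed barrier
#'
#' Computes the barrier implied by the claimed p_f and compares it with the
#' independently reported dG.  Discrepancies beyond \code{tol_kcal} flag the
#' pair as thermodynamically inconsistent (rate and activation energy cannot
#' be disentangled).
#'
#' @param p_f claimed unitary permeability, cm^3/s.
#' @param dG_claimed claimed barrier, kcal/mol.
#' @param tol_kcal tolerance, kcal/mol.
#' @inheritParams barrier_from_pf
#' @return List with \code{dG_implied}, \code{dG_claimed},
#'   \code{discrepancy} (kcal/mol) and logical \code{consistent}.
#' @examples
#' # a nanotube claim: p_f = 6.8e-13 cm^3/s together with dG = 24.1 kcal/mol
#' barrier_consistency(6.8e-13, 24.1, T_K = 298)
#' @export
barrier_consistency <- function(p_f, dG_claimed, tol_kcal = 1,
                                T_K = af_constants$T_default,
                                nu0 = af_constants$nu0,
                                v_w = af_constants$v_w) {
  dG_implied <- barrier_from_pf(p_f, T_K, nu0, v_w)
  disc <- dG_claimed - dG_implied
  list(dG_implied = dG_implied, dG_claimed = dG_claimed,
       discrepancy = disc, consistent = abs(disc) <= tol_kcal)
}

#' Composite upper limit for the water-transport barrier
#'
#' When pore water loses its bulk properties, an upper limit for the
#' activation barrier is obtained by adding the energy needed to move a
#' water molecule out of solution into the pore (the enthalpy of
#' vaporization) to the activation energy of water self-diffusion.  With
#' the standard component values (4.6 and 10.5 kcal/mol) the limit is about
#' 15 kcal/mol; the self-diffusion term alone is the lower limit, applying
#' when pore water remains bulk-like.
#'
#' @param E_selfdiff activation energy of water self-diffusion, kcal/mol.
#' @param dH_vap enthalpy of vaporization contribution, kcal/mol.
#' @return List with \code{lower} and \code{upper} barrier limits, kcal/mol.
#' @export
barrier_limits <- function(E_selfdiff = 4.6, dH_vap = 10.5) {
  .check_positive(E_selfdiff = E_selfdiff, dH_vap = dH_vap)
  list(lower = E_selfdiff, upper = E_selfdiff + dH_vap)
}

#' Temperature series of permeability measurements
#'
#' @param T_K temperatures, K (>= 2 distinct).
#' @param P_f permeabilities at each temperature, any consistent units
#'   (cm/s or cm^3/s), strictly positive.
#' @param meta optional named list.
#' @return Object of class \code{arrhenius_series}.
#' @export
arrhenius_series <- function(T_K, P_f, meta = list()) {
  if (length(T_K) != length(P_f)) stop("T_K and P_f lengths differ", call. = FALSE)
  if (length(unique(T_K)) < 2) stop("need >= 2 distinct temperatures", call. = FALSE)
  if (any(T_K <= 0)) stop("temperatures must be positive (K)", call. = FALSE)
  if (any(P_f <= 0)) stop("permeabilities must be positive", call. = FALSE)
  structure(list(T_K = T_K, P_f = P_f), class = "arrhenius_series",
            meta = meta)
}

#' Arrhenius analysis of a permeability temperature series
#'
#' Ordinary least squares of ln P_f on 1/T; the activation energy is
#' \eqn{E_a = -R \times slope}.  The slope of this plot is commonly read as
#' the Gibbs activation barrier of transport; strictly it is an Arrhenius
#' activation energy and no enthalpy/entropy decomposition is attempted
#' here.
#'
#' @param series an \code{\link{arrhenius_series}}.
#' @param conf confidence level.
#' @return List of class \code{arrhenius_fit} with \code{E_a} (kcal/mol),
#'   \code{intercept} (ln prefactor), \code{ci} (kcal/mol bounds on E_a) and
#'   the underlying \code{lm}.
#' @export
fit_activation_energy <- function(series, conf = 0.95) {
  stopifnot(inherits(series, "arrhenius_series"))
  invT <- 1 / series$T_K
  fit <- stats::lm(log(series$P_f) ~ invT)
  cf <- stats::coef(fit)
  E_a <- -af_constants$R_kcal * unname(cf[2])
  ci <- if (length(series$T_K) > 2) {
    raw <- suppressWarnings(stats::confint(fit, level = conf))
    -af_constants$R_kcal * raw[2, c(2, 1)]
  } else c(NA_real_, NA_real_)
  names(ci) <- c("lower", "upper")
  structure(list(E_a = E_a, intercept = unname(cf[1]), ci = ci, model = fit),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit: E_a = %.4g kcal/mol", x$E_a))
  if (!anyNA(x$ci)) cat(sprintf(" [%.4g, %.4g]", x$ci[1], x$ci[2]))
  cat(sprintf(", ln prefactor = %.4g\n", x$intercept))
  invisible(x)
}
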