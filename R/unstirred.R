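#' Steady-state unstirred-layer concentration profile
#'
#' During a transmembrane osmotic water flux the solution adjacent to the
#' membrane is diluted (on the draw side) or concentrated, because transport
#' within the stagnant unstirred layer is diffusion-limited.  The
#' steady-state solute concentration at distance x from the membrane is
#' \deqn{C(x) = C_s \exp\!\left(-\frac{v_t x}{D} + \frac{a x^3}{3D}\right)}
#' where C_s is the near-membrane concentration, v_t the transmembrane
#' volume-flow velocity, D the solute diffusion coefficient and a an
#' empirical stirring parameter describing the return to the stirred bulk.
#'
#' Sign convention: x is measured into the hyperosmotic (draw) compartment;
#' v_t > 0 produces near-membrane dilution (C_s below bulk).
#'
#' @param x distance(s) from the membrane, cm (>= 0).
#' @param C_s near-membrane solute concentration, mol/cm^3.
#' @param v_t transmembrane volume-flow velocity, cm/s.
#' @param D solute diffusion coefficient, cm^2/s.
#' @param a_stir stirring parameter (units 1/(cm s)).
#' @return Concentration(s) at x, mol/cm^3.
#' @examples
#' ul_profile(um_to_cm(50), mM_to_molcm3(100), 1e-4, 2e-5)  # ~97.5 mM
#' @export
ul_profile <- function(x, C_s, v_t, D, a_stir = 0) {
  if (any(x < 0)) stop("x must be >= 0", call. = FALSE)
  .check_positive(C_s = C_s, D = D)
  C_s * exp(-v_t * x / D + a_stir * x^3 / (3 * D))
}

#' Container for a measured concentration profile
#'
#' @param x distances from the membrane, cm, non-negative, increasing.
#' @param C concentrations, mol/cm^3, positive.
#' @param D solute diffusion coefficient, cm^2/s (fixed, from tables).
#' @param meta optional named list (e.g. generator ground truth).
#' @return Object of class \code{concentration_profile}.
#' @export
concentration_profile <- function(x, C, D, meta = list()) {
  if (length(x) != length(C)) stop("x and C lengths differ", call. = FALSE)
  if (any(x < 0) || any(diff(x) <= 0)) {
    stop("x must be non-negative and strictly increasing", call. = FALSE)
  }
  if (any(C <= 0)) stop("concentrations must be positive", call. = FALSE)
  .check_positive(D = D)
  structure(list(x = x, C = C, D = D), class = "concentration_profile",
            meta = meta)
}

#' Fit the unstirred-layer profile model
#'
#' In log space the profile is linear in its parameters:
#' \deqn{\ln C = \ln C_s - (v_t/D)\, x + (a/3D)\, x^3,} so ordinary least
#' squares of ln C on \{1, x, x^3\} recovers ln C_s, v_t and the stirring
#' parameter, with confidence intervals from the residual covariance.  The
#' stirring parameter can be frozen (e.g. from a no-gradient control scan)
#' by supplying \code{a_stir}.
#'
#' @param profile a \code{\link{concentration_profile}} (D fixed).
#' @param a_stir optional: freeze the stirring parameter at this value
#'   instead of fitting it.
#' @param conf confidence level for the intervals.
#' @return Object of class \code{ul_fit}: list with \code{C_s}, \code{v_t},
#'   \code{a_stir}, a \code{ci} matrix (rows C_s, v_t, a_stir), and the
#'   underlying \code{lm} fit.
#' @export
fit_ul_profile <- function(profile, a_stir = NULL, conf = 0.95) {
  stopifnot(inherits(profile, "concentration_profile"))
  x <- profile$x; D <- profile$D
  if (length(x) < 5) stop("need at least 5 points", call. = FALSE)
  if (length(unique(x)) < 2) stop("design is collinear: all x equal", call. = FALSE)
  lC <- log(profile$C)
  if (is.null(a_stir)) {
    fit <- stats::lm(lC ~ x + I(x^3))
    cf <- stats::coef(fit)
    ci_raw <- suppressWarnings(stats::confint(fit, level = conf))
    a_hat <- 3 * D * unname(cf[3])
    ci <- rbind(C_s = exp(ci_raw[1, ]),
                v_t = -D * ci_raw[2, c(2, 1)],
                a_stir = 3 * D * ci_raw[3, ])
  } else {
    off <- a_stir * x^3 / (3 * D)
    fit <- stats::lm(lC ~ x, offset = off)
    cf <- stats::coef(fit)
    ci_raw <- suppressWarnings(stats::confint(fit, level = conf))
    a_hat <- a_stir
    ci <- rbind(C_s = exp(ci_raw[1, ]),
                v_t = -D * ci_raw[2, c(2, 1)],
                a_stir = c(a_stir, a_stir))
  }
  colnames(ci) <- c("lower", "upper")
  structure(list(C_s = exp(unname(cf[1])),
                 v_t = -D * unname(cf[2]),
                 a_stir = a_hat,
                 ci = ci, model = fit),
            class = "ul_fit")
}

#' @export
print.ul_fit <- function(x, ...) {
  cat(sprintf("Unstirred-layer fit: v_t = %.4g cm/s [%.4g, %.4g]\n",
              x$v_t, x$ci["v_t", 1], x$ci["v_t", 2]))
  cat(sprintf("  C_s = %.4g mol/cm^3, a_stir = %.4g\n", x$C_s, x$a_stir))
  invisible(x)
}

#' Osmotic context for converting flow velocity to permeability
#'
#' @param C_osm near-membrane osmolyte concentration, mol/cm^3 (by
#'   convention the fitted near-membrane value C_s, since the driving force
#'   acts at the interface).
#' @param chi osmotic coefficient in (0, 2], default 1 (ideal solute).
#' @param V_w_molar partial molar volume of water, cm^3/mol.
#' @return Object of class \code{osmotic_context}.
#' @export
osmotic_context <- function(C_osm, chi = 1,
                            V_w_molar = af_constants$V_w_molar) {
  .check_positive(C_osm = C_osm, V_w_molar = V_w_molar)
  if (chi <= 0 || chi > 2) stop("chi must lie in (0, 2]", call. = FALSE)
  structure(list(C_osm = C_osm, chi = chi, V_w_molar = V_w_molar),
            class = "osmotic_context")
}

#' Membrane permeability from transmembrane flow velocity
#'
#' \deqn{P_f = \frac{v_t}{\chi\, C_{osm}\, V_w}} converts the volume-flow
#' velocity obtained from an unstirred-layer profile fit into the membrane
#' osmotic permeability.
#'
#' @param v_t transmembrane volume-flow velocity, cm/s.
#' @param ctx an \code{\link{osmotic_context}}.
#' @return P_f, cm/s.
#' @examples
#' pf_from_velocity(1e-4, osmotic_context(mM_to_molcm3(100)))  # ~0.056 cm/s
#' @export
pf_from_velocity <- function(v_t, ctx) {
  stopifnot(inherits(ctx, "osmotic_context"))
  v_t / (ctx$chi * ctx$C_osm * ctx$V_w_molar)
}
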