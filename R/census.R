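#' Channel count from macroscopic conductance
#'
#' For ion-conducting channels the membrane's macroscopic conductance G is
#' the single-channel conductance g times the number of reconstituted
#' channels, so \eqn{n = G/g}.  The count is returned as a real number
#' (ensemble average); rounding is left to the caller.  The electrical
#' census undercounts channels that conduct water but are electrically
#' silent (inactivated) -- see \code{\link{pf_from_conductance_slope}}.
#'
#' @param G macroscopic membrane conductance, S (>= 0).
#' @param g single-channel conductance, S (> 0).
#' @return Channel count (real-valued).
#' @examples
#' channels_from_conductance(2e-9, 2e-12)  # 1000
#' @export
channels_from_conductance <- function(G, g) {
  if (!is.numeric(g) || g <= 0) stop("g must be > 0", call. = FALSE)
  if (any(G < 0)) stop("G must be >= 0", call. = FALSE)
  G / g
}

#' Permeability-versus-predictor regression data
#'
#' Holds paired observations of ensemble membrane permeability P_f against
#' a channel-abundance predictor: either the macroscopic conductance G
#' (electrical census) or the channel surface density (FCS/AFM census).
#'
#' @param x predictor values (S, or channels/cm^2); >= 3 points.
#' @param P_f ensemble permeabilities, cm/s.
#' @param kind \code{"conductance"} or \code{"density"}.
#' @return Object of class \code{slope_census}.
#' @export
slope_census <- function(x, P_f, kind = c("conductance", "density")) {
  kind <- match.arg(kind)
  if (length(x) != length(P_f)) stop("x and P_f lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need >= 3 points for a slope census", call. = FALSE)
  structure(list(x = x, P_f = P_f, kind = kind), class = "slope_census")
}

# internal: OLS slope with CI, shared by the two slope methods
.census_regression <- function(census, conf = 0.95) {
  fit <- stats::lm(census$P_f ~ census$x)
  cf <- stats::coef(fit)
  ci <- suppressWarnings(stats::confint(fit, level = conf))
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       slope_ci = ci[2, ], intercept_ci = ci[1, ], model = fit)
}

#' Unitary permeability from a P_f-versus-conductance slope
#'
#' With n = G/g channels on a membrane of area A, the ensemble permeability
#' is \deqn{P_f = \frac{n\, p_f}{A} = \frac{p_f}{A g} G,} so regressing P_f
#' on G gives \eqn{p_f = slope \times A g}.  The regression intercept is the
#' channel-free (lipid background) permeability.
#'
#' If a fraction s of the channels is electrically silent yet still
#' conducts water, the conductance census sees only (1-s) n channels and
#' the naive slope estimate overestimates p_f by exactly 1/(1-s); supply
#' \code{silent_fraction} to correct for it when it is known (for KcsA,
#' about 0.9).
#'
#' @param census a \code{\link{slope_census}} with \code{kind = "conductance"}.
#' @param A membrane area, cm^2.
#' @param g single-channel conductance, S.
#' @param silent_fraction fraction of electrically silent (but
#'   water-conducting) channels in [0, 1); default 0.
#' @param conf confidence level for the slope interval.
#' @return List of class \code{pf_slope_fit} with \code{p_f} (cm^3/s),
#'   \code{p_f_ci}, \code{lipid_background} (cm/s, the intercept),
#'   \code{slope}, \code{slope_ci}, logical \code{slope_significant} (FALSE
#'   when the CI spans 0, accompanied by a warning) and the \code{lm} fit.
#' @export
pf_from_conductance_slope <- function(census, A, g, silent_fraction = 0,
                                      conf = 0.95) {
  stopifnot(inherits(census, "slope_census"), census$kind == "conductance")
  .check_positive(A = A, g = g)
  if (silent_fraction < 0 || silent_fraction >= 1) {
    stop("silent_fraction must lie in [0, 1)", call. = FALSE)
  }
  reg <- .census_regression(census, conf)
  corr <- 1 - silent_fraction
  p_f <- reg$slope * A * g * corr
  significant <- prod(reg$slope_ci) > 0
  if (!significant) {
    warning("slope confidence interval spans zero: p_f estimate is not significant")
  }
  structure(list(p_f = p_f, p_f_ci = reg$slope_ci * A * g * corr,
                 lipid_background = reg$intercept,
                 intercept_ci = reg$intercept_ci,
                 slope = reg$slope, slope_ci = reg$slope_ci,
                 slope_significant = significant,
                 silent_fraction = silent_fraction, model = reg$model),
            class = "pf_slope_fit")
}

#' Unitary permeability from a P_f-versus-density slope
#'
#' When the predictor is the channel surface density (channels/cm^2,
#' typically from the FCS census), the slope of P_f against density is
#' directly the unitary permeability in cm^3/s, and the intercept is the
#' lipid background permeability.
#'
#' @param census a \code{\link{slope_census}} with \code{kind = "density"}.
#' @param conf confidence level.
#' @return As \code{\link{pf_from_conductance_slope}}.
#' @export
pf_from_density_slope <- function(census, conf = 0.95) {
  stopifnot(inherits(census, "slope_census"), census$kind == "density")
  reg <- .census_regression(census, conf)
  significant <- prod(reg$slope_ci) > 0
  if (!significant) {
    warning("slope confidence interval spans zero: p_f estimate is not significant")
  }
  structure(list(p_f = reg$slope, p_f_ci = reg$slope_ci,
                 lipid_background = reg$intercept,
                 intercept_ci = reg$intercept_ci,
                 slope = reg$slope, slope_ci = reg$slope_ci,
                 slope_significant = significant,
                 silent_fraction = 0, model = reg$model),
            class = "pf_slope_fit")
}

#' @export
print.pf_slope_fit <- function(x, ...) {
  cat(sprintf("Slope census: p_f = %.4g cm^3/s [%.4g, %.4g]%s\n",
              x$p_f, x$p_f_ci[1], x$p_f_ci[2],
              if (x$slope_significant) "" else "  (NOT significant)"))
  cat(sprintf("  lipid background P_f = %.4g cm/s\n", x$lipid_background))
  invisible(x)
}

#' FCS two-step particle-counting census
#'
#' Large unilamellar vesicles are too small for direct protein counting in
#' the confocal volume, so counting proceeds in two steps: the fluorescent
#' proteoliposomes are counted first, then dissolved in detergent and the
#' labeled protein-containing micelles counted.  In the monomer-micelle
#' limit the count ratio, corrected for labeling efficiency, gives the
#' average number of labeled protomers per vesicle.
#'
#' @param vesicle_count particle count (or concentration) before detergent.
#' @param micelle_count particle count after detergent, same units.
#' @param protomers_per_oligomer protomers per functional oligomer (e.g. 4
#'   for a tetrameric channel).
#' @param labeling_efficiency fraction of protomers carrying a label, in
#'   (0, 1].
#' @param bare_fraction fraction of protein-free vesicles in [0, 1).
#' @return Object of class \code{fcs_census}.
#' @export
fcs_census <- function(vesicle_count, micelle_count,
                       protomers_per_oligomer = 1,
                       labeling_efficiency = 1,
                       bare_fraction = 0) {
  if (vesicle_count <= 0) stop("vesicle_count must be > 0", call. = FALSE)
  if (micelle_count < 0) stop("micelle_count must be >= 0", call. = FALSE)
  if (labeling_efficiency <= 0 || labeling_efficiency > 1) {
    stop("labeling_efficiency must lie in (0, 1]", call. = FALSE)
  }
  if (bare_fraction < 0 || bare_fraction >= 1) {
    stop("bare_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (protomers_per_oligomer < 1 ||
      protomers_per_oligomer != round(protomers_per_oligomer)) {
    stop("protomers_per_oligomer must be a positive integer", call. = FALSE)
  }
  structure(list(vesicle_count = vesicle_count,
                 micelle_count = micelle_count,
                 protomers_per_oligomer = protomers_per_oligomer,
                 labeling_efficiency = labeling_efficiency,
                 bare_fraction = bare_fraction),
            class = "fcs_census")
}

#' Channels per vesicle from an FCS census
#'
#' Converts the two-step counts into average protomers and oligomers per
#' vesicle (ensemble averages over all counted vesicles) and, when a bare
#' (protein-free) vesicle fraction is given, also per proteoliposome.
#' Labeling efficiencies below \code{efficiency_warn} trigger a warning,
#' because an insufficiently labeled sample cannot resolve the oligomeric
#' state.
#'
#' @param census an \code{\link{fcs_census}}.
#' @param efficiency_warn warn when labeling efficiency is below this.
#' @return List with \code{protomers_per_vesicle},
#'   \code{oligomers_per_vesicle}, \code{oligomers_per_proteoliposome} and
#'   logical \code{reconstituted} (FALSE with zero micelle count).
#' @examples
#' channels_per_vesicle(fcs_census(100, 800, protomers_per_oligomer = 4,
#'                                 labeling_efficiency = 0.8))
#' @export
channels_per_vesicle <- function(census, efficiency_warn = 0.8) {
  stopifnot(inherits(census, "fcs_census"))
  if (census$labeling_efficiency < efficiency_warn) {
    warning(sprintf(paste("labeling efficiency %.2f is below %.2f:",
                          "protomer counts per oligomer may be unreliable"),
                    census$labeling_efficiency, efficiency_warn))
  }
  if (census$micelle_count == 0) {
    return(list(protomers_per_vesicle = 0, oligomers_per_vesicle = 0,
                oligomers_per_proteoliposome = 0, reconstituted = FALSE))
  }
  protomers <- (census$micelle_count / census$vesicle_count) /
    census$labeling_efficiency
  oligomers <- protomers / census$protomers_per_oligomer
  per_pl <- oligomers / (1 - census$bare_fraction)
  list(protomers_per_vesicle = protomers,
       oligomers_per_vesicle = oligomers,
       oligomers_per_proteoliposome = per_pl,
       reconstituted = TRUE)
}

#' Channel surface density on a vesicle
#'
#' Helper converting oligomers per vesicle and the vesicle radius to a
#' surface density (channels/cm^2), the predictor used by
#' \code{\link{pf_from_density_slope}}.
#'
#' @param oligomers_per_vesicle average channel count per vesicle.
#' @param r0 vesicle radius, cm.
#' @return Density, channels/cm^2.
#' @export
channel_density <- function(oligomers_per_vesicle, r0) {
  .check_positive(r0 = r0)
  oligomers_per_vesicle / (4 * pi * r0^2)
}
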