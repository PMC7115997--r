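#' Light-scattering calibration
#'
#' In stopped-flow experiments the observable is the intensity of scattered
#' light, which (by a Rayleigh-Gans-Debye reduction) depends on the vesicle
#' volume through a quadratic: \deqn{I = a + b V + d V^2.}  The calibration
#' must be strictly monotone over the physical volume interval it is used
#' on, otherwise intensities cannot be inverted to volumes.
#'
#' @param a offset (intensity units).
#' @param b linear coefficient (intensity per cm^3).
#' @param d quadratic coefficient (intensity per cm^6).
#' @return Object of class \code{scatter_calibration}.
#' @export
scatter_calibration <- function(a, b, d = 0) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(d))
  structure(list(a = a, b = b, d = d), class = "scatter_calibration")
}

.check_monotone_calib <- function(calib, V_range) {
  # derivative b + 2 d V must not change sign on the interval
  dI <- calib$b + 2 * calib$d * range(V_range)
  if (prod(dI) <= 0 || all(dI == 0)) {
    stop("calibration is not strictly monotone over the volume range", call. = FALSE)
  }
  invisible(TRUE)
}

#' Forward scattering model: intensity from volume
#'
#' @param V volume(s), cm^3.
#' @param calib a \code{\link{scatter_calibration}}.
#' @return Intensity, arbitrary units.
#' @examples
#' intensity_from_volume(1, scatter_calibration(0.1, 2))  # 2.1
#' @export
intensity_from_volume <- function(V, calib) {
  stopifnot(inherits(calib, "scatter_calibration"))
  calib$a + calib$b * V + calib$d * V^2
}

#' Invert a scattering calibration: volume from intensity
#'
#' Solves \eqn{I = a + bV + dV^2} for V.  For a linear calibration (d = 0)
#' this is \eqn{(I-a)/b}; otherwise the quadratic is solved and exactly one
#' root must fall inside \code{bounds} (typically [V_eq, V0]).  Zero or two
#' in-bounds roots indicate an unusable calibration and raise an error
#' naming both roots.
#'
#' @param I intensity value(s).
#' @param calib a \code{\link{scatter_calibration}}.
#' @param bounds length-2 numeric, admissible volume interval (cm^3).
#' @return Volume(s), cm^3.
#' @export
volume_from_intensity <- function(I, calib, bounds) {
  stopifnot(inherits(calib, "scatter_calibration"),
            length(bounds) == 2, bounds[1] < bounds[2])
  if (calib$d == 0) {
    if (calib$b == 0) stop("degenerate calibration: b = d = 0", call. = FALSE)
    return((I - calib$a) / calib$b)
  }
  vapply(I, function(Ii) {
    disc <- calib$b^2 - 4 * calib$d * (calib$a - Ii)
    if (disc < 0) stop("no real root: intensity outside the calibration range",
                       call. = FALSE)
    roots <- (-calib$b + c(-1, 1) * sqrt(disc)) / (2 * calib$d)
    tol <- 1e-9 * diff(bounds)
    inb <- roots >= bounds[1] - tol & roots <= bounds[2] + tol
    if (sum(inb) != 1) {
      stop(sprintf("inversion ambiguous: roots %.6g and %.6g, %d inside bounds [%.6g, %.6g]",
                   roots[1], roots[2], sum(inb), bounds[1], bounds[2]),
           call. = FALSE)
    }
    roots[inb]
  }, numeric(1))
}

#' Convert an intensity trace to a volume trace
#'
#' @param trace an \code{\link{intensity_trace}}.
#' @param calib a \code{\link{scatter_calibration}}.
#' @param bounds admissible volume interval, cm^3 (e.g. c(V_eq, V0)).
#' @return A \code{\link{volume_trace}}.
#' @export
trace_to_volume <- function(trace, calib, bounds) {
  stopifnot(inherits(trace, "intensity_trace"))
  .check_monotone_calib(calib, bounds)
  volume_trace(trace$t, volume_from_intensity(trace$y, calib, bounds),
               meta = attr(trace, "meta"))
}

#' Estimate a scattering calibration
#'
#' When paired (V, I) observations are available the coefficients are
#' estimated by ordinary least squares on the quadratic.  When only the
#' endpoints are known -- the intensity at t = 0 (volume V0) and the plateau
#' intensity (volume V_eq) -- a linear calibration through the two points is
#' returned.  Intensity traces are conventionally normalized to I(0) = 1
#' before calibration.
#'
#' @param V volumes, cm^3.
#' @param I matching intensities.
#' @param quadratic fit the quadratic term (needs >= 3 distinct volumes).
#' @return A \code{\link{scatter_calibration}}.
#' @export
fit_calibration <- function(V, I, quadratic = TRUE) {
  stopifnot(length(V) == length(I), length(V) >= 2)
  if (quadratic && length(unique(V)) >= 3) {
    cf <- stats::coef(stats::lm(I ~ V + I(V^2)))
    scatter_calibration(unname(cf[1]), unname(cf[2]), unname(cf[3]))
  } else {
    cf <- stats::coef(stats::lm(I ~ V))
    scatter_calibration(unname(cf[1]), unname(cf[2]), 0)
  }
}

#' Two-population vesicle mixtures
#'
#' Protein reconstitution typically yields two co-existing populations:
#' bare lipid vesicles and proteoliposomes, with distinct P_f.  The observed
#' scattering signal is the weighted sum of the populations' intensities and
#' is generally biexponential.
#'
#' @param populations list of \code{\link{vesicle_spec}}.
#' @param weights numeric weights in (0, 1], summing to 1.
#' @return Object of class \code{mixture_spec}.
#' @export
mixture_spec <- function(populations, weights) {
  stopifnot(is.list(populations), length(populations) == length(weights))
  lapply(populations, function(p) stopifnot(inherits(p, "vesicle_spec")))
  if (any(weights <= 0) || any(weights > 1) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must lie in (0, 1] and sum to 1", call. = FALSE)
  }
  structure(list(populations = populations, weights = weights),
            class = "mixture_spec")
}

#' Scattered-light trace of a vesicle mixture
#'
#' Evaluates the Lambert-W deflation of each population, converts each
#' volume course to intensity through its own calibration, and sums with the
#' mixture weights.
#'
#' @param mix a \code{\link{mixture_spec}}.
#' @param calibs one \code{\link{scatter_calibration}}, recycled, or a list
#'   with one calibration per population.
#' @param t_grid output times, s, starting at 0.
#' @return An \code{\link{intensity_trace}}.
#' @export
mixture_trace <- function(mix, calibs, t_grid) {
  stopifnot(inherits(mix, "mixture_spec"))
  .check_times(t_grid)
  if (inherits(calibs, "scatter_calibration")) {
    calibs <- rep(list(calibs), length(mix$populations))
  }
  stopifnot(length(calibs) == length(mix$populations))
  I <- rep(0, length(t_grid))
  for (i in seq_along(mix$populations)) {
    V <- deflate_analytic(mix$populations[[i]], t_grid)
    I <- I + mix$weights[i] * intensity_from_volume(V, calibs[[i]])
  }
  intensity_trace(t_grid, I, meta = list(mixture = mix))
}
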