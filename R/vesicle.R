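#' Specification of an osmotically challenged vesicle population
#'
#' Bundles the geometry, osmolyte concentrations and membrane osmotic
#' permeability of one vesicle population.  Volume V0 and surface area A are
#' derived from the initial radius; the surface area is treated as
#' time-invariant during deflation (the vesicle wrinkles rather than losing
#' membrane).
#'
#' @param r0 initial radius, cm (use \code{nm_to_cm} at the boundary).
#' @param c_in0 initial internal osmolyte concentration, mol/cm^3.
#' @param c_out external osmolyte concentration (constant), mol/cm^3.
#' @param P_f membrane osmotic permeability, cm/s.
#' @param V_w_molar partial molar volume of water, cm^3/mol.
#' @return Object of class \code{vesicle_spec} with fields \code{r0},
#'   \code{V0}, \code{A}, \code{c_in0}, \code{c_out}, \code{P_f},
#'   \code{V_w_molar} and the derived gradient \code{c_delta = c_out - c_in0}.
#' @examples
#' vesicle_spec(r0 = nm_to_cm(100), c_in0 = mM_to_molcm3(290),
#'              c_out = mM_to_molcm3(300), P_f = 0.01)
#' @export
vesicle_spec <- function(r0, c_in0, c_out, P_f,
                         V_w_molar = af_constants$V_w_molar) {
  .check_positive(r0 = r0, c_in0 = c_in0, c_out = c_out, P_f = P_f,
                  V_w_molar = V_w_molar)
  structure(list(
    r0 = r0,
    V0 = (4 / 3) * pi * r0^3,
    A  = 4 * pi * r0^2,
    c_in0 = c_in0,
    c_out = c_out,
    c_delta = c_out - c_in0,
    P_f = P_f,
    V_w_molar = V_w_molar
  ), class = "vesicle_spec")
}

#' @export
print.vesicle_spec <- function(x, ...) {
  cat("Vesicle population\n")
  cat(sprintf("  r0    = %.4g cm (%.4g nm)\n", x$r0, x$r0 * 1e7))
  cat(sprintf("  c_in0 = %.4g mM, c_out = %.4g mM\n",
              molcm3_to_mM(x$c_in0), molcm3_to_mM(x$c_out)))
  cat(sprintf("  P_f   = %.4g cm/s\n", x$P_f))
  invisible(x)
}

#' Time-series containers for deflation experiments
#'
#' \code{volume_trace} holds a vesicle volume time series (cm^3);
#' \code{intensity_trace} a scattered-light intensity time series (arbitrary
#' units).  Times must start at zero and be strictly increasing.
#'
#' @param t times, s.
#' @param V volumes, cm^3.
#' @param I intensities, arbitrary units.
#' @param meta optional named list carried along (e.g. ground truth from a
#'   generator).
#' @return Object of class \code{volume_trace} / \code{intensity_trace}; both
#'   inherit from \code{af_trace} and behave as two-column data frames.
#' @name traces
NULL

.check_times <- function(t) {
  if (length(t) < 1 || t[1] != 0) stop("times must start at 0", call. = FALSE)
  if (any(diff(t) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  invisible(TRUE)
}

#' @rdname traces
#' @export
volume_trace <- function(t, V, meta = list()) {
  .check_times(t)
  if (length(V) != length(t)) stop("t and V lengths differ", call. = FALSE)
  structure(list(t = t, y = V), class = c("volume_trace", "af_trace"),
            meta = meta)
}

#' @rdname traces
#' @export
intensity_trace <- function(t, I, meta = list()) {
  .check_times(t)
  if (length(I) != length(t)) stop("t and I lengths differ", call. = FALSE)
  structure(list(t = t, y = I), class = c("intensity_trace", "af_trace"),
            meta = meta)
}

#' @export
print.af_trace <- function(x, ...) {
  kind <- if (inherits(x, "volume_trace")) "volume" else "intensity"
  cat(sprintf("%s trace: %d points, t in [0, %.4g] s, y in [%.4g, %.4g]\n",
              kind, length(x$t), max(x$t), min(x$y), max(x$y)))
  invisible(x)
}

#' Osmotic vesicle deflation by direct ODE integration
#'
#' Integrates the deflation law
#' \deqn{dV/dt = A P_f V_w (c_{in}(t) - c_{out}), \qquad
#'       c_{in}(t) = c_{in,0} V_0 / V(t)}
#' (osmolyte conserved inside the vesicle, surface area constant) with a
#' stiff-capable solver at relative tolerance 1e-10.
#'
#' @param spec a \code{\link{vesicle_spec}}.
#' @param t_grid output times, s, starting at 0.
#' @return A \code{\link{volume_trace}} on \code{t_grid}.
#' @examples
#' sp <- vesicle_spec(nm_to_cm(100), mM_to_molcm3(290), mM_to_molcm3(300), 0.01)
#' tr <- deflate_ode(sp, seq(0, 0.5, length.out = 200))
#' @export
deflate_ode <- function(spec, t_grid) {
  stopifnot(inherits(spec, "vesicle_spec"))
  .check_times(t_grid)
  rhs <- function(t, state, parms) {
    V <- state[1]
    c_in <- parms$c_in0 * parms$V0 / V
    list(parms$A * parms$P_f * parms$V_w_molar * (c_in - parms$c_out))
  }
  sol <- deSolve::ode(y = c(V = spec$V0), times = t_grid, func = rhs,
                      parms = spec, method = "lsoda",
                      rtol = 1e-10, atol = spec$V0 * 1e-12)
  diagn <- attr(sol, "istate")
  if (is.null(diagn) || nrow(sol) != length(t_grid) || anyNA(sol[, "V"])) {
    stop("deflate_ode: integration failed (see deSolve diagnostics)", call. = FALSE)
  }
  volume_trace(t_grid, as.numeric(sol[, "V"]),
               meta = list(spec = spec, model = "ode"))
}

#' Osmotic vesicle deflation, Lambert-W closed form
#'
#' The deflation ODE has the analytical solution
#' \deqn{V(t) = V_0 \frac{c_{in,0}}{c_{out}}\left[1 + W\!\left(
#'   \frac{c_\Delta}{c_{in,0}}
#'   \exp\!\left(\frac{c_\Delta}{c_{in,0}} -
#'   \frac{A P_f V_w c_{out}^2}{V_0 c_{in,0}} t\right)\right)\right]}
#' with \eqn{c_\Delta = c_{out} - c_{in,0}} and W the principal branch of the
#' Lambert function (\eqn{W(x)e^{W(x)} = x}).  The principal branch is the
#' one continuous with V(0) = V0: shrinking (\eqn{c_\Delta > 0}) keeps the
#' argument positive, moderate swelling (\eqn{-1 < c_\Delta/c_{in,0} < 0})
#' keeps it in (-1/e, 0).  Arguments at or below -1/e (extreme swelling)
#' leave the principal-branch domain and raise an error.
#'
#' @param spec a \code{\link{vesicle_spec}}.
#' @param t times, s (any non-negative vector).
#' @return Volumes at \code{t}, cm^3 (bare numeric; use
#'   \code{\link{volume_trace}} to wrap a grid starting at 0).
#' @examples
#' sp <- vesicle_spec(nm_to_cm(100), mM_to_molcm3(290), mM_to_molcm3(300), 0.01)
#' deflate_analytic(sp, c(0, 0.06, 1))
#' @export
deflate_analytic <- function(spec, t) {
  stopifnot(inherits(spec, "vesicle_spec"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  ratio <- spec$c_delta / spec$c_in0
  if (ratio <= -1) {
    stop(paste("Lambert-W principal branch requires c_delta/c_in0 > -1;",
               "this swelling regime leaves the branch domain"), call. = FALSE)
  }
  k <- spec$A * spec$P_f * spec$V_w_molar * spec$c_out^2 / (spec$V0 * spec$c_in0)
  arg <- ratio * exp(ratio - k * t)
  if (any(arg < -exp(-1))) {
    stop("Lambert-W argument below -1/e: outside the principal branch", call. = FALSE)
  }
  w <- vapply(arg, pracma::lambertWp, numeric(1))
  spec$V0 * (spec$c_in0 / spec$c_out) * (1 + w)
}

#' Equilibrium volume of a deflating/swelling vesicle
#'
#' The limit \eqn{V(\infty) = V_0 c_{in,0}/c_{out}} at which the internal
#' concentration has equilibrated with the external solution.
#'
#' @param spec a \code{\link{vesicle_spec}}.
#' @return Equilibrium volume, cm^3.
#' @export
equilibrium_volume <- function(spec) {
  stopifnot(inherits(spec, "vesicle_spec"))
  spec$V0 * spec$c_in0 / spec$c_out
}

#' Linearized deflation time constant
#'
#' For small osmotic gradients the deflation relaxes approximately
#' exponentially with \deqn{\tau = \frac{r_0\, c_{in,0}}{3 P_f V_w c_{out}^2}.}
#' Used to initialize fits and to convert between tau and P_f.
#'
#' @param spec a \code{\link{vesicle_spec}}.
#' @return Time constant, s.
#' @export
deflation_tau <- function(spec) {
  stopifnot(inherits(spec, "vesicle_spec"))
  spec$r0 * spec$c_in0 / (3 * spec$P_f * spec$V_w_molar * spec$c_out^2)
}
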