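#' Single-file channel geometry
#'
#' Describes the single-file region of a water channel: the number N of water
#' molecules in the column, the water-water spacing z, the column length
#' L = N z, and optionally the count N_H of pore-lining residues able to
#' donate or accept hydrogen bonds to the column.
#'
#' Any two of \code{N}, \code{L}, \code{z} determine the third; if all three
#' are supplied they must satisfy L = N z to within 1e-9 relative.
#'
#' @param N integer (>= 1), number of single-file water molecules.
#' @param L pore (column) length, cm.
#' @param z water-water spacing, cm; defaults to one water diameter
#'   (2.8e-8 cm) when it cannot be derived from \code{N} and \code{L}.
#' @param N_H optional integer (>= 0), hydrogen-bond donor/acceptor count.
#' @return An object of class \code{channel_geometry} with fields
#'   \code{N}, \code{L}, \code{z}, \code{N_H} and a \code{defaults_used}
#'   character vector recording any default that was filled in.
#' @examples
#' channel_geometry(N = 7)                      # gramicidin A
#' channel_geometry(N = 4, N_H = 20)            # KcsA selectivity filter
#' channel_geometry(L = 2.24e-7, z = 2.8e-8)    # N inferred = 8
#' @export
channel_geometry <- function(N = NULL, L = NULL, z = NULL, N_H = NULL) {
  defaults_used <- character()
  if (is.null(z) && !is.null(N) && !is.null(L)) {
    z <- L / N
  } else if (is.null(z)) {
    z <- af_constants$z_water
    defaults_used <- c(defaults_used, "z = 2.8e-8 cm (one water diameter)")
  }
  if (is.null(N) && !is.null(L)) N <- L / z
  if (is.null(L) && !is.null(N)) L <- N * z
  if (is.null(N) || is.null(L)) {
    stop("channel_geometry: supply at least N, or L (z defaults to one water diameter)",
         call. = FALSE)
  }
  .check_positive(N = N, L = L, z = z)
  if (abs(L - N * z) > 1e-9 * L) {
    stop(sprintf("inconsistent geometry: L = %.4g but N*z = %.4g (must agree to 1e-9 relative)",
                 L, N * z), call. = FALSE)
  }
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  if (!is.null(N_H) && (N_H < 0 || N_H != round(N_H))) {
    stop("N_H must be a non-negative integer", call. = FALSE)
  }
  structure(list(N = N, L = L, z = z, N_H = N_H,
                 defaults_used = defaults_used),
            class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat("Single-file channel geometry\n")
  cat(sprintf("  N   = %.3g water molecules\n", x$N))
  cat(sprintf("  z   = %.3g cm\n", x$z))
  cat(sprintf("  L   = %.3g cm\n", x$L))
  if (!is.null(x$N_H)) cat(sprintf("  N_H = %d hydrogen-bonding residues\n", as.integer(x$N_H)))
  if (length(x$defaults_used)) cat("  defaults:", paste(x$defaults_used, collapse = "; "), "\n")
  invisible(x)
}

#' Osmotic work to move a single-file water column
#'
#' The work required to move the N water molecules of a single-file column
#' across the membrane under an osmotic pressure difference:
#' \deqn{W = v_w N \Delta\Pi}
#'
#' @param N number of water molecules in the column (>= 0).
#' @param delta_Pi osmotic pressure difference, dyn/cm^2.
#' @param v_w volume of one water molecule, cm^3.
#' @return Work, erg.
#' @examples
#' # 8 waters, 100 mM gradient at 298 K
#' osmotic_work(8, osmotic_pressure(mM_to_molcm3(100), 298))
#' @export
osmotic_work <- function(N, delta_Pi, v_w = af_constants$v_w) {
  if (!is.numeric(N) || N < 0) stop("N must be >= 0", call. = FALSE)
  .check_positive(v_w = v_w)
  v_w * N * delta_Pi
}

#' Full chain of the classical single-file (hard-sphere) derivation
#'
#' Walks the classical force-balance derivation of unitary channel
#' permeability from end to end, returning every intermediate: the osmotic
#' work \eqn{W = v_w N \Delta\Pi}, the osmotic force \eqn{F_\Pi = W/L}
#' (which assumes W grows linearly with pore length L -- the hard-sphere
#' assumption), the friction coefficient \eqn{\gamma = kT/D_1}, the column
#' velocity \eqn{v = v_w \Delta\Pi/(L\gamma)} from the steady-state balance
#' \eqn{F_\Pi = F_\gamma = N\gamma v}, and the flux \eqn{\Phi = N v/L}.
#'
#' The linear length dependence of W is a modelling assumption valid for
#' hard spheres rolling through a homogeneous pipe; channels with
#' constriction zones or unevenly distributed hydrogen-bonding residues
#' violate it, which is why the downstream prediction p_f ~ 1/L fails
#' experimentally (see \code{\link{fit_log_linear}}).
#'
#' @param geometry a \code{\link{channel_geometry}}.
#' @param delta_Pi osmotic pressure difference, dyn/cm^2.
#' @param D_1 diffusion coefficient of a hypothetical isolated water molecule
#'   in the pore, cm^2/s.
#' @param v_w volume of one water molecule, cm^3.
#' @param T_K absolute temperature, K.
#' @return A list of class \code{finkelstein_derivation} with fields
#'   \code{W} (erg), \code{F_Pi}, \code{F_gamma} (dyn), \code{gamma} (g/s),
#'   \code{v} (cm/s), \code{Phi} (molecules/s), \code{delta_Pi},
#'   \code{delta_n_s} (molecules/cm^3) and \code{p_f} (cm^3/s, = Phi/delta_n_s).
#' @export
finkelstein_chain <- function(geometry, delta_Pi, D_1,
                              v_w = af_constants$v_w,
                              T_K = af_constants$T_default) {
  if (!inherits(geometry, "channel_geometry")) {
    stop("geometry must be a channel_geometry object", call. = FALSE)
  }
  .check_positive(D_1 = D_1, v_w = v_w, T_K = T_K)
  kT <- af_constants$kB_erg * T_K
  gamma <- kT / D_1                       # friction coefficient, g/s
  W <- v_w * geometry$N * delta_Pi        # osmotic work
  F_Pi <- W / geometry$L                  # assumes W linear in L
  v <- v_w * delta_Pi / (geometry$L * gamma)
  F_gamma <- geometry$N * gamma * v
  Phi <- geometry$N * v / geometry$L      # molecules/s
  delta_n_s <- delta_Pi / kT              # osmolyte number-density difference
  p_f <- if (delta_n_s != 0) Phi / delta_n_s else
    v_w * D_1 / (geometry$z * geometry$L) # limit value, identical algebraically
  structure(list(W = W, F_Pi = F_Pi, F_gamma = F_gamma, gamma = gamma,
                 v = v, Phi = Phi, delta_Pi = delta_Pi,
                 delta_n_s = delta_n_s, p_f = p_f),
            class = "finkelstein_derivation")
}

#' Unitary permeability from pore geometry (classical prediction)
#'
#' The classical single-file result \deqn{p_f = v_w D_1/(z L),} i.e. p_f
#' inversely proportional to pore length.  It rests on the hard-sphere
#' assumptions that the osmotic work grows linearly with L and that column
#' mobility scales as D_1/N; measured permeabilities instead fall
#' exponentially with N, so this function represents the hard-sphere limit,
#' not a validated predictor.
#'
#' @param v_w volume of one water molecule, cm^3.
#' @param D_1 single-molecule pore diffusion coefficient, cm^2/s.
#' @param z water-water spacing, cm.
#' @param L pore length, cm.
#' @return Unitary osmotic permeability p_f, cm^3/s.
#' @examples
#' pf_finkelstein(D_1 = 1e-5, z = 2.8e-8, L = 2.24e-7)  # ~4.8e-14 cm^3/s
#' @export
pf_finkelstein <- function(v_w = af_constants$v_w, D_1, z, L) {
  .check_positive(v_w = v_w, D_1 = D_1, z = z, L = L)
  v_w * D_1 / (z * L)
}

#' Unitary permeability from column mobility
#'
#' \deqn{p_f = D_w v_w / z^2} links p_f to the diffusion coefficient D_w of
#' a water molecule moving with the column; the relation is exact for fully
#' occupied single-file channels and is routinely used to extract p_f from
#' molecular dynamics trajectories.  It makes no assumption about how D_w
#' arises, so p_f and D_w are interchangeable descriptors.
#'
#' @param D_w column water diffusion coefficient, cm^2/s.
#' @param v_w volume of one water molecule, cm^3.
#' @param z water-water spacing, cm.
#' @return Unitary osmotic permeability p_f, cm^3/s.
#' @examples
#' pf_from_mobility(5e-5)   # bulk-like mobility (GlpF): ~1.9e-12 cm^3/s
#' pf_from_mobility(4e-9)   # four orders below bulk (AQP0): ~1.5e-16 cm^3/s
#' @export
pf_from_mobility <- function(D_w, v_w = af_constants$v_w,
                             z = af_constants$z_water) {
  if (!is.numeric(D_w) || D_w < 0) stop("D_w must be >= 0", call. = FALSE)
  .check_positive(v_w = v_w, z = z)
  D_w * v_w / z^2
}

#' Column mobility implied by a unitary permeability
#'
#' Inverse of \code{\link{pf_from_mobility}}: \eqn{D_w = p_f z^2 / v_w}.
#'
#' @param p_f unitary osmotic permeability, cm^3/s.
#' @inheritParams pf_from_mobility
#' @return D_w, cm^2/s.
#' @export
mobility_from_pf <- function(p_f, v_w = af_constants$v_w,
                             z = af_constants$z_water) {
  if (!is.numeric(p_f) || p_f < 0) stop("p_f must be >= 0", call. = FALSE)
  .check_positive(v_w = v_w, z = z)
  p_f * z^2 / v_w
}

#' Predicted osmotic-to-diffusive permeability ratio
#'
#' The classical single-file model predicts \eqn{p_f/p_d = N}.  The
#' prediction was never confirmed experimentally: measured ratios are about
#' 5 for gramicidin A (where molecular dynamics shows N = 7 waters in the
#' pore) and about 13 for AQP1 (whose structure accommodates about 8).  The
#' ratio is therefore an unreliable way of counting pore waters; this
#' function returns the model value and should be read with that caveat.
#'
#' @param N number of single-file water molecules (>= 1).
#' @return The predicted ratio, numerically equal to N.
#' @export
pf_pd_ratio_prediction <- function(N) {
  if (!is.numeric(N) || N < 1) stop("N must be >= 1", call. = FALSE)
  N
}
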