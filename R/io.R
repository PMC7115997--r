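#' File input/output
#'
#' All on-disk formats are header-based delimited text with units encoded in
#' the column names (time_s, volume_cm3, intensity_au, x_um, c_mM,
#' temperature_K, ...), so a file can never be read in the wrong unit
#' silently.  Conversion to internal CGS happens here and only here.
#' Malformed rows are rejected with their line numbers.
#'
#' @name aquaflux_io
NULL

.read_table_checked <- function(path, required, sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df
}

.bad_rows <- function(ok, path, what) {
  if (!all(ok)) {
    # +1 for header line
    stop(sprintf("%s: %s in data line(s) %s", path, what,
                 paste(which(!ok) + 1, collapse = ", ")), call. = FALSE)
  }
}

#' Read / write a deflation trace CSV
#'
#' Columns: \code{time_s} plus either \code{volume_cm3} or
#' \code{intensity_au}.  Times must start at 0 and be strictly increasing.
#'
#' @param path CSV file path.
#' @param trace a \code{\link{volume_trace}} or \code{\link{intensity_trace}}.
#' @return \code{read_trace}: the typed trace object. \code{write_trace}:
#'   the path, invisibly.
#' @export
read_trace <- function(path) {
  df <- .read_table_checked(path, "time_s")
  kind <- intersect(c("volume_cm3", "intensity_au"), names(df))
  if (length(kind) != 1) {
    stop(sprintf("%s: need exactly one of columns volume_cm3, intensity_au", path),
         call. = FALSE)
  }
  .bad_rows(is.finite(df$time_s), path, "non-numeric time_s")
  .bad_rows(is.finite(df[[kind]]), path, sprintf("non-numeric %s", kind))
  if (df$time_s[1] != 0 || any(diff(df$time_s) <= 0)) {
    stop(sprintf("%s: time_s must start at 0 and increase strictly", path),
         call. = FALSE)
  }
  if (kind == "volume_cm3") volume_trace(df$time_s, df$volume_cm3)
  else intensity_trace(df$time_s, df$intensity_au)
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "af_trace"))
  col <- if (inherits(trace, "volume_trace")) "volume_cm3" else "intensity_au"
  df <- stats::setNames(data.frame(trace$t, trace$y), c("time_s", col))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an unstirred-layer profile CSV
#'
#' Columns: \code{x_um} (distance from the membrane, micrometres) and
#' \code{c_mM} (solute concentration, mM).  Converted to cm and mol/cm^3.
#'
#' @param path CSV file path.
#' @param D_cm2_s solute diffusion coefficient, cm^2/s (from tables; not
#'   part of the scan file).
#' @return A \code{\link{concentration_profile}}.
#' @export
read_profile <- function(path, D_cm2_s) {
  df <- .read_table_checked(path, c("x_um", "c_mM"))
  .bad_rows(is.finite(df$x_um), path, "non-numeric x_um")
  .bad_rows(is.finite(df$c_mM) & df$c_mM > 0, path, "non-positive or non-numeric c_mM")
  concentration_profile(um_to_cm(df$x_um), mM_to_molcm3(df$c_mM), D_cm2_s)
}

#' @rdname read_profile
#' @param profile a \code{\link{concentration_profile}}.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "concentration_profile"))
  df <- data.frame(x_um = cm_to_um(profile$x), c_mM = molcm3_to_mM(profile$C))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an Arrhenius temperature-series CSV
#'
#' Columns: \code{temperature_K}, \code{Pf_value}, \code{Pf_units}
#' (informational; all rows must agree).
#'
#' @param path CSV file path.
#' @return An \code{\link{arrhenius_series}}.
#' @export
read_arrhenius <- function(path) {
  df <- .read_table_checked(path, c("temperature_K", "Pf_value"))
  .bad_rows(is.finite(df$temperature_K) & df$temperature_K > 0, path,
            "invalid temperature_K")
  .bad_rows(is.finite(df$Pf_value) & df$Pf_value > 0, path, "invalid Pf_value")
  if ("Pf_units" %in% names(df) && length(unique(df$Pf_units)) > 1) {
    stop(sprintf("%s: mixed Pf_units in one series", path), call. = FALSE)
  }
  arrhenius_series(df$temperature_K, df$Pf_value,
                   meta = list(units = if ("Pf_units" %in% names(df))
                     df$Pf_units[1] else NA_character_))
}

#' Read a channel catalog TSV
#'
#' Tab-separated columns: \code{name}, \code{N}, \code{N_H},
#' \code{pf_cm3_s}, \code{dG_kcal_mol}, \code{quality}.  Empty cells are
#' allowed for optional fields.
#'
#' @param path TSV file path.
#' @return A catalog data frame usable by \code{\link{fit_log_linear}}.
#' @export
read_catalog <- function(path) {
  df <- .read_table_checked(path, c("name", "pf_cm3_s"), sep = "\t")
  for (col in c("N", "N_H", "dG_kcal_mol")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  if (!"quality" %in% names(df)) df$quality <- "estimated"
  .bad_rows(is.na(df$pf_cm3_s) | df$pf_cm3_s > 0, path, "non-positive pf_cm3_s")
  bad_q <- !(df$quality %in% c("direct_count", "estimated"))
  .bad_rows(!bad_q, path, "unknown quality class")
  df
}

#' Read an FCS census TSV
#'
#' Tab-separated columns: \code{sample}, \code{vesicle_count},
#' \code{micelle_count}, \code{protomers_per_oligomer},
#' \code{labeling_efficiency}; optional \code{bare_fraction}.
#'
#' @param path TSV file path.
#' @return A named list of \code{\link{fcs_census}} objects, one per sample
#'   row.
#' @export
read_census <- function(path) {
  df <- .read_table_checked(path, c("sample", "vesicle_count", "micelle_count",
                                    "protomers_per_oligomer",
                                    "labeling_efficiency"), sep = "\t")
  if (!"bare_fraction" %in% names(df)) df$bare_fraction <- 0
  .bad_rows(is.finite(df$vesicle_count) & df$vesicle_count > 0, path,
            "invalid vesicle_count")
  .bad_rows(is.finite(df$micelle_count) & df$micelle_count >= 0, path,
            "invalid micelle_count")
  out <- lapply(seq_len(nrow(df)), function(i) {
    fcs_census(df$vesicle_count[i], df$micelle_count[i],
               df$protomers_per_oligomer[i], df$labeling_efficiency[i],
               df$bare_fraction[i])
  })
  stats::setNames(out, df$sample)
}

#' Provenance record for an analysis run
#'
#' Every CLI analysis writes a provenance record alongside its results:
#' which physical defaults were in effect (temperature, molecular water
#' volume, partial molar volume, osmotic coefficient), the seed, the
#' package version, and the call parameters.  No default constant is ever
#' applied silently.
#'
#' @param params named list of call parameters.
#' @param defaults named list of physical defaults in effect.
#' @param seed seed used, or NA.
#' @return A list of class \code{af_provenance}; serialize with
#'   \code{\link{write_provenance}}.
#' @export
provenance_record <- function(params = list(), defaults = list(
                                T_K = af_constants$T_default,
                                v_w_cm3 = af_constants$v_w,
                                V_w_molar_cm3_mol = af_constants$V_w_molar,
                                chi = 1),
                              seed = NA) {
  structure(list(
    package = "aquaflux",
    version = as.character(utils::packageVersion("aquaflux")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    params = params,
    defaults = defaults
  ), class = "af_provenance")
}

#' @rdname provenance_record
#' @param prov an \code{af_provenance} record.
#' @param path output JSON path.
#' @export
write_provenance <- function(prov, path) {
  stopifnot(inherits(prov, "af_provenance"))
  jsonlite::write_json(unclass(prov), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
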