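# CSV interchange: one file per release curve with columns time_h and
# conversion (or absorbance), plus an optional YAML sidecar with the
# same basename carrying the experiment condition, calibration and
# generation metadata.

sidecar_path <- function(path) paste0(sub("\\.[^.]+$", "", path), ".yml")

condition_to_list <- function(cond) {
  if (is.null(cond)) return(NULL)
  cond[c("temperature", "pH", "x_aa", "copolymer_conc", "drug_load",
         "label")]
}

condition_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  experiment_condition(x$temperature, x$pH %||% 7, x$x_aa %||% 0,
                       x$copolymer_conc %||% 0,
                       x$drug_load %||% 2e-4, x$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a release curve to CSV (with metadata sidecar)
#'
#' Writes `time_h,conversion` rows to `path` and, when the curve has a
#' condition or generating spec attached, a YAML sidecar with the same
#' basename holding the experiment condition, noise level and seed.
#'
#' @param curve A [release_curve()].
#' @param path Output CSV path.
#' @param calibration Optional `list(slope=, offset=)`; when given, an
#'   `absorbance` column is written instead of `conversion` and the
#'   calibration is stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_release_csv <- function(curve, path, calibration = NULL) {
  stopifnot(inherits(curve, "release_curve"))
  meta <- list(condition = condition_to_list(curve$condition))
  spec <- attr(curve, "spec")
  if (!is.null(spec))
    meta$generator <- list(k1 = spec$truth$k1,
                           k_minus1 = spec$truth$k_minus1,
                           noise_sd = spec$noise_sd, seed = spec$seed)
  if (!is.null(calibration)) {
    if (is.null(calibration$slope) || calibration$slope <= 0)
      rk_stop("io", "calibration slope must be > 0")
    a <- absorbance_view(curve, calibration$slope,
                         calibration$offset %||% 0)
    utils::write.csv(a, path, row.names = FALSE)
    meta$calibration <- list(slope = calibration$slope,
                             offset = calibration$offset %||% 0)
  } else {
    utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  }
  meta <- Filter(Negate(is.null), meta)
  if (length(meta)) yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a release curve from CSV
#'
#' Expects a header with `time_h` and one of `conversion` or
#' `absorbance`. Absorbance is converted through the linear calibration
#' in the YAML sidecar (same basename, `.yml`), which may also carry the
#' experiment condition. Validation failures name the offending row.
#'
#' @param path CSV path.
#' @return A [release_curve()].
#' @export
read_release_csv <- function(path) {
  if (!file.exists(path)) rk_stop("io", "no such file: ", path)
  df <- utils::read.csv(path)
  if (!"time_h" %in% names(df))
    rk_stop("io", path, ": missing required column time_h")
  meta <- if (file.exists(sidecar_path(path))) {
    yaml::read_yaml(sidecar_path(path))
  } else {
    NULL
  }
  if ("conversion" %in% names(df)) {
    xi <- df$conversion
  } else if ("absorbance" %in% names(df)) {
    cal <- meta$calibration
    if (is.null(cal))
      rk_stop("io", path, ": absorbance column needs a calibration ",
              "in the sidecar ", sidecar_path(path))
    xi <- conversion_from_absorbance(df$absorbance, cal$slope,
                                     cal$offset %||% 0)
  } else {
    rk_stop("io", path, ": need a conversion or absorbance column")
  }
  bad <- which(diff(df$time_h) <= 0)
  if (length(bad))
    rk_stop("io", path, ": time not strictly increasing at row ",
            bad[1] + 1L)
  out <- which(xi < 0 | xi > 1)
  if (length(out))
    rk_stop("io", path, ": conversion outside [0, 1] at row ", out[1])
  release_curve(df$time_h, xi, condition_from_list(meta$condition))
}

#' Tabulate release fits
#'
#' Collects one row per [fit_release()] result: the condition, the
#' estimated equilibrium conversion and constants, and fit diagnostics.
#'
#' @param fits A single `release_fit` or a list of them.
#' @return A data frame, one row per fit.
#' @export
results_table <- function(fits) {
  if (inherits(fits, "release_fit")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    stopifnot(inherits(f, "release_fit"))
    cond <- f$condition
    data.frame(
      label = if (is.null(cond)) "" else cond$label,
      temperature = if (is.null(cond)) NA_real_ else cond$temperature,
      pH = if (is.null(cond)) NA_real_ else cond$pH,
      x_aa = if (is.null(cond)) NA_real_ else cond$x_aa,
      copolymer_conc = if (is.null(cond)) NA_real_ else
        cond$copolymer_conc,
      xi_inf = f$equilibrium$xi_inf, K = f$constants$K,
      k_total = f$constants$k_total, k1 = f$constants$k1,
      k_minus1 = f$constants$k_minus1,
      k_minus1_prime = f$constants$k_minus1_prime %||% NA_real_,
      r_squared = if (is.null(f$linear)) NA_real_ else
        f$linear$r_squared,
      n_used = if (is.null(f$linear)) NA_integer_ else f$linear$n_used,
      n_excluded = if (is.null(f$linear)) NA_integer_ else
        f$linear$n_excluded,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a results table with run metadata
#'
#' Serializes a [results_table()] to CSV plus a YAML sidecar recording
#' provenance (package version, timestamp-free run metadata supplied by
#' the caller, e.g. inputs and seed).
#'
#' @param tab Data frame from [results_table()].
#' @param path Output CSV path.
#' @param metadata Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(tab, path, metadata = list()) {
  utils::write.csv(tab, path, row.names = FALSE)
  meta <- c(list(package = "revkin",
                 version = as.character(utils::packageVersion("revkin"))),
            metadata)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}
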