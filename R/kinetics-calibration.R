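#' Calibrate the absorbance-to-concentration coefficient from an NADH titration
#'
#' In a coupled ATPase assay read in a plate, the optical pathlength is not
#' known a priori, so the effective signal coefficient (extinction coefficient
#' times pathlength, in absorbance units per molar NADH) is fitted per
#' experiment from a titration of known NADH concentrations. The slope of
#' absorbance against concentration is estimated by ordinary least squares
#' with a free intercept.
#'
#' @param titration Data frame with columns `conc_M` (known NADH
#'   concentration, molar) and `absorbance` (measured absorbance at 340 nm).
#' @return An object of class `assay_calibration`: a list with
#'   `coefficient` (AU per molar), `se` (standard error of the slope),
#'   `intercept`, `n_points`, and the underlying `lm` fit.
#' @examples
#' tit <- tibble::tibble(conc_M = c(0, 100e-6, 200e-6),
#'                       absorbance = c(0, 0.622, 1.244))
#' cal <- calibrate_pathlength(tit)
#' cal$coefficient  # 6220 AU/M
#' @export
calibrate_pathlength <- function(titration) {
  check_columns(titration, c("conc_M", "absorbance"), "titration")
  if (nrow(titration) < 3) {
    abort("calibration needs at least 3 titration points")
  }
  if (any(titration$conc_M < 0)) abort("NADH concentrations must be >= 0")
  if (length(unique(titration$conc_M)) < 2) {
    abort("degenerate titration: all concentrations identical")
  }
  fit <- lm(absorbance ~ conc_M, data = titration)
  slope <- unname(coef(fit)[["conc_M"]])
  se <- suppressWarnings(summary(fit))$coefficients["conc_M", "Std. Error"]
  if (!is.finite(slope) || slope <= 0) {
    abort(sprintf("non-positive signal coefficient (%g AU/M): check titration",
                  slope))
  }
  structure(
    list(coefficient = slope, se = unname(se),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         n_points = nrow(titration), fit = fit),
    class = "assay_calibration"
  )
}

#' @export
print.assay_calibration <- function(x, ...) {
  cat(sprintf("Assay calibration: %.4g AU/M (SE %.3g, n = %d)\n",
              x$coefficient, x$se, x$n_points))
  invisible(x)
}

#' @method tidy assay_calibration
#' @export
tidy.assay_calibration <- function(x, ...) {
  tibble(term = c("coefficient", "intercept"),
         estimate = c(x$coefficient, x$intercept),
         std.error = c(x$se,
                       suppressWarnings(summary(x$fit))$coefficients["(Intercept)", "Std. Error"]))
}

#' Default NADH signal coefficient at 340 nm for a 1 cm path
#'
#' Used only when no titration data are available; an empirical calibration
#' from [calibrate_pathlength()] always takes precedence.
#' @return Coefficient in AU per molar (6220).
#' @export
default_nadh_coefficient <- function() 6220

#' Convert an absorbance progress curve to product concentration
#'
#' NADH depletion in the coupled assay maps 1:1 to ADP formation, so the
#' absorbance trace divided by the calibrated signal coefficient gives the
#' reporter concentration directly; per-point standard deviations are scaled
#' by the same factor.
#'
#' @param curve Progress-curve tibble with columns `time_s`, `value`,
#'   optionally `sd`, and a `units` column equal to `"absorbance"`.
#' @param cal An `assay_calibration`, or a single positive number (AU/M).
#' @return The curve with `value` (and `sd`) in molar and
#'   `units = "molar"`.
#' @seealso [concentration_to_signal()] for the inverse.
#' @export
signal_to_concentration <- function(curve, cal = default_nadh_coefficient()) {
  check_columns(curve, c("time_s", "value", "units"), "curve")
  coefficient <- if (inherits(cal, "assay_calibration")) cal$coefficient else cal
  if (!is.numeric(coefficient) || coefficient <= 0) {
    abort("signal coefficient must be a positive number")
  }
  if (!all(curve$units == "absorbance")) {
    abort("curve is not in absorbance units; already converted?")
  }
  curve$value <- curve$value / coefficient
  if ("sd" %in% names(curve)) curve$sd <- curve$sd / coefficient
  curve$units <- "molar"
  curve
}

#' Convert a molar progress curve back to absorbance units
#'
#' @inheritParams signal_to_concentration
#' @param curve Progress-curve tibble in molar units.
#' @return The curve in absorbance units.
#' @export
concentration_to_signal <- function(curve, cal = default_nadh_coefficient()) {
  check_columns(curve, c("time_s", "value", "units"), "curve")
  coefficient <- if (inherits(cal, "assay_calibration")) cal$coefficient else cal
  if (!is.numeric(coefficient) || coefficient <= 0) {
    abort("signal coefficient must be a positive number")
  }
  if (!all(curve$units == "molar")) {
    abort("curve is not in molar units; already converted?")
  }
  curve$value <- curve$value * coefficient
  if ("sd" %in% names(curve)) curve$sd <- curve$sd * coefficient
  curve$units <- "absorbance"
  curve
}

#' Average replicate progress curves point-by-point
#'
#' Replicates sharing a time grid and condition are averaged; the per-point
#' sample standard deviation becomes the `sd` column of the averaged curve and
#' its mean over time points (the scalar "average standard deviation" used to
#' weight downstream fits) is attached as attribute `avg_sd`.
#'
#' @param curves Tibble of replicate curves: columns `time_s`, `value`,
#'   `replicate`, and optionally `condition`, `S0_M`, `E0_M`, `units`.
#'   All replicates within a condition must share the identical time grid
#'   and metadata.
#' @return One averaged curve per condition (replicate column dropped), with
#'   columns `value` (mean), `sd` (per-point SD), `n_rep`, and attribute
#'   `avg_sd` (named by condition).
#' @export
average_replicates <- function(curves) {
  check_columns(curves, c("time_s", "value", "replicate"), "curves")
  if (!"condition" %in% names(curves)) curves$condition <- "all"
  meta_cols <- intersect(c("units", "S0_M", "E0_M"), names(curves))

  split_cond <- split(curves, curves$condition)
  out <- purrr::map(split_cond, function(df) {
    reps <- split(df, df$replicate)
    if (length(reps) < 2) {
      abort(sprintf("condition '%s' has %d replicate(s); need >= 2",
                    df$condition[1], length(reps)))
    }
    grids <- purrr::map(reps, ~ .x$time_s)
    if (!all(purrr::map_lgl(grids, ~ identical(.x, grids[[1]])))) {
      abort(sprintf("replicates of condition '%s' have mismatched time grids",
                    df$condition[1]))
    }
    for (mc in intersect(c("S0_M", "E0_M"), meta_cols)) {
      if (length(unique(df[[mc]])) > 1) {
        abort(sprintf("replicates of condition '%s' disagree on %s",
                      df$condition[1], mc))
      }
    }
    vals <- do.call(cbind, purrr::map(reps, ~ .x$value))
    avg <- tibble(
      time_s = grids[[1]],
      value = rowMeans(vals),
      sd = apply(vals, 1, sd),
      n_rep = length(reps),
      condition = df$condition[1]
    )
    for (mc in meta_cols) avg[[mc]] <- df[[mc]][1]
    avg
  })
  res <- dplyr::bind_rows(out)
  attr(res, "avg_sd") <- purrr::map_dbl(out, ~ mean(.x$sd))
  res
}
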