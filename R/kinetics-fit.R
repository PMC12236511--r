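#' Fit the Michaelis-Menten equation to initial-rate measurements
#'
#' Nonlinear least squares of \eqn{v_0 = k_{cat}[S]/(K_M + [S])} to
#' enzyme-normalized initial velocities at varied substrate concentration,
#' by trust-region Levenberg-Marquardt. Standard errors come from the fit
#' covariance; the specificity constant `kcat/KM` and its SE are derived by
#' first-order (delta-method) propagation.
#'
#' @param measurements Data frame with columns `conc_M` (substrate, molar)
#'   and `v0` (initial velocity, 1/s); optional `sd` used as weights
#'   (1/sd^2).
#' @return An object of class `mm_fit`: list with `parameters` (tibble of
#'   term / estimate / std.error for kcat, KM, kcat_over_KM), `vcov` (2x2,
#'   kcat & KM), `converged`, `rss`, `df.residual`, `n`, and the underlying
#'   `nls` fit.
#' @details A fit is flagged non-converged when the optimizer fails or when
#'   the data carry no curvature information (estimated KM far outside the
#'   measured concentration range, as happens when every point lies in the
#'   linear regime); boundary values are then not to be trusted.
#' @examples
#' s <- c(10, 50, 100, 500, 2000) * 1e-6
#' d <- tibble::tibble(conc_M = s, v0 = 10 * s / (100e-6 + s))
#' fit_initial_rates(d)$parameters
#' @export
fit_initial_rates <- function(measurements) {
  check_columns(measurements, c("conc_M", "v0"), "measurements")
  if (any(measurements$conc_M < 0)) abort("substrate concentrations must be >= 0")
  if (length(unique(measurements$conc_M)) < 4) {
    abort("need >= 4 distinct substrate concentrations")
  }

  wts <- if ("sd" %in% names(measurements) &&
             all(is.finite(measurements$sd)) && all(measurements$sd > 0)) {
    1 / measurements$sd^2
  } else {
    rep(1, nrow(measurements))
  }

  # heuristic starts: vmax a bit above the largest rate, KM near half-max
  vmax0 <- max(measurements$v0) * 1.2
  half <- vmax0 / 2
  km0 <- tryCatch(
    approx(measurements$v0, measurements$conc_M, xout = half, ties = mean)$y,
    error = function(e) NA_real_)
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(measurements$conc_M)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      v0 ~ kcat * conc_M / (KM + conc_M),
      data = measurements, weights = wts,
      start = list(kcat = vmax0, KM = km0),
      lower = c(kcat = 0, KM = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    return(structure(list(parameters = NULL, vcov = NULL, converged = FALSE,
                          message = conditionMessage(fit),
                          n = nrow(measurements)),
                     class = "mm_fit"))
  }

  est <- coef(fit)
  V <- vcov(fit)
  kcat <- est[["kcat"]]; KM <- est[["KM"]]
  # delta method for kcat/KM: g = (1/KM, -kcat/KM^2)
  g <- c(1 / KM, -kcat / KM^2)
  se_spec <- sqrt(max(drop(t(g) %*% V %*% g), 0))
  se <- sqrt(diag(V))

  # curvature check: KM far outside the measured range means the data are
  # effectively linear in [S] and kcat/KM is the only identified quantity
  converged <- is.finite(KM) && KM <= 10 * max(measurements$conc_M) &&
    KM >= min(measurements$conc_M[measurements$conc_M > 0]) / 100

  structure(
    list(
      parameters = tibble(
        term = c("kcat", "KM", "kcat_over_KM"),
        estimate = c(kcat, KM, kcat / KM),
        std.error = c(se[["kcat"]], se[["KM"]], se_spec)),
      vcov = V,
      converged = converged,
      rss = sum(stats::residuals(fit)^2 * wts),
      df.residual = nrow(measurements) - 2,
      n = nrow(measurements),
      fit = fit),
    class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten initial-rate fit",
      if (!x$converged) "(NOT CONVERGED)" else "", "\n")
  if (!is.null(x$parameters)) print(x$parameters)
  invisible(x)
}

#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) x$parameters

#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(rss = x$rss %||% NA_real_, df.residual = x$df.residual %||% NA_real_,
         nobs = x$n, converged = x$converged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
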