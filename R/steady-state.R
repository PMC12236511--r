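#' Steady-state Michaelis-Menten parameters from elementary rate constants
#'
#' Closed-form steady-state algebra of the three-step scheme
#' \eqn{E+S \rightleftharpoons ES \rightleftharpoons EP \rightarrow E+P}:
#' \deqn{k_{cat} = \frac{k_2 k_3}{k_2 + k_{-2} + k_3}}
#' \deqn{k_{cat}/K_M = \frac{k_1 k_2 k_3}{k_{-1}k_{-2} + k_{-1}k_3 + k_2 k_3}}
#' \deqn{K_M = \frac{k_{cat}}{k_{cat}/K_M}}
#' Uncertainty is propagated from a covariance of the elementary constants by
#' the delta method (first-order, numerical gradients), with an optional
#' Monte-Carlo cross-check that resamples rate-constant vectors from the
#' covariance.
#'
#' @param params A [rate_constants()] object.
#' @param covariance Optional 5x5 covariance matrix of the rate constants on
#'   the natural scale, ordered (k1, k_minus1, k2, k_minus2, k3). Must be
#'   symmetric positive semi-definite.
#' @param method `"delta"` (default) or `"mc"` for Monte-Carlo propagation.
#' @param n_mc Number of Monte-Carlo resamples (default 10000).
#' @param seed Seed for the Monte-Carlo resampling.
#' @return A tibble of class `steady_state_params` with columns `term`
#'   (`kcat`, `KM`, `kcat_over_KM`), `estimate` and `std.error` (NA when no
#'   covariance is supplied). Units: 1/s, M, 1/(M s).
#' @examples
#' k <- rate_constants(1e6, 0, 1, 0, 1)
#' derive_steady_state(k)  # kcat = 0.5 /s, kcat/KM = 1e6 /M/s
#' @export
derive_steady_state <- function(params, covariance = NULL,
                                method = c("delta", "mc"),
                                n_mc = 10000, seed = NULL) {
  params <- as_rate_constants(params)
  method <- match.arg(method)

  est <- steady_state_values(params)
  se <- c(kcat = NA_real_, KM = NA_real_, kcat_over_KM = NA_real_)

  if (!is.null(covariance)) {
    covariance <- as.matrix(covariance)
    if (!all(dim(covariance) == c(5, 5))) {
      abort("covariance must be 5x5, ordered (k1, k_minus1, k2, k_minus2, k3)")
    }
    if (max(abs(covariance - t(covariance))) >
        1e-8 * max(1, max(abs(covariance)))) {
      abort("covariance must be symmetric")
    }
    ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev), 1)) {
      abort("covariance is not positive semi-definite")
    }
    if (method == "delta") {
      J <- steady_state_jacobian(params)
      v <- diag(J %*% covariance %*% t(J))
      se <- sqrt(pmax(v, 0))
      names(se) <- c("kcat", "KM", "kcat_over_KM")
    } else {
      if (!is.null(seed)) set.seed(seed)
      draws <- MASS::mvrnorm(n_mc, mu = unclass(params), Sigma = covariance)
      ok <- draws[, "k1"] > 0 & draws[, "k2"] > 0 & draws[, "k3"] > 0 &
        draws[, "k_minus1"] >= 0 & draws[, "k_minus2"] >= 0
      if (sum(ok) < n_mc / 2) {
        warn("more than half of Monte-Carlo draws violated positivity; SEs may be biased")
      }
      vals <- apply(draws[ok, , drop = FALSE], 1, function(row) {
        steady_state_values(rate_constants(row[1], row[2], row[3], row[4],
                                           row[5]))
      })
      se <- apply(vals, 1, sd)
    }
  }

  structure(
    tibble(term = c("kcat", "KM", "kcat_over_KM"),
           estimate = unname(est[c("kcat", "KM", "kcat_over_KM")]),
           std.error = unname(se[c("kcat", "KM", "kcat_over_KM")])),
    class = c("steady_state_params", class(tibble())),
    params = params, method = if (is.null(covariance)) "none" else method
  )
}

steady_state_values <- function(k) {
  kcat <- k[["k2"]] * k[["k3"]] / (k[["k2"]] + k[["k_minus2"]] + k[["k3"]])
  spec <- k[["k1"]] * k[["k2"]] * k[["k3"]] /
    (k[["k_minus1"]] * k[["k_minus2"]] + k[["k_minus1"]] * k[["k3"]] +
       k[["k2"]] * k[["k3"]])
  c(kcat = kcat, KM = kcat / spec, kcat_over_KM = spec)
}

# numerical Jacobian of (kcat, KM, kcat/KM) wrt the five constants
steady_state_jacobian <- function(params) {
  k0 <- unclass(params)
  J <- matrix(0, nrow = 3, ncol = 5,
              dimnames = list(c("kcat", "KM", "kcat_over_KM"), names(k0)))
  for (i in seq_along(k0)) {
    h <- max(abs(k0[i]), 1e-12) * 1e-6
    up <- k0; up[i] <- up[i] + h
    dn <- k0; dn[i] <- max(dn[i] - h, 0)
    fu <- steady_state_values(up)
    fd <- steady_state_values(dn)
    J[, i] <- (fu - fd) / (up[i] - dn[i])
  }
  J
}
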