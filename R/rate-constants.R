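#' Elementary rate constants of the three-step catalytic scheme
#'
#' The reaction scheme underlying full progress-curve analysis is
#' \deqn{E + S \rightleftharpoons ES \rightleftharpoons EP \rightarrow E + P}
#' with association rate `k1` (per-molar per-second), complex dissociation
#' `k_minus1` (per-second), forward chemistry `k2` (per-second), reverse
#' chemistry `k_minus2` (per-second) and product release `k3` (per-second).
#'
#' @param k1 Second-order substrate association rate, 1/(M s). Must be > 0.
#' @param k_minus1 ES dissociation rate, 1/s. Must be >= 0.
#' @param k2 Forward chemistry rate, 1/s. Must be > 0.
#' @param k_minus2 Reverse chemistry rate, 1/s. Must be >= 0.
#' @param k3 Product release rate, 1/s. Must be > 0.
#'
#' @return A named numeric vector of class `rate_constants`.
#' @examples
#' rate_constants(k1 = 1e5, k_minus1 = 6, k2 = 5, k_minus2 = 0.5, k3 = 5)
#' @export
rate_constants <- function(k1, k_minus1, k2, k_minus2, k3) {
  k <- c(k1 = unname(k1), k_minus1 = unname(k_minus1), k2 = unname(k2),
         k_minus2 = unname(k_minus2), k3 = unname(k3))
  if (any(!is.finite(k))) abort("rate constants must be finite")
  if (k[["k1"]] <= 0 || k[["k2"]] <= 0 || k[["k3"]] <= 0) {
    abort("k1, k2 and k3 must be strictly positive")
  }
  if (k[["k_minus1"]] < 0 || k[["k_minus2"]] < 0) {
    abort("k_minus1 and k_minus2 must be non-negative")
  }
  structure(k, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Elementary rate constants:\n")
  cat(sprintf("  k1       = %g /M/s\n", x[["k1"]]))
  cat(sprintf("  k_minus1 = %g /s\n", x[["k_minus1"]]))
  cat(sprintf("  k2       = %g /s\n", x[["k2"]]))
  cat(sprintf("  k_minus2 = %g /s\n", x[["k_minus2"]]))
  cat(sprintf("  k3       = %g /s\n", x[["k3"]]))
  invisible(x)
}

as_rate_constants <- function(x) {
  if (inherits(x, "rate_constants")) return(x)
  x <- unlist(x)
  check <- c("k1", "k_minus1", "k2", "k_minus2", "k3")
  if (!all(check %in% names(x))) {
    abort("need named entries k1, k_minus1, k2, k_minus2, k3")
  }
  rate_constants(x[["k1"]], x[["k_minus1"]], x[["k2"]], x[["k_minus2"]],
                 x[["k3"]])
}
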