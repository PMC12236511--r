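make_noiseless_curves <- function(k, E0 = 2.4e-6,
                                  S0 = c(750e-6, 375e-6, 188e-6),
                                  times = seq(0, 300, 10), sd = 1e-8) {
  purrr::map(S0, function(s) {
    sim <- simulate_progress(k, E0, s, times)
    cv <- as_progress_curve(sim)
    cv$sd <- sd
    cv
  }) |> dplyr::bind_rows()
}

test_that("a fit initialized at the truth of noiseless data stays there", {
  k <- default_rate_constants()
  curves <- make_noiseless_curves(k)
  fit <- fit_progress_curves(curves, start = k, n_starts = 0,
                             check_identifiability = FALSE)
  expect_lt(fit$chisq, 1e-6)
  ss_t <- derive_steady_state(k)
  expect_equal(fit$steady_state$estimate, ss_t$estimate, tolerance = 1e-4)
})

test_that("steady-state parameters are recovered from noisy averaged curves", {
  truth <- derive_steady_state(default_rate_constants())
  curves <- gen_progress_curves(seed = 123)
  avg <- average_replicates(curves)
  fit <- fit_progress_curves(avg, n_starts = 8, seed = 4,
                             check_identifiability = FALSE)
  kc <- fit$steady_state$estimate[fit$steady_state$term == "kcat"]
  km <- fit$steady_state$estimate[fit$steady_state$term == "KM"]
  expect_lt(abs(kc - truth$estimate[truth$term == "kcat"]) /
              truth$estimate[truth$term == "kcat"], 0.1)
  expect_lt(abs(km - truth$estimate[truth$term == "KM"]) /
              truth$estimate[truth$term == "KM"], 0.1)
})

test_that("elementary constants trade off while steady-state parameters hold", {
  # multiply k1 by 10 and rescale k_minus1 so kcat and KM are unchanged:
  # kcat depends only on (k2, k_minus2, k3); kcat/KM scales with
  # k1 / (k_minus1 (k_minus2 + k3) + k2 k3)
  k <- default_rate_constants()
  den <- k[["k_minus1"]] * (k[["k_minus2"]] + k[["k3"]]) +
    k[["k2"]] * k[["k3"]]
  km1_new <- (10 * den - k[["k2"]] * k[["k3"]]) /
    (k[["k_minus2"]] + k[["k3"]])
  k_alt <- rate_constants(10 * k[["k1"]], km1_new, k[["k2"]],
                          k[["k_minus2"]], k[["k3"]])
  ss <- derive_steady_state(k); ss_alt <- derive_steady_state(k_alt)
  expect_equal(ss$estimate, ss_alt$estimate, tolerance = 1e-10)

  # curves with known per-point noise SD used as weights; at low noise the
  # chi-square ratio is dominated by the pre-steady-state lag offset
  # interacting with the noise cross-term, so the probe uses 5% noise
  set.seed(55)
  curves <- make_noiseless_curves(k)
  sigma <- 0.05 * max(curves$value)
  curves$value <- curves$value + rnorm(nrow(curves), sd = sigma)
  curves$sd <- sigma
  c1 <- progress_chisq(k, curves)
  c2 <- progress_chisq(k_alt, curves)
  expect_lt(abs(c1 - c2) / c1, 1e-3)

  # the flat direction must be reported: at least one elementary constant
  # flagged non-identifiable by profiling
  fit <- fit_progress_curves(curves, start = k, n_starts = 2, seed = 9,
                             check_identifiability = TRUE)
  expect_true(any(!fit$identifiable, na.rm = TRUE))
})

test_that("zero or missing SDs are floored with a warning", {
  k <- default_rate_constants()
  curves <- make_noiseless_curves(k)
  curves$sd <- 0
  expect_warning(
    fit <- fit_progress_curves(curves, start = k, n_starts = 0,
                               check_identifiability = FALSE),
    "floor")
  expect_true(fit$sd_floored)
})

test_that("degenerate curve sets are rejected", {
  k <- default_rate_constants()
  curves <- make_noiseless_curves(k, S0 = 750e-6)
  expect_error(fit_progress_curves(curves, check_identifiability = FALSE),
               ">= 2")
})
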