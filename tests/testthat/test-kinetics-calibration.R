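test_that("pathlength calibration recovers an exact line with zero SE", {
  tit <- tibble::tibble(conc_M = c(0, 100e-6, 200e-6),
                        absorbance = c(0, 0.622, 1.244))
  cal <- calibrate_pathlength(tit)
  expect_equal(cal$coefficient, 6220, tolerance = 1e-10)
  expect_equal(cal$se, 0, tolerance = 1e-6)
  expect_equal(cal$n_points, 3)
})

test_that("degenerate titrations are rejected", {
  expect_error(calibrate_pathlength(
    tibble::tibble(conc_M = c(0, 1e-4), absorbance = c(0, 0.6))), "at least 3")
  expect_error(calibrate_pathlength(
    tibble::tibble(conc_M = rep(1e-4, 4), absorbance = c(1, 2, 3, 4))),
    "identical")
  expect_error(calibrate_pathlength(
    tibble::tibble(conc_M = c(0, 1e-4, 2e-4), absorbance = c(0, 0, 0))),
    "non-positive")
})

test_that("noisy titration recovers the coefficient within 3 SE (OLS oracle)", {
  set.seed(42)
  true_coef <- 5000
  conc <- seq(0, 200e-6, length.out = 10)
  tit <- tibble::tibble(conc_M = conc,
                        absorbance = true_coef * conc + rnorm(10, sd = 0.005))
  cal <- calibrate_pathlength(tit)
  # oracle: plain lm, computed independently
  ofit <- lm(absorbance ~ conc_M, data = tit)
  expect_equal(cal$coefficient, unname(coef(ofit)["conc_M"]))
  expect_lt(abs(cal$coefficient - true_coef), 3 * cal$se)
})

test_that("absorbance <-> concentration conversion is exact and invertible", {
  cal <- calibrate_pathlength(tibble::tibble(
    conc_M = c(0, 100e-6, 200e-6), absorbance = c(0, 0.622, 1.244)))
  curve <- tibble::tibble(time_s = 0:2, value = c(0.622, 0.311, 0),
                          sd = c(0.01, 0.01, 0.01), units = "absorbance")
  conv <- signal_to_concentration(curve, cal)
  expect_equal(conv$value[1], 100e-6)
  expect_equal(conv$value[3], 0)
  expect_equal(conv$sd, curve$sd / 6220)
  expect_identical(unique(conv$units), "molar")
  # exact round trip
  back <- concentration_to_signal(conv, cal)
  expect_identical(back$value, curve$value)
  # double conversion errors out
  expect_error(signal_to_concentration(conv, cal), "absorbance")
  expect_error(concentration_to_signal(curve, cal), "molar")
})

test_that("replicate averaging gives pointwise mean, SD, and average-SD metadata", {
  base <- tibble::tibble(time_s = c(0, 5, 10), value = 0,
                         condition = "c1", S0_M = 1e-4, E0_M = 1e-6)
  r1 <- dplyr::mutate(base, value = c(0, 0, 0), replicate = "a")
  r2 <- dplyr::mutate(base, value = c(2, 2, 2), replicate = "b")
  avg <- average_replicates(dplyr::bind_rows(r1, r2))
  expect_equal(avg$value, c(1, 1, 1))
  expect_equal(avg$sd, rep(sqrt(2), 3))
  expect_equal(unname(attr(avg, "avg_sd")), sqrt(2))
  # identical replicates -> zero SD
  avg2 <- average_replicates(dplyr::bind_rows(
    dplyr::mutate(r1, replicate = "a"), dplyr::mutate(r1, replicate = "b")))
  expect_equal(avg2$sd, rep(0, 3))

  expect_error(average_replicates(r1), ">= 2")
  r3 <- dplyr::mutate(r2, time_s = c(0, 5, 11))
  expect_error(average_replicates(dplyr::bind_rows(r1, r3)), "time grids")
})

test_that("per-point SD of averaged replicates tracks the noise SD", {
  set.seed(7)
  tt <- seq(0, 100, by = 2)
  truth <- 1e-5 * (1 - exp(-tt / 30))
  reps <- purrr::map(1:8, function(r) {
    tibble::tibble(time_s = tt, value = truth + rnorm(length(tt), sd = 1e-6),
                   replicate = sprintf("r%d", r), condition = "x")
  }) |> dplyr::bind_rows()
  avg <- average_replicates(reps)
  frac_ok <- mean(abs(avg$sd - 1e-6) < 0.5 * 1e-6)
  expect_gte(frac_ok, 0.9)
})
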