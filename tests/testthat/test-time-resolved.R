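test_that("fractions and binomial errors follow the counting definitions", {
  tab <- tibble::tibble(dataset_id = "a", time_s = 57,
                        n_decamer = 50, n_filament = 50, n_unassigned = 100)
  fr <- compute_fractions(tab)
  expect_equal(fr$filament_fraction, 0.5)
  expect_equal(fr$se, 0.05)
  expect_equal(fr$n_assigned, 100)
  # all-decamer row
  fr0 <- compute_fractions(tibble::tibble(
    dataset_id = "b", time_s = 10, n_decamer = 100, n_filament = 0))
  expect_equal(fr0$filament_fraction, 0)
  expect_equal(fr0$filament_fraction + fr0$decamer_fraction, 1)
  # zero assigned errors with the row named
  expect_error(compute_fractions(tibble::tibble(
    dataset_id = "bad", time_s = 5, n_decamer = 0, n_filament = 0)), "bad")
})

test_that("fractions are invariant to unassigned counts", {
  t1 <- make_count_table(c(0.2, 0.3, 0.4), c(50, 100, 150), n_unassigned = 0)
  t2 <- dplyr::mutate(t1, n_unassigned = c(500, 1000, 1))
  f1 <- compute_fractions(t1); f2 <- compute_fractions(t2)
  expect_equal(f1$filament_fraction, f2$filament_fraction)
  tr1 <- linear_trend(f1, n_perm = 500, n_boot = 500, seed = 1)
  tr2 <- linear_trend(f2, n_perm = 500, n_boot = 500, seed = 1)
  expect_equal(tr1$slope, tr2$slope)
})

test_that("sampled fractions stay within 3 binomial SE of the truth", {
  set.seed(71)
  p_true <- 0.3; n <- 10000
  for (i in 1:20) {
    nf <- rbinom(1, n, p_true)
    fr <- compute_fractions(tibble::tibble(
      dataset_id = "x", time_s = 100, n_decamer = n - nf, n_filament = nf))
    expect_lt(abs(fr$filament_fraction - p_true), 3 * sqrt(p_true * 0.7 / n))
  }
})

test_that("an exact line is fit exactly; constant fractions give p near 1", {
  times <- c(57, 172, 287, 402, 517)
  f <- 0.001 * times + 0.1
  tab <- make_count_table(f, times, n_total = 100000)
  fr <- compute_fractions(tab)
  tr <- linear_trend(fr, n_perm = 2000, n_boot = 500, seed = 3)
  expect_equal(tr$slope, 0.001, tolerance = 1e-2)
  expect_equal(tr$r, 1, tolerance = 1e-4)
  expect_lt(tr$p_perm, 0.05)

  flat <- compute_fractions(make_count_table(rep(0.3, 5), times))
  trf <- linear_trend(flat, n_perm = 2000, n_boot = 500, seed = 4)
  expect_equal(trf$slope, 0, tolerance = 1e-12)
  expect_gt(trf$p_perm, 0.9)
})

test_that("trend inference validates its inputs", {
  fr <- compute_fractions(make_count_table(c(0.2, 0.3), c(50, 100)))
  expect_error(linear_trend(fr, seed = 1), ">= 3")
  fr3 <- compute_fractions(make_count_table(c(0.2, 0.3, 0.4), c(50, 50, 50)))
  expect_error(linear_trend(fr3, seed = 1), "identical")
  fr5 <- compute_fractions(make_count_table(c(0.2, 0.3, 0.4), c(10, 20, 30)))
  expect_error(linear_trend(fr5), "seed")
})

test_that("bootstrap CI covers a known slope on the binomial generator", {
  true_slope <- 7.6e-4
  set.seed(77)
  seeds <- sample.int(1e6, 60)
  cover <- 0
  for (s in seeds) {
    tab <- gen_particle_counts(seed = s)
    fr <- compute_fractions(tab)
    tr <- linear_trend(fr, n_perm = 50, n_boot = 1000, seed = s + 1)
    if (tr$ci_lower <= true_slope && true_slope <= tr$ci_upper) {
      cover <- cover + 1
    }
  }
  expect_gte(cover / length(seeds), 0.93)
})

test_that("slope estimation is unbiased on the binomial generator", {
  set.seed(78)
  n_rep <- 300
  slopes <- vapply(sample.int(1e6, n_rep), function(s) {
    fr <- compute_fractions(gen_particle_counts(seed = s))
    unname(coef(lm(filament_fraction ~ time_s, data = fr))[2])
  }, numeric(1))
  mc_se <- sd(slopes) / sqrt(n_rep)
  expect_lt(abs(mean(slopes) - 7.6e-4), 2 * mc_se)
})

test_that("processing-mode comparison is zero for identical tables and antisymmetric", {
  tab <- gen_particle_counts(seed = 5)
  cmp0 <- compare_modes(tab, tab)
  expect_true(all(cmp0$delta == 0))

  # constructed 0.05 offset in filament fraction
  times <- c(57, 172, 287, 402, 517)
  t_ind <- make_count_table(c(0.25, 0.35, 0.45, 0.55, 0.65), times)
  t_pool <- make_count_table(c(0.20, 0.30, 0.40, 0.50, 0.60), times)
  cmp <- compare_modes(t_ind, t_pool)
  expect_equal(cmp$delta, rep(0.05, 5), tolerance = 1e-9)
  # antisymmetry under swapping tables
  cmp_rev <- compare_modes(t_pool, t_ind)
  expect_equal(cmp_rev$delta, -cmp$delta)

  bad <- dplyr::mutate(tab, dataset_id = paste0(dataset_id, "_x"))
  expect_error(compare_modes(tab, bad), "differ")
})
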