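#' Decamer/filament fractions from particle count tables
#'
#' Normalizes per-dataset decamer and filament particle picks to the total
#' number of assigned particles; 2-D classes that could not be assigned
#' either state are excluded from the denominator. Each fraction carries a
#' binomial standard error `sqrt(f (1 - f) / n_assigned)`.
#'
#' @param table Data frame with columns `dataset_id`, `time_s`,
#'   `n_decamer`, `n_filament`, and optionally `n_unassigned`, `mode`.
#' @return A tibble of class `fraction_series`: the input plus `n_assigned`,
#'   `filament_fraction`, `decamer_fraction`, `se`.
#' @examples
#' tab <- tibble::tibble(dataset_id = "a", time_s = 57,
#'                       n_decamer = 50, n_filament = 50, n_unassigned = 100)
#' compute_fractions(tab)  # fraction 0.5, se 0.05
#' @export
compute_fractions <- function(table) {
  check_columns(table, c("dataset_id", "time_s", "n_decamer", "n_filament"),
                "table")
  counts <- c(table$n_decamer, table$n_filament)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  if (any(table$time_s <= 0)) abort("quench times must be positive")
  assigned <- table$n_decamer + table$n_filament
  if (any(assigned < 1)) {
    bad <- table$dataset_id[assigned < 1]
    abort(sprintf("zero assigned particles in dataset(s): %s",
                  paste(bad, collapse = ", ")))
  }
  out <- as_tibble(table)
  out$n_assigned <- assigned
  out$filament_fraction <- table$n_filament / assigned
  out$decamer_fraction <- table$n_decamer / assigned
  out$se <- sqrt(out$filament_fraction * (1 - out$filament_fraction) / assigned)
  class(out) <- c("fraction_series", class(out))
  out
}

#' Linear trend of filament fraction with reaction quench time
#'
#' Ordinary least-squares slope and intercept of filament fraction against
#' quench time, with Pearson r. Because such series are tiny (a handful of
#' datasets), inference is non-parametric: a two-sided permutation p-value
#' obtained by shuffling the time labels, and a percentile bootstrap 95%
#' confidence interval for the slope from resampling rows with replacement.
#' Rows are unweighted by default (one dataset, one point);
#' inverse-variance weighting by the binomial SE is available.
#'
#' @param series A `fraction_series` from [compute_fractions()] (or any data
#'   frame with `time_s` and `filament_fraction`; `se` needed if weighted).
#' @param n_perm Number of permutations (default 10000).
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Seed for both resampling schemes (required).
#' @param weighted Inverse-variance weights 1/se^2 (default FALSE).
#' @return An object of class `trend_result`: list with `slope` (fraction
#'   per second), `intercept`, `r`, `p_perm`, `ci_lower`, `ci_upper`,
#'   `n_perm`, `n_boot`, `seed`, `n`, and the `lm` fit.
#' @export
linear_trend <- function(series, n_perm = 10000, n_boot = 10000, seed,
                         weighted = FALSE) {
  check_columns(series, c("time_s", "filament_fraction"), "series")
  if (missing(seed) || is.null(seed)) {
    abort("a seed is required for permutation/bootstrap inference")
  }
  if (nrow(series) < 3) abort("need >= 3 time points")
  if (length(unique(series$time_s)) < 2) abort("all times identical")

  w <- if (weighted) {
    check_columns(series, "se", "series (weighted)")
    1 / pmax(series$se, 1e-12)^2
  } else {
    rep(1, nrow(series))
  }
  t_obs <- series$time_s
  f_obs <- series$filament_fraction

  wslope <- function(tt, ff, ww) {
    mt <- sum(ww * tt) / sum(ww)
    mf <- sum(ww * ff) / sum(ww)
    sum(ww * (tt - mt) * (ff - mf)) / sum(ww * (tt - mt)^2)
  }
  slope <- wslope(t_obs, f_obs, w)
  mt <- sum(w * t_obs) / sum(w)
  mf <- sum(w * f_obs) / sum(w)
  intercept <- mf - slope * mt
  # constant fractions have no defined correlation; report 0 (no trend)
  r <- if (sd(f_obs) > 0) cor(t_obs, f_obs) else 0

  set.seed(seed)
  n <- length(t_obs)
  # permutation slopes, vectorized: shuffle time labels against fixed
  # (fraction, weight) pairs
  Tm <- vapply(seq_len(n_perm), function(i) sample(t_obs), numeric(n))
  sw <- sum(w)
  mtv <- colSums(w * Tm) / sw
  num <- colSums((w * f_obs) * Tm) - sw * mtv * mf
  den <- colSums(w * Tm^2) - sw * mtv^2
  perm_slopes <- num / den
  p_perm <- (1 + sum(abs(perm_slopes) >= abs(slope))) / (n_perm + 1)

  # bootstrap-t interval: resample rows with replacement, use the bootstrap
  # SD of the slope with a t(n-2) quantile; raw percentile intervals
  # undercover badly at the handful-of-datasets sizes this is built for
  Im <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  tb <- matrix(t_obs[Im], nrow = n)
  fb <- matrix(f_obs[Im], nrow = n)
  wb <- matrix(w[Im], nrow = n)
  swb <- colSums(wb)
  mtb <- colSums(wb * tb) / swb
  mfb <- colSums(wb * fb) / swb
  denb <- colSums(wb * tb^2) - swb * mtb^2
  boot_slopes <- (colSums(wb * tb * fb) - swb * mtb * mfb) / denb
  boot_slopes[abs(denb) < .Machine$double.eps * max(t_obs)^2] <- NA_real_
  se_boot <- sd(boot_slopes, na.rm = TRUE)
  tq <- stats::qt(0.975, df = length(t_obs) - 2)
  ci <- slope + c(-1, 1) * tq * se_boot

  fit <- lm(filament_fraction ~ time_s, data = series, weights = w)
  structure(
    list(slope = slope, intercept = intercept, r = r, p_perm = p_perm,
         ci_lower = ci[1], ci_upper = ci[2], n_perm = n_perm,
         n_boot = n_boot, seed = seed, n = nrow(series), weighted = weighted,
         fit = fit),
    class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "Linear trend: slope %.3g /s (95%% boot CI %.3g to %.3g), r = %.3f, perm p = %.4g (n = %d)\n",
    x$slope, x$ci_lower, x$ci_upper, x$r, x$p_perm, x$n))
  invisible(x)
}

#' @method tidy trend_result
#' @export
tidy.trend_result <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept),
         conf.low = c(x$ci_lower, NA_real_),
         conf.high = c(x$ci_upper, NA_real_),
         p.value = c(x$p_perm, NA_real_))
}

#' @method glance trend_result
#' @export
glance.trend_result <- function(x, ...) {
  tibble(r = x$r, p.perm = x$p_perm, n = x$n, n.perm = x$n_perm,
         n.boot = x$n_boot, weighted = x$weighted)
}

#' Compare filament fractions between two processing modes
#'
#' Time-resolved datasets can be 2-D classified independently per time point
#' or pooled and classified together; this compares the per-dataset filament
#' fractions between the two modes. Deltas are reported as independent minus
#' pooled with a combined binomial standard error.
#'
#' @param independent,pooled Particle count tables (see
#'   [compute_fractions()]) with matching `dataset_id` sets.
#' @return A tibble with `dataset_id`, `time_s`, `fraction_independent`,
#'   `fraction_pooled`, `delta`, `se_delta`.
#' @export
compare_modes <- function(independent, pooled) {
  fi <- compute_fractions(independent)
  fp <- compute_fractions(pooled)
  if (!setequal(fi$dataset_id, fp$dataset_id)) {
    abort(sprintf(
      "dataset ids differ between modes (only independent: %s; only pooled: %s)",
      paste(setdiff(fi$dataset_id, fp$dataset_id), collapse = ","),
      paste(setdiff(fp$dataset_id, fi$dataset_id), collapse = ",")))
  }
  dplyr::inner_join(
    dplyr::select(fi, "dataset_id", "time_s",
                  fraction_independent = "filament_fraction", se_i = "se"),
    dplyr::select(fp, "dataset_id",
                  fraction_pooled = "filament_fraction", se_p = "se"),
    by = "dataset_id") |>
    dplyr::mutate(delta = .data$fraction_independent - .data$fraction_pooled,
                  se_delta = sqrt(.data$se_i^2 + .data$se_p^2)) |>
    dplyr::select("dataset_id", "time_s", "fraction_independent",
                  "fraction_pooled", "delta", "se_delta")
}
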