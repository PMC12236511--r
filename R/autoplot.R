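#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_tile
#'   geom_abline geom_errorbar labs scale_fill_gradient2 theme_minimal
NULL

#' @method autoplot kde_estimate
#' @export
autoplot.kde_estimate <- function(object, ...) {
  ggplot(object, aes(x = .data$grid, y = .data$density)) +
    geom_line() +
    labs(x = "distance (Å)", y = "density") +
    theme_minimal()
}

#' @method autoplot histogram_counts
#' @export
autoplot.histogram_counts <- function(object, ...) {
  ggplot(object, aes(x = .data$mid, y = .data$count)) +
    geom_col(width = object$upper[1] - object$lower[1]) +
    labs(x = "distance (Å)", y = "count") +
    theme_minimal()
}

#' @method autoplot distance_distribution
#' @export
autoplot.distance_distribution <- function(object, bins = 150, ...) {
  h <- histogram_counts(object$distance, bins = bins)
  autoplot(h) +
    labs(title = sprintf("minimum distance, residues %d-%d (%s)",
                         attr(object, "res_a"), attr(object, "res_b"),
                         attr(object, "pairing")))
}

#' @method autoplot rmsf_profile
#' @export
autoplot.rmsf_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$resno, y = .data$rmsf,
                     group = .data$chain, colour = .data$chain)) +
    geom_line() +
    labs(x = "residue", y = "RMSF (Å)") +
    theme_minimal()
}

#' @method autoplot dd_matrix
#' @export
autoplot.dd_matrix <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$res_i, y = .data$res_j,
                           fill = .data$difference)) +
    geom_tile() +
    scale_fill_gradient2() +
    labs(x = "residue i", y = "residue j",
         fill = "Δd (Å)",
         title = sprintf("Cα distance-difference matrix, chain %s",
                         object$chain)) +
    theme_minimal()
}

#' @method autoplot fraction_series
#' @export
autoplot.fraction_series <- function(object, ...) {
  ggplot(object, aes(x = .data$time_s, y = .data$filament_fraction)) +
    geom_errorbar(aes(ymin = .data$filament_fraction - .data$se,
                      ymax = .data$filament_fraction + .data$se),
                  width = 0) +
    geom_point() +
    labs(x = "quench time (s)", y = "filament fraction") +
    theme_minimal()
}

#' @method autoplot trend_result
#' @export
autoplot.trend_result <- function(object, ...) {
  df <- object$fit$model
  ggplot(df, aes(x = .data$time_s, y = .data$filament_fraction)) +
    geom_point() +
    geom_abline(slope = object$slope, intercept = object$intercept) +
    labs(x = "quench time (s)", y = "filament fraction",
         subtitle = sprintf("slope %.3g /s, r = %.3f, perm p = %.3g",
                            object$slope, object$r, object$p_perm)) +
    theme_minimal()
}

#' Plot progress curves with the fitted model overlaid
#'
#' @param fit A `scheme_fit` from [fit_progress_curves()].
#' @param curves The curves that were fitted (molar units).
#' @param E0 Enzyme concentration if not in the curves.
#' @return A ggplot object.
#' @export
plot_progress_fit <- function(fit, curves, E0 = NULL) {
  prepared <- prepare_curves(curves, E0)
  model_df <- purrr::map(prepared, function(cv) {
    tms <- if (cv$times[1] > 0) c(0, cv$times) else cv$times
    sim <- simulate_progress(fit$rate_constants, cv$E0, cv$S0, tms)
    tibble(time_s = sim$time_s, value = sim$P, condition = cv$condition)
  }) |> dplyr::bind_rows()
  ggplot(curves, aes(x = .data$time_s, y = .data$value,
                     colour = .data$condition)) +
    geom_point(size = 0.6, alpha = 0.6) +
    geom_line(data = model_df) +
    labs(x = "time (s)", y = "product (M)") +
    theme_minimal()
}
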