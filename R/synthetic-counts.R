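#' Generate particle count tables with a known linear filament-fraction trend
#'
#' Draws filament counts binomially around a true filament fraction that is
#' linear in quench time, `f(t) = slope * t + intercept`, at each of a set of
#' quench times; decamer counts are the remaining assigned particles and
#' unassigned counts are drawn independently. Defaults emulate a
#' time-resolved experiment spanning quench times 57-517 s in which filament
#' fraction grows from about 15% to about 50% of assigned particles.
#'
#' @param times Quench times, seconds (default five times evenly spanning
#'   57-517 s).
#' @param slope True fraction change per second (default 7.6e-4).
#' @param intercept True fraction at t = 0 (default 0.107).
#' @param n_total Assigned particles per dataset (scalar or per-time vector,
#'   default 5000).
#' @param unassigned_frac Expected unassigned fraction of an independent
#'   draw of the same size (default 0.3).
#' @param seed Seed (required).
#' @param mode Processing-mode label stored in the table (default
#'   `"independent"`).
#' @return A `ParticleCountTable` tibble: `dataset_id`, `time_s`,
#'   `n_decamer`, `n_filament`, `n_unassigned`, `mode`; attribute `truth`
#'   records slope/intercept and the per-time true fractions.
#' @export
gen_particle_counts <- function(times = seq(57, 517, length.out = 5),
                                slope = 7.6e-4, intercept = 0.107,
                                n_total = 5000, unassigned_frac = 0.3,
                                seed, mode = "independent") {
  if (missing(seed) || is.null(seed)) abort("seed is required")
  f_true <- slope * times + intercept
  if (any(f_true < 0 | f_true > 1)) {
    abort("true fraction slope*t + intercept leaves [0, 1] at the given times")
  }
  n_total <- rep(n_total, length.out = length(times))
  set.seed(seed)
  n_fil <- stats::rbinom(length(times), size = n_total, prob = f_true)
  n_una <- stats::rbinom(length(times), size = n_total,
                         prob = unassigned_frac)
  out <- tibble(
    dataset_id = sprintf("t%03ds", round(times)),
    time_s = times,
    n_decamer = n_total - n_fil,
    n_filament = n_fil,
    n_unassigned = n_una,
    mode = mode)
  attr(out, "truth") <- list(slope = slope, intercept = intercept,
                             fraction = f_true, n_total = n_total,
                             seed = seed)
  out
}
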