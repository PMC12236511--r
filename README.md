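# loopstate

Quantitative analysis of enzyme filamentation experiments: full
progress-curve kinetics, structural-ensemble geometry, and time-resolved
particle-fraction trends, with seeded synthetic-data generators so every
stage runs and is testable without external downloads.

## The scientific problem

Some metabolic enzymes reversibly polymerize into filaments, and
polymerization can change their catalysis. Characterizing this requires
three quantitative pipelines that this package provides as composable,
tibble-first R functions:

1. **Kinetics.** Activity is read through an NADH-coupled assay
   (absorbance loss at 340 nm reports ADP production 1:1). When the
   substrate concentrations needed to measure K_M are so low that initial
   rates are unusable, the full progress curve is fitted to the mass-action
   ODE system of the three-step scheme

   E + S ⇌(k1, k−1) ES ⇌(k2, k−2) EP →(k3) E + P

   and the steady-state parameters are derived with propagated uncertainty:

   k_cat = k2·k3/(k2 + k−2 + k3),
   k_cat/K_M = k1·k2·k3/(k−1·k−2 + k−1·k3 + k2·k3),
   K_M = k_cat/(k_cat/K_M).

2. **Ensemble geometry.** From multi-model coordinate files (e.g. Bayesian
   ensemble refinement output): least-squares superposition with rotation
   angle/axis extraction, per-residue RMSF, minimum inter-residue distance
   distributions with kernel density estimates (Scott bandwidth × adjust
   factor) and 150-bin histograms, Cα distance-difference matrices, helical
   filament twist/rise, ring-interface rotation, and per-monomer domain
   ("crimping") rotation.

3. **Time-resolved particle fractions.** Decamer vs filament class counts
   across reaction quench times are converted to fractions with binomial
   errors, and the linear trend with time is tested by permutation
   (two-sided, seeded) with a bootstrap-t confidence interval for the
   slope — appropriate at the tiny n (≈5 datasets) these experiments have.

## Worked example

```r
library(loopstate)

# --- kinetics: simulate the assay design, fit, derive parameters ---------
curves <- gen_progress_curves(seed = 11)      # 3 x S0, 8 replicates, 5 min
avg    <- average_replicates(curves)
fit    <- fit_progress_curves(avg, seed = 2)
fit$steady_state
#> # A tibble: 3 × 3
#>   term              estimate     std.error
#> * <chr>                <dbl>         <dbl>
#> 1 kcat             2.38        0.00588
#> 2 KM               0.0000548   0.000000669
#> 3 kcat_over_KM 43313.        437.
```

The generator's ground truth is kcat = 2.381 1/s and KM = 55.2 uM
(from k1 = 1e5 /M/s, k−1 = 6, k2 = 5, k−2 = 0.5, k3 = 5 /s), so the fit
recovers the turnover number to ~0.3% and the Michaelis constant to ~1%
at 1% trace noise. Elementary constants that the curves cannot pin down
are flagged `non-identifiable` by ±1-log-unit profiling; quote only the
steady-state combinations.

```r
# --- geometry: a filament with known twist -------------------------------
fil <- gen_ring_assembly(twist_deg = 26, rise_A = 45)
rc  <- attr(fil, "truth")$ring_chains
filament_twist(fil, rc[[1]], rc[[2]])[c("twist_deg", "rise_A")]
#> $twist_deg
#> [1] 26
#> $rise_A
#> [1] 45

# --- counts: fraction trend over quench times ----------------------------
tab <- gen_particle_counts(seed = 7)          # 5 quench times, 57-517 s
fr  <- compute_fractions(tab)
linear_trend(fr, n_perm = 2000, n_boot = 2000, seed = 8)
#> Linear trend: slope 0.000725 /s (95% boot CI 0.000648 to 0.000802),
#> r = 0.999, perm p = 0.01099 (n = 5)
```

The slope says the filament fraction grows by ~0.07 percentage points per
second of reaction time; the permutation p-value is the exact-style
two-sided test against no time dependence (its floor at n = 5 datasets is
1/(n_perm + 1) over the 120 distinct orderings).

Result objects have `tidy()`/`glance()` methods and `autoplot()` /
`plot_progress_fit()` visualizations.

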