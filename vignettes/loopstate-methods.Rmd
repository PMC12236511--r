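---
title: "Models and methods behind loopstate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind loopstate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopstate)
```

`loopstate` implements the quantitative analyses used to characterize an
enzyme that polymerizes into filaments with functional consequences: full
progress-curve kinetics of a coupled ATPase assay, geometric statistics on
conformational ensembles of the assembly, and trend inference on
time-resolved particle-class counts. This vignette explains the models, the
defaults and why they were chosen, the numerical decisions, and what the
synthetic-data generators do and do not emulate.

## 1. Kinetics

### The reaction scheme

Steady-state activity is measured through an NADH-coupled assay: ADP
production is reported 1:1 by NADH oxidation, read as absorbance loss at
340 nm. The package treats the coupling enzymes as an instantaneous
stoichiometric reporter; their own kinetics are out of scope, and
`crop_to_exhaustion()` restricts fits to the part of a curve where at most
a configurable fraction (default 10%) of the reporter pool has been
consumed, because the coupling system stops being non-rate-limiting late in
the reaction.

The kinetic model is the minimal three-step scheme

$$E + S \underset{k_{-1}}{\overset{k_1}{\rightleftharpoons}} ES
  \underset{k_{-2}}{\overset{k_2}{\rightleftharpoons}} EP
  \overset{k_3}{\rightarrow} E + P$$

with mass-action ODEs integrated by `simulate_progress()`. Free enzyme is
eliminated through the conservation law $E = E_0 - ES - EP$, and both
enzyme and substrate conservation are verified to hold along every
trajectory (to better than $10^{-9}$ relative in the test suite). The
steady-state parameters follow in closed form:

$$k_{cat} = \frac{k_2 k_3}{k_2 + k_{-2} + k_3}, \qquad
  \frac{k_{cat}}{K_M} = \frac{k_1 k_2 k_3}
  {k_{-1}k_{-2} + k_{-1}k_3 + k_2 k_3}, \qquad
  K_M = \frac{k_{cat}}{k_{cat}/K_M}.$$

These closed forms are the unique steady-state algebra of the scheme. They
are validated against an independent numerical oracle (the clamped-substrate
steady state solved by linear algebra, followed by a hyperbola fit over 50
substrate concentrations) to a relative error below $10^{-3}$ over a
100-point random sweep of rate constants spanning six decades each.

### Numerical choices

* **Integration.** `deSolve::lsoda`, a stiff-capable adaptive integrator,
  with relative tolerance $10^{-8}$ and absolute tolerance $10^{-12}$ M.
  The system becomes stiff when $k_1 S_0$ is large relative to the
  unimolecular rates. Internally the state is rescaled by
  $\max(S_0, E_0)$ so that micromolar trajectories are integrated near
  unit magnitude; tolerances are rescaled correspondingly, so the
  documented molar tolerances are preserved.
* **Global fitting.** `fit_progress_curves()` minimizes the weighted
  chi-square $\sum \left((P_{model} - P_{obs})/\sigma\right)^2$ jointly over
  all curves, with the five rate constants parameterized in $\log_{10}$
  space (positivity for free, better conditioning). Optimization is
  trust-region Levenberg–Marquardt (`minpack.lm::nls.lm`) from 8 seeded
  random starts drawn from broad log-uniform ranges; the best three coarse
  basins are polished and the lowest chi-square wins. Box constraints two
  decades beyond the start ranges keep the optimizer out of regimes where
  the ODE system is numerically insoluble (such evaluations return a large
  penalty rather than failing).
* **Weights.** Per-point standard deviations from replicate averaging are
  the weights. Zero or missing SDs are raised to a floor of 0.1% of the
  per-curve dynamic range, to avoid infinite weights on coincidentally
  noise-free points; the fit records when flooring occurred.
* **Identifiability.** Full progress curves at a few starting substrate
  concentrations determine $k_{cat}$, $K_M$ and $k_{cat}/K_M$ well, but not
  all five elementary constants: multiplying $k_1$ by 10 while rescaling
  $k_{-1}$ to hold $K_M$ fixed changes the chi-square by less than
  $10^{-3}$ relative. The fit therefore profiles each constant within
  $\pm 1$ log unit (re-optimizing the others) and flags it non-identifiable
  when the chi-square changes by less than 2. Only the steady-state
  combinations are guaranteed deliverables; they are returned by
  `derive_steady_state()` with the fitted covariance.
* **Uncertainty propagation.** Default is the first-order delta method with
  numerical gradients of the closed forms; a Monte-Carlo mode (default
  10000 seeded resamples from the parameter covariance) is available as a
  cross-check and agrees within 25% for well-conditioned covariances.
* **Calibration.** The absorbance-per-molar coefficient is fitted per
  experiment from an NADH titration (`calibrate_pathlength()`, OLS with a
  free intercept). The textbook coefficient of 6220 AU/M (extinction
  coefficient at 340 nm times a 1 cm path) is only a fallback when no
  titration exists; an empirical calibration always takes precedence
  because plate wells have variable effective pathlengths.
* **Initial rates.** `fit_initial_rates()` fits
  $v_0 = k_{cat}[S]/(K_M + [S])$ by Levenberg–Marquardt. When the data
  carry no curvature (all points in the linear regime) the estimated $K_M$
  runs far outside the measured range; the fit is then flagged
  non-converged rather than returning boundary values.

### Study conditions emulated by the generator

`gen_progress_curves()` produces the design the kinetics pipeline expects:
three starting substrate concentrations of 750, 375 and 188 uM, eight
replicates each, a five-minute read. Defaults chosen once and documented
here: a 5 s sampling interval (typical of plate readers in kinetic mode;
the source assays report only the total duration), enzyme at 2.4 uM
(0.1 mg/mL at a ~42 kDa subunit), Gaussian per-point noise with SD equal to
1% of each curve's final signal (plate-reader noise is additive to good
approximation), and true rate constants
$k_1 = 10^5\,\mathrm{M^{-1}s^{-1}}, k_{-1} = 6, k_2 = 5, k_{-2} = 0.5,
k_3 = 5\ \mathrm{s^{-1}}$, giving $k_{cat} \approx 2.4\,\mathrm{s^{-1}}$ and
$K_M \approx 55$ uM — the regime of the ammonia kinetics this tooling
targets. Replicate-level fitting is possible, but the default pipeline
averages replicates and fits the mean with per-point SDs, matching the
stated analysis procedure.

## 2. Ensemble geometry

Structures are tidy atom tables (one row per atom per model) read from PDB
or mmCIF via bio3d. Author residue numbering is preserved as deposited;
alternate locations resolve to the highest-occupancy conformer with ties
broken alphabetically; multi-model files must share topology exactly.

* **Superposition.** `superpose()` is the Kabsch algorithm (SVD of the
  cross-covariance with the determinant correction, so a reflection is
  never returned). The rotation angle is
  $\theta = \arccos((\mathrm{tr}\,R - 1)/2)$ and the axis comes from the
  antisymmetric part of $R$, falling back to the unit eigenvector near
  180 degrees. Tests verify agreement with a brute-force axis/angle search.
* **Filament twist.** `filament_twist()` superposes one ring's C-alpha
  atoms onto the next and reports the screw parameters: rotation reduced
  modulo the ring symmetry into $[0, 36]$ degrees for 5-fold rings (any
  value outside that range is equivalent under the dihedral symmetry of
  the assembly), and rise as the translation component along the rotation
  axis. Deposited chain labels are arbitrary, so the cyclic chain
  correspondence is found automatically by minimizing the superposition
  RMSD over the five cyclic assignments, unless supplied explicitly.
* **Interface and domain rotations.** `interpentamer_rotation()` aligns two
  states on an anchor ring and reports the residual probe-ring rotation
  (no symmetry reduction — the interesting signal is a fraction of a
  degree). `domain_rotation()` does the same within a chain, aligning on a
  fixed domain and reporting the mobile domain's rotation; both are
  invariant to global rigid transforms of either input.
* **RMSF.** Conformations are superposed onto the ensemble mean by
  iterative mean-structure alignment (two passes), then
  $\mathrm{RMSF} = \sqrt{\langle \|x - \bar{x}\|^2\rangle}$ per reported
  atom (C-alpha by default). The alignment selection excludes the flexible
  active-site gating loop (residues 289–312 by default, configurable) so
  loop motion is not absorbed into the fit. The exact alignment selection
  used by any upstream study is rarely stated; the default here is a
  documented package choice, not a claim about any particular publication.
  For a loop hopping between two states separated by $d$ with occupancy
  $p$, the RMSF is $d\sqrt{p(1-p)}$ — the package recovers this closed
  form to 1%.
* **Distance distributions.** `min_distance_distribution()` takes, per
  conformation and per chain, the minimum distance over all atom pairs of
  a residue pair (10 values per conformation for a 10-chain assembly).
  Hydrogens are excluded by default so MD-derived ensembles (which have
  them) and deposited models (which may not) are comparable. The KDE uses
  a Gaussian kernel with Scott's-rule base bandwidth
  $\hat\sigma n^{-1/5}$ times an adjustment factor (default 1); the
  adjustment factor is the conventionally reported quantity, the base rule
  is a documented choice. Histograms use 150 equal-width bins with an
  inclusive right-most edge, so counts are always conserved.
* **Distance-difference matrices.** `ca_distance_difference()` computes
  $D_{ij} = \|x_i^A - x_j^A\| - \|x_i^B - x_j^B\|$ over one chain's
  C-alpha atoms, after excluding configurable residue ranges (typically
  the gating loop and a disordered terminal peptide, whose heterogeneity
  would otherwise dominate the map). Being built from intramolecular
  distances it is exactly invariant to rigid motions, and the largest
  absolute entry is reported with its residue pair.
* **Single-pair distances.** `ca_pair_distance()` measures one C-alpha
  pair, intra-chain or across adjacent chains, and always reports which
  pairing was used — cross-interface contacts are ambiguous between the
  two conventions, so the choice is never silent.

### What the structure generators emulate

`gen_ring_assembly()` builds idealized C-alpha-only chains (short chiral
helical arcs) arranged in n-fold rings, with configurable twist and rise
between stacked rings; `gen_loop_ensemble()` adds a two-state loop segment
with configured displacement, occupancy and isotropic jitter, plus a
contact residue placed so the loop-tip minimum distance is an exact
two-point mixture. These are deliberately not protein folds: the geometry
operations consume only topology and coordinates, and real folds add no
test power. What the generators do **not** emulate: side chains and their
packing, correlated (non-isotropic) coordinate uncertainty, partial
occupancy density, missing residues, or experimental map noise — so
passing round-trips demonstrate the correctness of the measurement
machinery, not robustness to every pathology of real deposited models.

## 3. Time-resolved particle fractions

`compute_fractions()` normalizes decamer and filament particle picks to
the total assigned particles, excluding unclassifiable picks from the
denominator, with binomial standard errors $\sqrt{f(1-f)/n}$. All results
are invariant to the unassigned counts.

`linear_trend()` fits the fraction-versus-quench-time line by OLS.
Because such series are tiny (five datasets is typical), inference is
non-parametric:

* a two-sided permutation p-value from shuffling the time labels (10000
  seeded permutations by default), using the add-one estimator
  $(1 + \#\{|b^*| \ge |b|\})/(n_{perm}+1)$;
* a 95% confidence interval for the slope from resampling rows with
  replacement. The interval is a **bootstrap-t** construction — slope
  $\pm\ t_{n-2,0.975}$ times the bootstrap SD — rather than raw
  percentiles, because with five rows the percentile interval measurably
  undercovers (about 89% at nominal 95% on the binomial generator, versus
  about 98% for the bootstrap-t form). Coverage is verified in the test
  suite on the binomial generator.

Rows are unweighted by default, matching the one-dataset-one-point
convention of such plots; inverse-variance weighting by the binomial SE is
available by flag. Seeds are mandatory for any resampling operation.
`compare_modes()` contrasts per-dataset fractions between
independently-classified and pooled-classified processing, with combined
binomial errors; which mode a given study plotted is often unstated, so
both are supported and reported side by side.

`gen_particle_counts()` draws filament counts binomially around a linear
true fraction at five quench times spanning 57–517 s. Default line: from
about 15% filament at the first quench to about 50% at the last
(slope $7.6\times10^{-4}\,\mathrm{s^{-1}}$, intercept 0.107), the
magnitude of filament accumulation such experiments report; 5000 assigned
particles per dataset is a typical per-class yield. The binomial noise
model assumes independent particle assignment, which ignores
micrograph-level correlations in real data.

## 4. Problem sizes and statistical checks

The test suite runs at sizes chosen to make every statistical check
well-powered yet quick: a 100-point rate-constant sweep for the
steady-state algebra; 20 seeded simulate-and-refit repeats for
progress-curve recovery (pass = both $k_{cat}$ and $K_M$ within 10%);
20-to-30-conformation ensembles for geometry round-trips; 1000 null
simulations (2000 permutations each) for the uniformity of the permutation
p-value — at 200 simulations the Kolmogorov–Smirnov statistic of genuinely
uniform draws already exceeds 0.05 more often than not
($\mathbb{E}[D_n] \approx 0.87/\sqrt{n}$), so 1000 draws are used to give
the 0.05 bound its intended meaning — and 100 repeats for bootstrap
coverage.

## 5. Known limitations

* The kinetics module treats the varied substrate against a saturating
  background (the scheme is effectively single-substrate); multi-substrate
  mechanism discrimination is out of scope.
* Elementary rate constants from progress curves are reported but usually
  non-identifiable; only $k_{cat}$, $K_M$, $k_{cat}/K_M$ should be quoted.
* The geometry module analyzes coordinates only: no density maps, map-model
  quality scores, or B-factor statistics.
* Synthetic ensembles validate the measurement pipeline; conclusions about
  any particular deposited model still require running the same operations
  on its coordinates.
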