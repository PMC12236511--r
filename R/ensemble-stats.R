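#' Per-residue RMSF of a conformational ensemble
#'
#' Each conformation is superposed onto the ensemble mean structure by
#' iterative mean-structure alignment (two passes: align onto the first
#' conformation, recompute the mean, re-align onto it), using the C-alpha
#' atoms of the alignment selection. The RMSF of a residue's reported atom
#' is the root-mean-square displacement from its mean position across
#' conformations. By default the alignment excludes the flexible active-site
#' gating loop (residues 289-312) so that loop motion is not absorbed into
#' the fit; the exclusion is configurable.
#'
#' @param ensemble An `atom_tbl` with >= 2 models.
#' @param chains Chains analyzed (default all).
#' @param align_resno Residues used for alignment (default all except
#'   `exclude_align_resno`).
#' @param exclude_align_resno Residues excluded from the alignment selection
#'   (default 289:312, the gating-loop range; ignored when absent).
#' @param atom Reported atom name (default `"CA"`).
#' @return A tibble of class `rmsf_profile`: columns `chain`, `resno`,
#'   `rmsf` (Angstrom).
#' @export
rmsf <- function(ensemble, chains = NULL, align_resno = NULL,
                 exclude_align_resno = 289:312, atom = "CA") {
  if (n_models(ensemble) < 2) abort("RMSF needs an ensemble of >= 2 models")
  ens <- if (is.null(chains)) ensemble else ensemble[ensemble$chain %in% chains, ]

  models <- split_models(ens)
  align_idx <- with(models[[1]],
    elety == atom &
      (if (is.null(align_resno)) !(resno %in% exclude_align_resno)
       else resno %in% align_resno))
  if (sum(align_idx) < 3) abort("alignment selection has < 3 atoms")
  report_idx <- models[[1]]$elety == atom

  X <- purrr::map(models, coords_of)
  aligned <- align_to_reference(X, X[[1]], align_idx)
  mean1 <- Reduce(`+`, aligned) / length(aligned)
  aligned <- align_to_reference(X, mean1, align_idx)
  mean2 <- Reduce(`+`, aligned) / length(aligned)

  disp2 <- Reduce(`+`, purrr::map(aligned, ~ rowSums((.x - mean2)^2))) /
    length(aligned)
  out <- tibble(chain = models[[1]]$chain[report_idx],
                resno = models[[1]]$resno[report_idx],
                rmsf = sqrt(disp2[report_idx]))
  class(out) <- c("rmsf_profile", class(out))
  out
}

align_to_reference <- function(X, ref, align_idx) {
  purrr::map(X, function(xi) {
    tr <- superpose(xi[align_idx, , drop = FALSE],
                    ref[align_idx, , drop = FALSE])
    apply_transform(tr, xi)
  })
}

#' Minimum inter-residue distance distribution over an ensemble
#'
#' For every conformation and every analyzed chain, computes the minimum
#' distance between any two atoms of the selected residue pair — the summary
#' used for stabilizing-contact distributions. Intra-chain pairing is the
#' default; cross-chain contacts (e.g. across a ring interface) are obtained
#' with an explicit chain map. Hydrogens are excluded by default so that MD
#' ensembles (which carry them) and deposited models (which may not) are
#' comparable.
#'
#' @param ensemble An `atom_tbl`.
#' @param res_a,res_b Author residue numbers of the pair.
#' @param chains Chains analyzed (default all chains in the ensemble); for a
#'   10-chain assembly this yields 10 distances per conformation.
#' @param chain_map Optional named character vector mapping the chain holding
#'   `res_a` to the chain holding `res_b` (cross-chain pairing); default
#'   pairs within each chain.
#' @param exclude_hydrogens Drop atoms with element H (default TRUE).
#' @return A tibble of class `distance_distribution`: columns `model`,
#'   `chain_a`, `chain_b`, `distance` (Angstrom). Attributes record the
#'   residue pair and pairing mode.
#' @export
min_distance_distribution <- function(ensemble, res_a, res_b, chains = NULL,
                                      chain_map = NULL,
                                      exclude_hydrogens = TRUE) {
  ens <- ensemble
  if (exclude_hydrogens && "element" %in% names(ens)) {
    ens <- ens[ens$element != "H", ]
  }
  if (is.null(chains)) chains <- unique(ens$chain)
  if (is.null(chain_map)) {
    chain_map <- setNames(chains, chains)
  }
  models <- split_models(ens)
  rows <- purrr::map(models, function(m) {
    purrr::map(names(chain_map), function(ca) {
      cb <- chain_map[[ca]]
      A <- coords_of(select_atoms(m, chain = ca, resno = res_a))
      B <- coords_of(select_atoms(m, chain = cb, resno = res_b))
      if (nrow(A) == 0) {
        abort(sprintf("residue %d missing in chain %s", res_a, ca))
      }
      if (nrow(B) == 0) {
        abort(sprintf("residue %d missing in chain %s", res_b, cb))
      }
      tibble(model = m$model[1], chain_a = ca, chain_b = cb,
             distance = min_cross_distance(A, B))
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "res_a") <- res_a
  attr(out, "res_b") <- res_b
  attr(out, "pairing") <- if (all(names(chain_map) == unname(chain_map)))
    "intra-chain" else "cross-chain"
  class(out) <- c("distance_distribution", class(out))
  out
}

min_cross_distance <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(min(d2), 0))
}

#' Gaussian kernel density estimate with Scott's-rule bandwidth
#'
#' Density of a sample of distances (or any 1-D values) using a Gaussian
#' kernel whose base bandwidth is Scott's rule, `sd(x) * n^(-1/5)`,
#' multiplied by an adjustment factor; evaluated on a 512-point grid spanning
#' `[min - 3h, max + 3h]`. The returned density integrates to 1 (within
#' 1e-3 by the trapezoid rule on its grid).
#'
#' @param samples Numeric vector, >= 2 values with nonzero variance.
#' @param bandwidth_adjust Multiplier on the Scott bandwidth (default 1).
#' @param n_grid Grid size (default 512).
#' @return A tibble of class `kde_estimate`: columns `grid`, `density`;
#'   attribute `bandwidth`.
#' @export
kde_density <- function(samples, bandwidth_adjust = 1, n_grid = 512) {
  x <- as.numeric(samples)
  x <- x[is.finite(x)]
  if (length(x) < 2) abort("KDE needs >= 2 finite samples")
  if (sd(x) == 0) {
    abort("zero-variance samples: KDE undefined, use histogram_counts()")
  }
  h <- sd(x) * length(x)^(-1 / 5) * bandwidth_adjust
  d <- density(x, bw = h, from = min(x) - 3 * h, to = max(x) + 3 * h,
               n = n_grid, kernel = "gaussian")
  out <- tibble(grid = d$x, density = d$y)
  attr(out, "bandwidth") <- h
  class(out) <- c("kde_estimate", class(out))
  out
}

#' Equal-width histogram counts
#'
#' Bins a sample into `bins` equal-width intervals spanning [min, max]; the
#' right-most edge is inclusive, so counts always sum to the sample size.
#' The 150-bin default matches common practice for contact-distance
#' distributions.
#'
#' @param samples Numeric vector, >= 1 finite value.
#' @param bins Number of bins (default 150).
#' @return A tibble of class `histogram_counts`: columns `lower`, `upper`,
#'   `mid`, `count`; attribute `edges`.
#' @export
histogram_counts <- function(samples, bins = 150) {
  x <- as.numeric(samples)
  x <- x[is.finite(x)]
  if (length(x) < 1) abort("histogram needs >= 1 finite sample")
  rng <- range(x)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- graphics::hist(x, breaks = edges, include.lowest = TRUE, right = TRUE,
                      plot = FALSE)
  out <- tibble(lower = edges[-length(edges)], upper = edges[-1],
                mid = h$mids, count = h$counts)
  attr(out, "edges") <- edges
  class(out) <- c("histogram_counts", class(out))
  out
}

#' C-alpha distance-difference matrix between two conformational states
#'
#' For one chain present in both models, computes
#' `D(i,j) = |CA_i^A - CA_j^A| - |CA_i^B - CA_j^B|` over all included
#' residue pairs. Being built from intramolecular distances it is invariant
#' to any rigid transform of either model. Flexible segments whose
#' heterogeneity would dominate the map (e.g. the gating loop and a
#' disordered terminal peptide) can be excluded by residue range.
#'
#' @param model_a,model_b `atom_tbl` structures.
#' @param chain Chain id to analyze.
#' @param exclusions Integer vector of residue numbers to omit (e.g.
#'   `c(289:312, 369:373)`); default none.
#' @return An object of class `dd_matrix`: list with `matrix` (symmetric,
#'   zero diagonal, dimnames = residue numbers), `residues`, `chain`,
#'   `exclusions`, and `max_pair` (tibble: `res_i`, `res_j`, `difference`
#'   with the largest absolute entry).
#' @export
ca_distance_difference <- function(model_a, model_b, chain,
                                   exclusions = NULL) {
  ca <- function(m) {
    s <- select_atoms(m[m$model == m$model[1], ], chain = chain,
                      elety = "CA", exclude_resno = exclusions)
    s[order(s$resno), ]
  }
  a <- ca(model_a); b <- ca(model_b)
  if (!identical(a$resno, b$resno)) {
    only_a <- setdiff(a$resno, b$resno)
    only_b <- setdiff(b$resno, a$resno)
    abort(sprintf(
      "residue sets differ after exclusion (only in A: %s; only in B: %s)",
      paste(only_a, collapse = ","), paste(only_b, collapse = ",")))
  }
  if (nrow(a) < 2) abort("fewer than 2 residues after exclusion")
  DA <- as.matrix(stats::dist(coords_of(a)))
  DB <- as.matrix(stats::dist(coords_of(b)))
  D <- DA - DB
  dimnames(D) <- list(a$resno, a$resno)
  idx <- which(abs(D) == max(abs(D)), arr.ind = TRUE)[1, ]
  structure(
    list(matrix = D, residues = a$resno, chain = chain,
         exclusions = exclusions,
         max_pair = tibble(res_i = a$resno[idx[1]], res_j = a$resno[idx[2]],
                           difference = D[idx[1], idx[2]])),
    class = "dd_matrix")
}

#' @export
print.dd_matrix <- function(x, ...) {
  cat(sprintf("C-alpha distance-difference matrix, chain %s, %d residues\n",
              x$chain, length(x$residues)))
  cat(sprintf("  largest |difference|: %.3f A between residues %d and %d\n",
              x$max_pair$difference, x$max_pair$res_i, x$max_pair$res_j))
  invisible(x)
}

#' @method tidy dd_matrix
#' @export
tidy.dd_matrix <- function(x, ...) {
  D <- x$matrix
  expand.grid(res_i = x$residues, res_j = x$residues) |>
    as_tibble() |>
    dplyr::mutate(difference = as.vector(D))
}

#' Single C-alpha to C-alpha distance between two residues
#'
#' Measures one inter-residue C-alpha distance, typically across a ring
#' interface (e.g. residue 74 of one chain against residue 263 of the
#' adjacent chain). Applied to two models and subtracted, it gives the
#' distance change accompanying a conformational transition. The chain
#' pairing actually measured is returned so intra- vs cross-chain use is
#' never silent.
#'
#' @param model An `atom_tbl`.
#' @param chain_a,res_a Chain and residue of the first C-alpha.
#' @param chain_b,res_b Chain and residue of the second C-alpha (default
#'   `chain_b = chain_a`, i.e. intra-chain).
#' @return List with `distance` (Angstrom), `pairing` (`"intra-chain"` or
#'   `"cross-chain"`), `chain_a`, `chain_b`, `res_a`, `res_b`.
#' @export
ca_pair_distance <- function(model, chain_a, res_a, chain_b = chain_a,
                             res_b) {
  m <- model[model$model == model$model[1], ]
  pa <- select_atoms(m, chain = chain_a, resno = res_a, elety = "CA")
  pb <- select_atoms(m, chain = chain_b, resno = res_b, elety = "CA")
  if (nrow(pa) != 1) {
    abort(sprintf("C-alpha of residue %d in chain %s not found (or not unique)",
                  res_a, chain_a))
  }
  if (nrow(pb) != 1) {
    abort(sprintf("C-alpha of residue %d in chain %s not found (or not unique)",
                  res_b, chain_b))
  }
  d <- sqrt(sum((coords_of(pa) - coords_of(pb))^2))
  list(distance = d,
       pairing = if (chain_a == chain_b) "intra-chain" else "cross-chain",
       chain_a = chain_a, chain_b = chain_b, res_a = res_a, res_b = res_b)
}
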