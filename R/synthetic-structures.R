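# deterministic chain template: a short helical arc of C-alpha positions,
# chiral and non-collinear so superposition is well conditioned
chain_template <- function(n_res) {
  u <- seq(0, 1, length.out = n_res)
  cbind(x = 6 * cos(2.2 * pi * u),
        y = 6 * sin(2.2 * pi * u),
        z = 12 * (u - 0.5))
}

ca_tibble <- function(coords, chain, resno, model = 1L) {
  tibble(model = model, chain = chain, resno = as.integer(resno),
         resid = "ALA", elety = "CA", element = "C",
         x = coords[, 1], y = coords[, 2], z = coords[, 3],
         occ = 1, b = 0)
}

#' Generate an idealized stacked-ring (filament) C-alpha assembly
#'
#' Builds one or more n-fold symmetric rings of idealized C-alpha-only
#' chains; successive rings are rotated by a configured twist about the ring
#' axis and translated by a configured rise, emulating the stacked-ring
#' architecture of an enzyme filament with a known ground truth. The chains
#' are idealized helical arcs, not real protein folds: the geometry
#' operations need only topology and coordinates.
#'
#' @param chains_per_ring Ring symmetry (default 5).
#' @param n_rings Number of stacked rings (default 2).
#' @param twist_deg Rotation from each ring to the next, degrees (default 26).
#' @param rise_A Axial translation per ring, Angstrom (default 45).
#' @param radius_A Ring radius, Angstrom (default 45).
#' @param n_res Residues per chain (default 30).
#' @param resno Residue numbers, length `n_res` (default `1:n_res`).
#' @param jitter_A SD of isotropic Gaussian coordinate jitter (default 0).
#' @param seed Seed, required when `jitter_A > 0`.
#' @return An `atom_tbl` (single model) with chains labelled A, B, ... ring
#'   by ring, and attribute `truth`: list with `twist_deg`, `rise_A`,
#'   `ring_chains` (list of chain-id vectors per ring).
#' @export
gen_ring_assembly <- function(chains_per_ring = 5L, n_rings = 2L,
                              twist_deg = 26, rise_A = 45, radius_A = 45,
                              n_res = 30L, resno = NULL, jitter_A = 0,
                              seed = NULL) {
  if (chains_per_ring < 3) abort("need >= 3 chains per ring")
  if (is.null(resno)) resno <- seq_len(n_res)
  if (length(resno) != n_res) abort("resno must have length n_res")
  if (jitter_A > 0 && is.null(seed)) abort("seed required when jitter_A > 0")
  if (!is.null(seed)) set.seed(seed)

  template <- sweep(chain_template(n_res), 2, c(radius_A, 0, 0), "+")
  chain_ids <- make.unique(rep(LETTERS, length.out = chains_per_ring * n_rings),
                           sep = "")
  ring_chains <- split(chain_ids,
                       rep(seq_len(n_rings), each = chains_per_ring))

  parts <- list()
  for (ring in seq_len(n_rings)) {
    ring_rot <- rotation_matrix((ring - 1) * twist_deg, c(0, 0, 1))
    ring_shift <- c(0, 0, (ring - 1) * rise_A)
    for (j in seq_len(chains_per_ring)) {
      Rj <- rotation_matrix((j - 1) * 360 / chains_per_ring, c(0, 0, 1))
      xyz <- template %*% t(Rj) %*% t(ring_rot)
      xyz <- sweep(xyz, 2, ring_shift, "+")
      if (jitter_A > 0) {
        xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = jitter_A), ncol = 3)
      }
      parts[[length(parts) + 1]] <-
        ca_tibble(xyz, ring_chains[[ring]][j], resno)
    }
  }
  out <- dplyr::bind_rows(parts)
  class(out) <- c("atom_tbl", class(out))
  attr(out, "truth") <- list(twist_deg = twist_deg, rise_A = rise_A,
                             ring_chains = ring_chains)
  out
}

#' Generate a multi-conformation ensemble with a two-state flexible loop
#'
#' Builds an ensemble of ring assemblies in which a designated loop segment
#' of every chain switches between a closed (template) and an open (displaced)
#' state with a configured occupancy, plus isotropic Gaussian jitter on all
#' atoms. A contact residue is placed so that the minimum distance between it
#' and the loop tip is `contact_distance_A` in the closed state and
#' `contact_distance_A + displacement_A` in the open state, giving known
#' two-point mixtures for distance-distribution checks and the closed-form
#' two-state RMSF `d * sqrt(p (1 - p))` at the loop.
#'
#' @param n_conf Number of conformations (default 20).
#' @param n_chains Chains arranged on one ring (default 10).
#' @param n_res Residues per chain (default 40).
#' @param loop_resno Residue numbers forming the mobile loop (default 20:28;
#'   must be within `1:n_res`).
#' @param displacement_A Open-state displacement of the loop, Angstrom
#'   (default 10).
#' @param occupancy Probability of the open state per chain per conformation
#'   (default 0.5).
#' @param jitter_A SD of Gaussian coordinate jitter (default 0.05).
#' @param contact_distance_A Closed-state contact distance (default 4).
#' @param radius_A Ring radius (default 40).
#' @param seed Seed (required).
#' @return An `atom_tbl` ensemble with attribute `truth`: list with
#'   `occupancy`, `displacement_A`, `expected_loop_rmsf`, `tip_resno`,
#'   `contact_resno`, `closed_distance`, `open_distance`, `loop_resno`.
#' @export
gen_loop_ensemble <- function(n_conf = 20L, n_chains = 10L, n_res = 40L,
                              loop_resno = 20:28, displacement_A = 10,
                              occupancy = 0.5, jitter_A = 0.05,
                              contact_distance_A = 4, radius_A = 40,
                              seed) {
  if (missing(seed) || is.null(seed)) abort("seed is required")
  if (occupancy < 0 || occupancy > 1) abort("occupancy must be in [0, 1]")
  if (n_conf < 2) abort("need >= 2 conformations")
  if (!all(loop_resno %in% seq_len(n_res))) {
    abort("loop_resno must lie within 1:n_res")
  }
  set.seed(seed)

  tip <- loop_resno[ceiling(length(loop_resno) / 2)]
  contact <- min(loop_resno) - 2L
  if (contact < 1) abort("loop_resno leaves no room for the contact residue")

  # local frame: open-state displacement along +x; contact residue sits
  # contact_distance_A below the closed tip along -x
  template <- sweep(chain_template(n_res), 2, c(radius_A, 0, 0), "+")
  u_dir <- c(1, 0, 0)
  template[contact, ] <- template[tip, ] - contact_distance_A * u_dir

  chain_ids <- make.unique(rep(LETTERS, length.out = n_chains), sep = "")
  states <- matrix(stats::runif(n_conf * n_chains) < occupancy,
                   nrow = n_conf)

  confs <- purrr::map(seq_len(n_conf), function(cf) {
    purrr::map(seq_len(n_chains), function(j) {
      xyz <- template
      if (states[cf, j]) {
        xyz[loop_resno, ] <- sweep(xyz[loop_resno, , drop = FALSE], 2,
                                   displacement_A * u_dir, "+")
      }
      Rj <- rotation_matrix((j - 1) * 360 / n_chains, c(0, 0, 1))
      xyz <- xyz %*% t(Rj)
      if (jitter_A > 0) {
        xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = jitter_A), ncol = 3)
      }
      ca_tibble(xyz, chain_ids[j], seq_len(n_res), model = cf)
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(confs)
  class(out) <- c("atom_tbl", class(out))
  attr(out, "truth") <- list(
    occupancy = occupancy, displacement_A = displacement_A,
    expected_loop_rmsf = displacement_A * sqrt(occupancy * (1 - occupancy)),
    tip_resno = tip, contact_resno = contact,
    closed_distance = contact_distance_A,
    open_distance = contact_distance_A + displacement_A,
    loop_resno = loop_resno, states = states, seed = seed)
  out
}
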