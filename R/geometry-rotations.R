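#' Filament twist and rise between two stacked ring assemblies
#'
#' Superposes the C-alpha atoms of one ring (or decamer) onto the next along
#' the filament axis and reports the screw parameters: the rotation angle
#' reduced modulo the ring symmetry (for 5-fold rings into [0, 36] degrees)
#' and the rise, i.e. the translation component along the rotation axis.
#' Because deposited chain labels are arbitrary, the chain correspondence
#' between the rings may be given explicitly or found automatically as the
#' cyclic assignment minimizing the post-superposition RMSD.
#'
#' @param model An `atom_tbl` (single model used; first model if several).
#' @param ring_a,ring_b Character vectors of chain ids for the two rings, in
#'   ring order.
#' @param symmetry Rotational symmetry of the ring (default 5).
#' @param chain_map Optional integer offset (0 to symmetry-1) fixing the
#'   cyclic correspondence ring_a[i] -> ring_b[i + offset]; `NULL` (default)
#'   tries all offsets and keeps the best.
#' @return List with `twist_deg` (in [0, 180/symmetry]), `rise_A`, `rmsd`,
#'   `chain_map` (the ring_b chains paired with ring_a, in order),
#'   `transform` (the underlying `rigid_transform`).
#' @export
filament_twist <- function(model, ring_a, ring_b, symmetry = 5L,
                           chain_map = NULL) {
  m <- model[model$model == model$model[1], ]
  ca_a <- ring_ca_coords(m, ring_a)
  offsets <- if (is.null(chain_map)) 0:(length(ring_b) - 1) else chain_map
  fits <- purrr::map(offsets, function(off) {
    perm <- ring_b[(seq_along(ring_b) - 1 + off) %% length(ring_b) + 1]
    ca_b <- ring_ca_coords(m, perm)
    if (nrow(ca_a) != nrow(ca_b)) {
      abort(sprintf("C-alpha counts differ between rings (%d vs %d)",
                    nrow(ca_a), nrow(ca_b)))
    }
    list(tr = superpose(ca_a, ca_b), chains = perm)
  })
  best <- fits[[which.min(purrr::map_dbl(fits, ~ .x$tr$rmsd))]]
  tr <- best$tr
  rise <- abs(sum(tr$axis * tr$translation))
  list(twist_deg = rotation_angle(tr, symmetry), rise_A = rise,
       rmsd = tr$rmsd, chain_map = best$chains, transform = tr)
}

ring_ca_coords <- function(m, chains) {
  missing <- setdiff(chains, unique(m$chain))
  if (length(missing)) {
    abort(sprintf("chain(s) not in model: %s", paste(missing, collapse = ", ")))
  }
  dplyr::bind_rows(purrr::map(chains, function(ch) {
    sel <- select_atoms(m, chain = ch, elety = "CA")
    sel[order(sel$resno), ]
  })) |> coords_of()
}

#' Rotation about the ring-ring (pentamer-pentamer) interface between states
#'
#' Quantifies the global conformational change between two states of the same
#' assembly: model B is first superposed onto model A using the C-alpha atoms
#' of an anchor ring; the residual transform between the two probe-ring
#' C-alpha sets is then the rotation of the probe ring relative to the
#' anchor, reported without symmetry reduction.
#'
#' @param model_a,model_b `atom_tbl` structures sharing chain/residue
#'   topology over the selections.
#' @param anchor_chains,probe_chains Chain ids of the anchor and probe rings.
#' @param resno Optional residue subset used for both selections.
#' @return List with `angle_deg`, `anchor_rmsd` (quality of the anchor
#'   alignment), `transform` (probe-ring `rigid_transform`).
#' @export
interpentamer_rotation <- function(model_a, model_b, anchor_chains,
                                   probe_chains, resno = NULL) {
  a <- model_a[model_a$model == model_a$model[1], ]
  b <- model_b[model_b$model == model_b$model[1], ]
  sel <- function(m, chains) {
    s <- select_atoms(m, chain = chains, resno = resno, elety = "CA")
    s <- s[order(match(s$chain, chains), s$resno), ]
    if (nrow(s) == 0) abort("selection resolved to zero atoms")
    coords_of(s)
  }
  anc_a <- sel(a, anchor_chains); anc_b <- sel(b, anchor_chains)
  prb_a <- sel(a, probe_chains); prb_b <- sel(b, probe_chains)
  if (nrow(anc_a) != nrow(anc_b) || nrow(prb_a) != nrow(prb_b)) {
    abort("C-alpha counts differ between models over the selections")
  }
  tr_anchor <- superpose(anc_b, anc_a)
  prb_b_aligned <- apply_transform(tr_anchor, prb_b)
  tr_probe <- superpose(prb_b_aligned, prb_a)
  list(angle_deg = tr_probe$angle_deg, anchor_rmsd = tr_anchor$rmsd,
       transform = tr_probe)
}

#' Inter-domain ("crimping") rotation within a single chain
#'
#' Aligns two states of one chain on a fixed domain (e.g. the catalytic
#' domain) and reports the residual rotation of a mobile domain (e.g. the
#' beta-grasp domain). The result is invariant to any global rigid transform
#' of either model.
#'
#' @param model_a,model_b `atom_tbl` structures.
#' @param chain Chain id analyzed in both models.
#' @param fixed_resno Residue numbers of the fixed (alignment) domain.
#' @param mobile_resno Residue numbers of the mobile domain.
#' @return List with `angle_deg`, `fixed_rmsd`, `transform`.
#' @export
domain_rotation <- function(model_a, model_b, chain, fixed_resno,
                            mobile_resno) {
  a <- model_a[model_a$model == model_a$model[1], ]
  b <- model_b[model_b$model == model_b$model[1], ]
  sel <- function(m, rn) {
    s <- select_atoms(m, chain = chain, resno = rn, elety = "CA")
    s <- s[order(s$resno), ]
    if (nrow(s) == 0) abort("selection resolved to zero atoms")
    coords_of(s)
  }
  fix_a <- sel(a, fixed_resno); fix_b <- sel(b, fixed_resno)
  mob_a <- sel(a, mobile_resno); mob_b <- sel(b, mobile_resno)
  if (nrow(fix_a) != nrow(fix_b) || nrow(mob_a) != nrow(mob_b)) {
    abort("C-alpha counts differ between models over the domain selections")
  }
  tr_fix <- superpose(fix_b, fix_a)
  mob_b_aligned <- apply_transform(tr_fix, mob_b)
  tr_mob <- superpose(mob_b_aligned, mob_a)
  list(angle_deg = tr_mob$angle_deg, fixed_rmsd = tr_fix$rmsd,
       transform = tr_mob)
}
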