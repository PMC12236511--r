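#' Read an atomic structure or multi-model ensemble into a tidy atom table
#'
#' Parses PDB or mmCIF coordinate files (via bio3d) into a long tibble with
#' one row per atom per model. Multi-model files (MODEL/ENDMDL blocks, e.g.
#' ensemble-refinement output) yield one `model` value per conformation;
#' topology (chain, residue, atom name) is required to be identical across
#' models. Alternate locations are resolved to the highest-occupancy
#' conformer (ties broken alphabetically by altloc id). Coordinates are in
#' Angstrom; author residue numbering is preserved as deposited.
#'
#' @param path Path to the coordinate file.
#' @param format `"pdb"` or `"cif"`; default guessed from the extension.
#' @return A tibble of class `atom_tbl` with columns `model`, `chain`,
#'   `resno`, `resid`, `elety` (atom name), `element`, `x`, `y`, `z`, `occ`,
#'   `b`.
#' @export
read_structure <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- switch(format,
    pdb = bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    cif = bio3d::read.cif(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    abort(sprintf("unknown format '%s' (use 'pdb' or 'cif')", format)))
  atom_tbl_from_bio3d(pdb)
}

atom_tbl_from_bio3d <- function(pdb) {
  at <- pdb$atom
  n_models <- nrow(pdb$xyz)
  keep <- resolve_altloc(at)
  at <- at[keep, , drop = FALSE]

  per_model <- purrr::map(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE]
    tibble(
      model = m,
      chain = as.character(at$chain),
      resno = as.integer(at$resno),
      resid = as.character(at$resid),
      elety = as.character(at$elety),
      element = element_of(at),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occ = as.numeric(at$o), b = as.numeric(at$b))
  })
  out <- dplyr::bind_rows(per_model)
  if (any(!is.finite(out$x + out$y + out$z))) {
    abort("non-finite coordinates in structure file")
  }
  check_shared_topology(out)
  class(out) <- c("atom_tbl", class(out))
  out
}

# highest occupancy wins; ties broken alphabetically by altloc id
resolve_altloc <- function(at) {
  alt <- at$alt
  if (all(is.na(alt) | alt == "")) return(seq_len(nrow(at)))
  key <- paste(at$chain, at$resno, at$elety, sep = "\r")
  ord <- order(key, -at$o, dplyr::coalesce(alt, ""))
  sort(ord[!duplicated(key[ord])])
}

element_of <- function(at) {
  el <- as.character(at$elesy)
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # fall back to the first alphabetic character of the atom name
    el[miss] <- toupper(sub("^[0-9]*([A-Za-z]).*$", "\\1", at$elety[miss]))
  }
  toupper(trimws(el))
}

check_shared_topology <- function(tbl) {
  keys <- split(paste(tbl$chain, tbl$resno, tbl$elety, sep = "\r"), tbl$model)
  ref <- keys[[1]]
  for (m in seq_along(keys)[-1]) {
    if (!identical(keys[[m]], ref)) {
      bad <- which(keys[[m]] != ref)[1]
      if (is.na(bad)) bad <- min(length(ref), length(keys[[m]])) + 1
      abort(sprintf(
        "model %s topology differs from model 1 at atom %d (%s vs %s)",
        names(keys)[m], bad,
        if (bad <= length(keys[[m]])) gsub("\r", "/", keys[[m]][bad]) else "<absent>",
        if (bad <= length(ref)) gsub("\r", "/", ref[bad]) else "<absent>"))
    }
  }
  invisible(tbl)
}

#' Write an atom table to a (multi-model) PDB file
#'
#' Single-model tables produce a plain PDB; tables with several `model`
#' values produce MODEL/ENDMDL blocks. Coordinates are written at PDB
#' fixed-width precision (1e-3 Angstrom).
#'
#' @param struct An `atom_tbl` tibble (see [read_structure()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(struct, path) {
  check_columns(struct, c("model", "chain", "resno", "elety", "x", "y", "z"),
                "struct")
  m1 <- struct[struct$model == struct$model[1], ]
  xyz <- t(vapply(split_models(struct), function(df) {
    as.numeric(t(as.matrix(df[, c("x", "y", "z")])))
  }, numeric(3 * nrow(m1))))
  if (nrow(m1) == 1) xyz <- matrix(xyz, ncol = 3)
  bio3d::write.pdb(
    file = path, xyz = xyz,
    chain = m1$chain, resno = m1$resno,
    resid = if ("resid" %in% names(m1)) m1$resid else "ALA",
    eleno = seq_len(nrow(m1)), elety = m1$elety,
    o = if ("occ" %in% names(m1)) m1$occ else 1,
    b = if ("b" %in% names(m1)) m1$b else 0,
    elesy = if ("element" %in% names(m1)) m1$element else "C")
  invisible(path)
}

split_models <- function(struct) {
  split(struct, struct$model)
}

#' Number of conformations in an atom table
#' @param struct An `atom_tbl`.
#' @return Integer count of distinct models.
#' @export
n_models <- function(struct) dplyr::n_distinct(struct$model)

# coordinate matrix (n_atoms x 3) of a filtered single-model selection
coords_of <- function(tbl) {
  as.matrix(tbl[, c("x", "y", "z")])
}

# select atoms: by chain(s), residue numbers, atom name(s); single model
# unless model = NULL (all models)
select_atoms <- function(struct, chain = NULL, resno = NULL, elety = NULL,
                         model = NULL, exclude_resno = NULL,
                         exclude_hydrogens = FALSE) {
  out <- struct
  if (!is.null(model)) out <- out[out$model %in% model, ]
  if (!is.null(chain)) out <- out[out$chain %in% chain, ]
  if (!is.null(resno)) out <- out[out$resno %in% resno, ]
  if (!is.null(exclude_resno)) out <- out[!out$resno %in% exclude_resno, ]
  if (!is.null(elety)) out <- out[out$elety %in% elety, ]
  if (exclude_hydrogens && "element" %in% names(out)) {
    out <- out[out$element != "H", ]
  }
  out
}
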