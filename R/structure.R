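## Multi-model coordinate container for duplex DNA.
##
## A `dna_structure` holds one atom table (the topology, shared by every
## model) and a list of coordinate matrices, one per model. Residues are
## numbered 1-based within each chain, matching the C1 G2 C3 G4 ... notation
## used throughout the per-step analyses.

#' Construct a multi-model DNA structure
#'
#' @param atoms data frame with columns `chain`, `resi` (1-based integer
#'   within chain), `resn` (residue code, e.g. `"DG"`, `"8OG"`), `atom`
#'   (atom name), `element` (element symbol).
#' @param xyz list of numeric matrices (one per model, `nrow(atoms)` x 3,
#'   angstrom), or a single matrix for a one-model structure.
#' @param meta free-text provenance.
#' @return An object of class `dna_structure`.
#' @export
dna_structure <- function(atoms, xyz, meta = "") {
  if (is.matrix(xyz)) xyz <- list(xyz)
  stopifnot(is.data.frame(atoms), length(xyz) >= 1)
  need <- c("chain", "resi", "resn", "atom", "element")
  if (!all(need %in% names(atoms)))
    stop("atoms table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  for (m in xyz) {
    if (!is.matrix(m) || nrow(m) != nrow(atoms) || ncol(m) != 3)
      stop("every model must be an nrow(atoms) x 3 coordinate matrix",
           call. = FALSE)
    if (!all(is.finite(m)))
      stop("coordinates must be finite", call. = FALSE)
  }
  if (anyNA(atoms$atom) || any(!nzchar(atoms$atom)))
    stop("atom names must be non-empty", call. = FALSE)
  key <- paste(atoms$chain, atoms$resi, atoms$atom)
  if (anyDuplicated(key))
    stop("atom names must be unique within a residue: ",
         key[anyDuplicated(key)], call. = FALSE)
  structure(list(atoms = atoms, xyz = unname(xyz), meta = meta),
            class = "dna_structure")
}

#' @export
print.dna_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat("<dna_structure> ", n_models(x), " model(s), ",
      nrow(x$atoms), " atoms, chains: ", paste(ch, collapse = ", "), "\n",
      sep = "")
  for (c0 in ch) {
    res <- residues(x, c0)
    cat("  chain ", c0, ": ", paste0(res$resn, collapse = " "), "\n", sep = "")
  }
  if (nzchar(x$meta)) cat("  meta: ", x$meta, "\n", sep = "")
  invisible(x)
}

#' Number of models in a structure
#' @param s a `dna_structure`.
#' @return Integer model count.
#' @export
n_models <- function(s) length(s$xyz)

#' Coordinates of one model
#' @param s a `dna_structure`.
#' @param model model index (1-based).
#' @return Coordinate matrix (atoms x 3) with `chain:resi:atom` row names.
#' @export
model_xyz <- function(s, model = 1) {
  if (model < 1 || model > n_models(s))
    stop("model index out of range: ", model, call. = FALSE)
  m <- s$xyz[[model]]
  rownames(m) <- atom_keys(s)
  m
}

atom_keys <- function(s) paste(s$atoms$chain, s$atoms$resi, s$atoms$atom,
                               sep = ":")

#' Chains of a structure
#' @param s a `dna_structure`.
#' @return Character vector of chain identifiers.
#' @export
chains <- function(s) unique(s$atoms$chain)

#' Residue table of one chain
#' @param s a `dna_structure`.
#' @param chain chain identifier.
#' @return Data frame with `resi` and `resn`, ordered 5' to 3'.
#' @export
residues <- function(s, chain) {
  a <- s$atoms[s$atoms$chain == chain, c("resi", "resn")]
  out <- unique(a)
  out[order(out$resi), , drop = FALSE]
}

## index of a single atom (0 if absent)
atom_index <- function(s, chain, resi, atom) {
  i <- which(s$atoms$chain == chain & s$atoms$resi == resi &
               s$atoms$atom == atom)
  if (length(i) == 0) 0L else i[1]
}

## named coordinates of one residue in one model
residue_xyz <- function(s, chain, resi, model = 1) {
  sel <- s$atoms$chain == chain & s$atoms$resi == resi
  if (!any(sel)) stop("no residue ", chain, ":", resi, call. = FALSE)
  m <- s$xyz[[model]][sel, , drop = FALSE]
  rownames(m) <- s$atoms$atom[sel]
  m
}

## Atom-set conventions used by superposition and RMSD statistics.
.BACKBONE_ATOMS <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'")

#' Select atom indices by convention
#'
#' @param s a `dna_structure`.
#' @param selection `"all"` (every atom, hydrogens included), `"all-heavy"`
#'   (hydrogens excluded), `"backbone"` (sugar-phosphate backbone heavy
#'   atoms: P, OP1, OP2, O5', C5', C4', C3', O3'), or a character vector of
#'   atom names taken as a custom selection.
#' @return Integer vector of row indices into the atom table.
#' @export
select_atoms <- function(s, selection = "all-heavy") {
  if (length(selection) == 1 && selection %in%
      c("all", "all-heavy", "backbone")) {
    switch(selection,
           "all" = seq_len(nrow(s$atoms)),
           "all-heavy" = which(s$atoms$element != "H"),
           "backbone" = which(s$atoms$atom %in% .BACKBONE_ATOMS))
  } else {
    which(s$atoms$atom %in% selection)
  }
}

## Apply a function over models, returning a list.
lapply_models <- function(s, f, ...) lapply(seq_len(n_models(s)), f, ...)
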