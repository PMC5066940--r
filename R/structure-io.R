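## PDB reading/writing, nomenclature normalization, duplex pairing.

#' Read a multi-model PDB structure
#'
#' Parses a (possibly multi-model) PDB file via bio3d and returns a
#' [dna_structure()]. Residues are renumbered 1-based within each chain in
#' order of appearance; MODEL/ENDMDL records delimit coordinate frames and a
#' file without them is a single model. Every model must share the atom
#' topology of the first. Alternate locations other than A are dropped with
#' a warning.
#'
#' @param path file path.
#' @param format only `"pdb"` is supported.
#' @param normalize also run [normalize_nomenclature()]. Default `TRUE`.
#' @return A [dna_structure()].
#' @export
read_structure <- function(path, format = c("pdb"), normalize = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  .check_pdb_records(path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("topology error: models do not share one atom ",
                             "topology (", conditionMessage(e), ")",
                             call. = FALSE))
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " non-A altloc atom(s)")
    at <- at[keep, ]
  }
  ## renumber residues 1-based per chain, preserving order of appearance
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  rkey <- paste(chain, at$resno, at$insert)
  resi <- integer(nrow(at))
  for (c0 in unique(chain)) {
    i <- chain == c0
    resi[i] <- match(rkey[i], unique(rkey[i]))
  }
  elem <- at$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  elem[bad] <- element_of(trimws(at$elety[bad]))
  atoms <- data.frame(chain = chain, resi = resi,
                      resn = trimws(at$resid), atom = trimws(at$elety),
                      element = trimws(elem), stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(pdb$atom))
    stop("topology error: models do not share one atom topology",
         call. = FALSE)
  models <- lapply(seq_len(nrow(xyz)), function(m) {
    mm <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    mm[keep, , drop = FALSE]
  })
  s <- dna_structure(atoms, models, meta = paste0("read from ", path))
  if (normalize) normalize_nomenclature(s) else s
}

## Minimal well-formedness scan so a malformed ATOM record is reported with
## its line number (the wrapped parser's own errors lack one).
.check_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  if (!any(rec)) stop("parse error: no ATOM/HETATM records in ", path,
                      call. = FALSE)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("parse error at line ", i, ": ATOM record shorter than the ",
           "coordinate fields", call. = FALSE)
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords))))
      stop("parse error at line ", i, ": non-numeric coordinate field",
           call. = FALSE)
  }
  invisible(TRUE)
}

## alias tables for nomenclature normalization
.RES_ALIASES <- c(
  DA = "DA", A = "DA", ADE = "DA",
  DC = "DC", C = "DC", CYT = "DC",
  DG = "DG", G = "DG", GUA = "DG",
  DT = "DT", T = "DT", THY = "DT",
  `8OG` = "8OG", OG8 = "8OG", `8OG5` = "8OG", GDO = "8OG")

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "HOH", "WAT")

.ATOM_ALIASES <- c(`O1P` = "OP1", `O2P` = "OP2", `C5M` = "C7",
                   `H2'1` = "H2'", `H2'2` = "H2''", `H5'1` = "H5'",
                   `H5'2` = "H5''", `HO5'` = "H5T", `HO3'` = "H3T")

#' Normalize residue and atom nomenclature
#'
#' Unifies primed/starred sugar atom names (`O3*` and unicode primes become
#' `O3'`), maps residue aliases (G/GUA/DG to DG and so on), recognizes the
#' 8-oxoguanine component 8OG (including DG records that carry an O8 atom),
#' and passes protein/water residues through untouched. A residue that is
#' neither mappable nor ignorable is an error.
#'
#' @param s a [dna_structure()].
#' @param ignore extra residue names to pass through untouched.
#' @return The normalized [dna_structure()].
#' @export
normalize_nomenclature <- function(s, ignore = character()) {
  atoms <- s$atoms
  nm <- atoms$atom
  nm <- gsub("′", "'", nm)
  nm <- chartr("*", "'", nm)
  hit <- nm %in% names(.ATOM_ALIASES)
  nm[hit] <- .ATOM_ALIASES[nm[hit]]
  atoms$atom <- nm

  rn <- toupper(atoms$resn)
  known <- rn %in% names(.RES_ALIASES)
  passthrough <- rn %in% c(.AA3, ignore)
  if (any(!known & !passthrough))
    stop("nomenclature error: unmappable residue(s): ",
         paste(unique(rn[!known & !passthrough]), collapse = ", "),
         call. = FALSE)
  rn[known] <- .RES_ALIASES[rn[known]]
  ## a DG that carries the C8 oxidation (O8 atom) is the 8OG component
  rkey <- paste(atoms$chain, atoms$resi)
  has_o8 <- rkey %in% rkey[atoms$atom == "O8"]
  rn[known & rn == "DG" & has_o8] <- "8OG"
  if (any(rn == "8OG" & !has_o8))
    stop("nomenclature error: 8OG residue without an O8 atom", call. = FALSE)
  atoms$resn <- rn
  atoms$element <- ifelse(atoms$element == "", element_of(atoms$atom),
                          atoms$element)
  dna_structure(atoms, s$xyz, meta = s$meta)
}

#' Write a structure as a PDB file
#'
#' Emits fixed-width PDB 3.3 ATOM/HETATM records; multi-model structures are
#' framed with MODEL/ENDMDL and chains are closed with TER. 8-oxoguanine is
#' written under component code 8OG as HETATM.
#'
#' @param s a [dna_structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  at <- s$atoms
  many <- n_models(s) > 1
  con <- file(path, "w")
  on.exit(close(con))
  serial_fmt <- function(i) sprintf("%5d", i %% 100000)
  for (m in seq_len(n_models(s))) {
    if (many) writeLines(sprintf("MODEL %8d", m), con)
    xyz <- s$xyz[[m]]
    serial <- 0L
    for (c0 in unique(at$chain)) {
      rows <- which(at$chain == c0)
      for (i in rows) {
        serial <- serial + 1L
        rec <- if (at$resn[i] %in% c("DA", "DC", "DG", "DT")) "ATOM  "
               else "HETATM"
        nm <- at$atom[i]
        nmf <- if (nchar(nm) >= 4) substr(paste0(nm, "    "), 1, 4)
               else paste0(" ", substr(paste0(nm, "   "), 1, 3))
        writeLines(sprintf(
          "%s%s %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial_fmt(serial), nmf, at$resn[i], c0, at$resi[i],
          xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0,
          at$element[i]), con)
      }
      serial <- serial + 1L
      last <- rows[length(rows)]
      writeLines(sprintf("TER   %s      %-3s %s%4d", serial_fmt(serial),
                         at$resn[last], c0, at$resi[last]), con)
    }
    if (many) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## legal Watson-Crick pairings (8-oxoguanine keeps the guanine edge)
.WC_OK <- matrix(c("DA", "DT", "DT", "DA", "DG", "DC", "DC", "DG",
                   "8OG", "DC", "DC", "8OG"), ncol = 2, byrow = TRUE)

pair_ok <- function(a, b) any(.WC_OK[, 1] == a & .WC_OK[, 2] == b)

#' Antiparallel duplex pairing map
#'
#' Pairs residue i of the first strand with residue N+1-i of the second and
#' checks complementarity under A:T, G:C, 8OG:C. Terminal pairs are flagged
#' (Watson-Crick restraints are emitted for non-terminal pairs only).
#'
#' @param s optional [dna_structure()] whose chains must match the
#'   sequences.
#' @param seq_a,seq_b strand sequences, both 5' to 3' (A/C/G/T/X);
#'   `seq_b` defaults to `seq_a` (a self-complementary duplex).
#' @param chain_a,chain_b chain identifiers in `s`. Defaults "A", "B".
#' @return A data frame of class `duplex_map` with columns `pair`
#'   (position along strand A), `res_a`, `res_b` (paired residue index on
#'   strand B, 5' to 3' numbering), `code_a`, `code_b`, `terminal`.
#' @export
pair_duplex <- function(s = NULL, seq_a, seq_b = seq_a, chain_a = "A",
                        chain_b = "B") {
  map_codes <- function(x) {
    if (length(x) == 1 && is.character(x)) parse_duplex_sequence(x)$a else x
  }
  a <- map_codes(seq_a)
  b <- map_codes(seq_b)
  if (length(a) != length(b))
    stop("pairing error: strands differ in length", call. = FALSE)
  n <- length(a)
  partner <- b[n + 1 - seq_len(n)]
  bad <- which(!mapply(pair_ok, a, partner))
  if (length(bad) > 0)
    stop("pairing error: non-complementary position(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(s)) {
    for (spec in list(list(chain_a, a), list(chain_b, b))) {
      have <- residues(s, spec[[1]])$resn
      if (!identical(have, spec[[2]]))
        stop("pairing error: chain ", spec[[1]],
             " does not match the given sequence", call. = FALSE)
    }
  }
  out <- data.frame(pair = seq_len(n), res_a = seq_len(n),
                    res_b = n + 1 - seq_len(n),
                    code_a = a, code_b = partner,
                    terminal = seq_len(n) %in% c(1L, n),
                    stringsAsFactors = FALSE)
  attr(out, "chain_a") <- chain_a
  attr(out, "chain_b") <- chain_b
  class(out) <- c("duplex_map", "data.frame")
  out
}
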