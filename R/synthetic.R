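## Ground-truth-known duplex generators.
##
## Two builders cover complementary needs: `build_helix()` places whole
## base-pair templates on an ideal screw axis, so per-step twist and rise are
## known exactly; `build_torsion_exact()` grows the sugar-phosphate chain by
## internal coordinates, so requested backbone torsions (in particular
## epsilon and zeta) are realized exactly. A single helical placement cannot
## guarantee both sets of parameters at once, which is why each recovery test
## uses the builder that owns its ground truth.

#' Parse a duplex sequence
#'
#' Accepts the one-letter alphabet A, C, G, T plus X for 8-oxoguanine and
#' returns residue codes for both strands of the antiparallel duplex
#' (pairing rule A:T, G:C, 8OG:C). When the oligo anneals with itself under
#' that rule - as a lesion-bearing derivative of a palindrome does, because
#' X pairs the C that faced the original G - the duplex is formed of two
#' copies of the same strand, so the lesion appears once per strand (the
#' physical situation for a self-complementary sample). Otherwise the second
#' strand is the reverse complement.
#'
#' @param sequence character scalar, 5' to 3' of the reference strand.
#' @return List with `a` and `b`: residue-code vectors for the two strands,
#'   each 5' to 3'.
#' @export
parse_duplex_sequence <- function(sequence) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  map <- c(A = "DA", C = "DC", G = "DG", T = "DT", X = "8OG")
  if (!all(letters1 %in% names(map)))
    stop("invalid sequence symbol(s): ",
         paste(unique(setdiff(letters1, names(map))), collapse = ", "),
         call. = FALSE)
  a <- unname(map[letters1])
  n <- length(a)
  self_anneal <- all(mapply(pair_ok, a, a[n + 1 - seq_len(n)]))
  b <- if (self_anneal) a else rev(unname(.COMPLEMENT[a]))
  list(a = a, b = b)
}

## Assemble the atom table + coordinates for a list of per-residue named
## coordinate matrices, dropping the 5'-phosphate of each strand terminus.
.assemble_structure <- function(res_a, res_b, codes_a, codes_b, meta) {
  strip5 <- function(m) m[!rownames(m) %in% c("P", "OP1", "OP2"), ,
                          drop = FALSE]
  res_a[[1]] <- strip5(res_a[[1]])
  res_b[[1]] <- strip5(res_b[[1]])
  rows <- list()
  xyz <- list()
  emit <- function(chain, i, code, m) {
    rows[[length(rows) + 1]] <<- data.frame(
      chain = chain, resi = i, resn = code, atom = rownames(m),
      element = element_of(rownames(m)), stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1]] <<- unname(m)
  }
  for (i in seq_along(res_a)) emit("A", i, codes_a[i], res_a[[i]])
  for (j in seq_along(res_b)) emit("B", j, codes_b[j], res_b[[j]])
  dna_structure(do.call(rbind, rows), do.call(rbind, xyz), meta = meta)
}

#' Build an ideal duplex helix with known twist and rise
#'
#' Places idealized base-pair templates along a straight axis. Twist and rise
#' can be set per step, so a local unwinding (or a BII-coupled twist dip) can
#' be injected at chosen steps; the returned ground truth equals the
#' placement parameters exactly.
#'
#' @param sequence duplex sequence (A/C/G/T/X, X = 8-oxoguanine), 5' to 3'.
#' @param twist helical twist per step in degrees; scalar or vector of
#'   length `nchar(sequence) - 1`. Default 36.
#' @param rise rise per step in angstrom; scalar or vector as above.
#'   Default 3.38.
#' @return List with `structure` (a one-model [dna_structure()]) and
#'   `params`: data frame of the ground-truth per-step `twist` and `rise`.
#' @export
build_helix <- function(sequence, twist = 36, rise = 3.38) {
  seqs <- parse_duplex_sequence(sequence)
  n <- length(seqs$a)
  if (n < 2) stop("need at least 2 base pairs", call. = FALSE)
  twist <- rep_len(twist, n - 1)
  rise <- rep_len(rise, n - 1)
  theta <- cumsum(c(0, twist))
  z <- cumsum(c(0, rise))
  flip <- rot_x(180)
  res_a <- vector("list", n)
  res_b <- vector("list", n)
  for (i in seq_len(n)) {
    R <- rot_z(theta[i])
    tmpl_a <- nt_template(seqs$a[i])
    res_a[[i]] <- sweep(tmpl_a %*% t(R), 2, c(0, 0, z[i]), "+")
    jb <- n + 1 - i                       # chain B residue paired with A:i
    tmpl_b <- nt_template(seqs$b[jb])
    res_b[[jb]] <- sweep(tmpl_b %*% t(flip) %*% t(R), 2, c(0, 0, z[i]), "+")
  }
  s <- .assemble_structure(res_a, res_b, seqs$a, seqs$b,
                           meta = paste0("ideal helix ", sequence))
  list(structure = s,
       params = data.frame(step = seq_len(n - 1), twist = twist, rise = rise))
}

## Backbone internal-coordinate defaults for the torsion-exact builder,
## matched to the torsions the ideal helix realizes so that the two builders
## produce comparable B-form baselines.
.CHAIN_IDEAL <- list(
  alpha = 307.913, beta = 165.675, gamma = 52.253, delta = 122.721,
  eps = 188.886, zeta = 253.887,
  bonds = c(`C3'-O3'` = 1.42, `O3'-P` = 1.587, `P-O5'` = 1.60,
            `O5'-C5'` = 1.44, `C5'-C4'` = 1.51, `C4'-C3'` = 1.52),
  angles = c(`C4'-C3'-O3'` = 109.412, `C3'-O3'-P` = 118.732,
             `O3'-P-O5'` = 103.822, `P-O5'-C5'` = 122.714,
             `O5'-C5'-C4'` = 110.2, `C5'-C4'-C3'` = 114.7))

#' Build a duplex with exact backbone torsions
#'
#' Grows the reference strand 5' to 3' by internal-coordinate chaining with
#' standard bond lengths and angles, so the requested epsilon and zeta (and
#' the other backbone torsions) are realized exactly at every linkage. The
#' complementary strand is placed by Watson-Crick pairing geometry from the
#' fitted base frames.
#'
#' @param sequence duplex sequence (A/C/G/T/X), 5' to 3'.
#' @param eps,zeta per-nucleotide epsilon/zeta targets in degrees, scalar or
#'   vector of length `nchar(sequence)` (the value at position k governs the
#'   linkage 3' of nucleotide k, i.e. step k; the last entry is unused).
#'   Defaults are the BI baseline (eps about 189, zeta about 254).
#' @param bii_at integer positions whose 3' linkage is switched to a
#'   canonical BII geometry (eps 270, zeta 180); convenience overlay on
#'   `eps`/`zeta`.
#' @return A one-model [dna_structure()]; the requested torsions are the
#'   ground truth.
#' @export
build_torsion_exact <- function(sequence, eps = NULL, zeta = NULL,
                                bii_at = NULL) {
  seqs <- parse_duplex_sequence(sequence)
  n <- length(seqs$a)
  if (n < 2) stop("need at least 2 base pairs", call. = FALSE)
  p <- .CHAIN_IDEAL
  eps <- if (is.null(eps)) rep(p$eps, n) else rep_len(eps, n)
  zeta <- if (is.null(zeta)) rep(p$zeta, n) else rep_len(zeta, n)
  if (!is.null(bii_at)) {
    if (any(bii_at < 1 | bii_at >= n))
      stop("bii_at positions must be in 1..", n - 1, call. = FALSE)
    eps[bii_at] <- 270
    zeta[bii_at] <- 180
  }
  if (any(eps < 0 | eps >= 360) || any(zeta < 0 | zeta >= 360))
    stop("eps/zeta targets must lie in [0, 360)", call. = FALSE)
  bl <- p$bonds
  ba <- p$angles

  ## backbone chain for strand A: per residue P, O5', C5', C4', C3', O3'
  bb <- vector("list", n)
  ## seed residue 1 (no 5'-phosphate)
  o5 <- c(0, 0, 0)
  c5 <- c(bl["O5'-C5'"], 0, 0)
  c4 <- place_atom(c(0, 1, 0), o5, c5, bl["C5'-C4'"], ba["O5'-C5'-C4'"], 0)
  c3 <- place_atom(o5, c5, c4, bl["C4'-C3'"], ba["C5'-C4'-C3'"], p$gamma)
  o3 <- place_atom(c5, c4, c3, bl["C3'-O3'"], ba["C4'-C3'-O3'"], p$delta)
  bb[[1]] <- rbind(`O5'` = o5, `C5'` = c5, `C4'` = c4, `C3'` = c3,
                   `O3'` = o3)
  for (i in 2:n) {
    prev <- bb[[i - 1]]
    pp <- place_atom(prev["C4'", ], prev["C3'", ], prev["O3'", ],
                     bl["O3'-P"], ba["C3'-O3'-P"], eps[i - 1])
    o5 <- place_atom(prev["C3'", ], prev["O3'", ], pp,
                     bl["P-O5'"], ba["O3'-P-O5'"], zeta[i - 1])
    c5 <- place_atom(prev["O3'", ], pp, o5,
                     bl["O5'-C5'"], ba["P-O5'-C5'"], p$alpha)
    c4 <- place_atom(pp, o5, c5, bl["C5'-C4'"], ba["O5'-C5'-C4'"], p$beta)
    c3 <- place_atom(o5, c5, c4, bl["C4'-C3'"], ba["C5'-C4'-C3'"], p$gamma)
    o3 <- place_atom(c5, c4, c3, bl["C3'-O3'"], ba["C4'-C3'-O3'"], p$delta)
    op1 <- place_atom(c5, o5, pp, 1.49, 108, 60)
    op2 <- place_atom(c5, o5, pp, 1.49, 108, 180)
    bb[[i]] <- rbind(P = pp, OP1 = op1, OP2 = op2, `O5'` = o5, `C5'` = c5,
                     `C4'` = c4, `C3'` = c3, `O3'` = o3)
  }

  ## dress each backbone residue with the sugar/base template, then place the
  ## complementary strand from the fitted base frames
  flip <- rot_x(180)
  res_a <- vector("list", n)
  res_b <- vector("list", n)
  for (i in seq_len(n)) {
    tmpl <- nt_template(seqs$a[i])
    triad <- c("C5'", "C4'", "C3'")
    fit <- kabsch(tmpl[triad, , drop = FALSE], bb[[i]][triad, , drop = FALSE])
    keep <- setdiff(rownames(tmpl), rownames(bb[[i]]))
    dressed <- sweep(tmpl[keep, , drop = FALSE] %*% t(fit$R), 2, fit$t, "+")
    res_a[[i]] <- rbind(bb[[i]], dressed)

    fr <- base_frame_xyz(res_a[[i]], seqs$a[i])
    jb <- n + 1 - i
    tmpl_b <- nt_template(seqs$b[jb])
    res_b[[jb]] <- sweep(tmpl_b %*% t(flip) %*% t(fr$axes), 2, fr$origin, "+")
  }
  .assemble_structure(res_a, res_b, seqs$a, seqs$b,
                      meta = paste0("torsion-exact duplex ", sequence))
}

#' Jittered coordinate ensemble
#'
#' Expands a structure into `n` models by adding independent Gaussian
#' displacements (sd `sigma` angstrom) to every coordinate of the parent
#' model. Deterministic under `seed`; the caller's RNG state is preserved.
#'
#' @param s a [dna_structure()]; model `parent` is the jitter parent.
#' @param sigma per-coordinate displacement sd, angstrom (`sigma >= 0`).
#' @param n number of models to generate.
#' @param seed integer seed.
#' @param parent index of the parent model. Default 1.
#' @return A [dna_structure()] with `n` models.
#' @export
make_ensemble <- function(s, sigma, n, seed = 1, parent = 1) {
  stopifnot(sigma >= 0, n >= 1)
  base <- s$xyz[[parent]]
  xyz <- with_local_seed(seed, {
    lapply(seq_len(n), function(i)
      base + matrix(stats::rnorm(length(base), 0, sigma), nrow(base), 3))
  })
  dna_structure(s$atoms, xyz,
                meta = paste0(s$meta, " | ensemble n=", n, " sigma=", sigma))
}

#' Combine models from topology-identical structures
#'
#' @param ... `dna_structure` objects sharing one atom table.
#' @return A [dna_structure()] whose models are the concatenation of the
#'   inputs' models.
#' @export
bind_models <- function(...) {
  ss <- list(...)
  a0 <- ss[[1]]$atoms
  for (s in ss[-1]) {
    if (!identical(a0[c("chain", "resi", "atom")],
                   s$atoms[c("chain", "resi", "atom")]))
      stop("structures do not share an atom topology", call. = FALSE)
  }
  dna_structure(a0, do.call(c, lapply(ss, `[[`, "xyz")),
                meta = ss[[1]]$meta)
}

#' Synthesize a NOESY peak list from a structure
#'
#' Generates isolated-spin-pair peak volumes as a noisy r^-6 transform of
#' the true interproton distances of one strand: for every proton pair
#' closer than `max_distance`, one record per mixing time with volume
#' `c_mt * r^-6 * exp(noise * z)`, `z ~ N(0,1)`. Cytosine H5-H6 pairs (the
#' calibration standard) always fall inside the horizon.
#'
#' @param s a [dna_structure()] with hydrogens.
#' @param model model index used for the ground-truth distances.
#' @param chain chain whose intra-strand peaks are generated. Default "A".
#' @param max_distance NOE horizon in angstrom. Default 5.
#' @param noise multiplicative log-normal noise fraction. Default 0.
#' @param seed integer seed.
#' @param mixing_times NOESY mixing times in ms. Default `c(70, 140, 200)`.
#' @return Data frame with columns `peak_id`, `res_i`, `atom_i`, `res_j`,
#'   `atom_j`, `volume`, `mixing_time_ms`.
#' @export
synth_peaklist <- function(s, model = 1, chain = "A", max_distance = 5,
                           noise = 0, seed = 1,
                           mixing_times = c(70, 140, 200)) {
  sel <- which(s$atoms$chain == chain & s$atoms$element == "H")
  if (length(sel) == 0)
    stop("structure has no hydrogens on chain ", chain, call. = FALSE)
  xyz <- s$xyz[[model]][sel, , drop = FALSE]
  at <- s$atoms[sel, ]
  d <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(d) & d <= max_distance, arr.ind = TRUE)
  if (nrow(pairs) == 0) stop("no proton pairs within the horizon",
                             call. = FALSE)
  r <- d[pairs]
  out <- with_local_seed(seed, {
    recs <- lapply(mixing_times, function(mt) {
      vol <- (mt / max(mixing_times)) * r^-6 *
        exp(noise * stats::rnorm(length(r)))
      data.frame(res_i = at$resi[pairs[, 1]], atom_i = at$atom[pairs[, 1]],
                 res_j = at$resi[pairs[, 2]], atom_j = at$atom[pairs[, 2]],
                 volume = vol, mixing_time_ms = mt,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  })
  out <- cbind(peak_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
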