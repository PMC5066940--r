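## Backbone, glycosidic and sugar torsions; the epsilon-zeta statistic;
## BI/BII substate classification; sugar pseudorotation.
##
## Conventions: named backbone torsions are reported in [0, 360); epsilon
## minus zeta is differenced with wrapping into (-180, 180], which puts
## canonical BI near -80 and canonical BII near +90, so a single threshold
## separates the substates. Step k spans nucleotides k and k+1: the
## phosphodiester linkage 3' of nucleotide k carries the step's epsilon and
## zeta.

#' BI/BII boundary (degrees)
#'
#' A step is BII when epsilon - zeta exceeds this threshold, BI otherwise
#' (the boundary value itself classifies as BI).
#' @export
BII_THRESHOLD <- 20

.TORSION_DEFS <- function(resi) list(
  alpha = list(c("O3'", resi - 1), c("P", resi), c("O5'", resi),
               c("C5'", resi)),
  beta = list(c("P", resi), c("O5'", resi), c("C5'", resi), c("C4'", resi)),
  gamma = list(c("O5'", resi), c("C5'", resi), c("C4'", resi),
               c("C3'", resi)),
  delta = list(c("C5'", resi), c("C4'", resi), c("C3'", resi),
               c("O3'", resi)),
  epsilon = list(c("C4'", resi), c("C3'", resi), c("O3'", resi),
                 c("P", resi + 1)),
  zeta = list(c("C3'", resi), c("O3'", resi), c("P", resi + 1),
              c("O5'", resi + 1)))

.NU_DEFS <- list(
  nu0 = c("C4'", "O4'", "C1'", "C2'"),
  nu1 = c("O4'", "C1'", "C2'", "C3'"),
  nu2 = c("C1'", "C2'", "C3'", "C4'"),
  nu3 = c("C2'", "C3'", "C4'", "O4'"),
  nu4 = c("C3'", "C4'", "O4'", "C1'"))

#' Backbone, glycosidic and sugar torsions of one nucleotide
#'
#' Computes alpha, beta, gamma, delta, epsilon, zeta and chi in [0, 360) and
#' the sugar torsions nu0-nu4 in (-180, 180]. Angles whose atoms do not
#' exist (epsilon/zeta at the 3' strand terminus, alpha/beta at the 5'
#' terminus) are returned as `NA` with the availability flag `FALSE`; a
#' missing backbone atom that should exist on an internal residue is an
#' error naming the residue and atom.
#'
#' @param s a [dna_structure()].
#' @param model,chain,resi residue address.
#' @return An object of class `torsion_set`: list with `chain`, `resi`,
#'   `resn`, `angles` (named vector), `nu` (named vector), `available`
#'   (named logical).
#' @export
backbone_torsions <- function(s, model = 1, chain = "A", resi) {
  res <- residues(s, chain)
  if (!resi %in% res$resi) stop("no residue ", chain, ":", resi,
                                call. = FALSE)
  code <- res$resn[match(resi, res$resi)]
  first <- min(res$resi)
  last <- max(res$resi)
  xyz <- s$xyz[[model]]

  getpos <- function(atom, at_resi) {
    if (at_resi < first || at_resi > last) return(NULL)
    i <- atom_index(s, chain, at_resi, atom)
    if (i == 0) {
      ## backbone atoms are mandatory except the 5'-terminal phosphate group
      terminal_p <- atom %in% c("P", "OP1", "OP2") && at_resi == first
      if (atom %in% .BACKBONE_ATOMS && !terminal_p)
        stop("missing atom ", atom, " in residue ", chain, ":", at_resi,
             call. = FALSE)
      return(NULL)
    }
    xyz[i, ]
  }

  defs <- .TORSION_DEFS(resi)
  purine <- code %in% c("DA", "DG", "8OG")
  defs$chi <- if (purine) {
    list(c("O4'", resi), c("C1'", resi), c("N9", resi), c("C4", resi))
  } else {
    list(c("O4'", resi), c("C1'", resi), c("N1", resi), c("C2", resi))
  }
  angles <- vapply(defs, function(d) {
    pts <- lapply(d, function(ar) getpos(ar[1], as.integer(ar[2])))
    if (any(vapply(pts, is.null, logical(1)))) return(NA_real_)
    dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]], range = "unsigned")
  }, numeric(1))

  nu <- vapply(.NU_DEFS, function(d) {
    pts <- lapply(d, function(a) getpos(a, resi))
    if (any(vapply(pts, is.null, logical(1)))) return(NA_real_)
    dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]], range = "signed")
  }, numeric(1))

  structure(list(chain = chain, resi = resi, resn = code, model = model,
                 angles = angles, nu = nu,
                 available = c(!is.na(angles), !is.na(nu))),
            class = "torsion_set")
}

#' @export
print.torsion_set <- function(x, ...) {
  cat("<torsion_set> ", x$chain, ":", x$resi, " (", x$resn, "), model ",
      x$model, "\n", sep = "")
  print(round(x$angles, 1))
  print(round(x$nu, 1))
  invisible(x)
}

#' Classify a dinucleotide step as BI or BII
#'
#' Applies the epsilon-zeta rule: the step 3' of the nucleotide is BII when
#' wrap(epsilon - zeta) exceeds 20 degrees and BI otherwise (including at
#' exactly 20, which the defining inequalities leave unassigned).
#'
#' @param ts a `torsion_set` from [backbone_torsions()], or a list/vector
#'   with elements `epsilon` and `zeta` in degrees.
#' @return List with `step` (the nucleotide's index, `NA` when unknown),
#'   `eps_minus_zeta` in (-180, 180], and `state` (`"BI"`, `"BII"`, or `NA`
#'   when epsilon or zeta is unavailable).
#' @export
classify_step <- function(ts) {
  if (inherits(ts, "torsion_set")) {
    eps <- ts$angles[["epsilon"]]
    zeta <- ts$angles[["zeta"]]
    step <- ts$resi
  } else {
    eps <- ts[["epsilon"]]
    zeta <- ts[["zeta"]]
    step <- NA_integer_
  }
  if (is.na(eps) || is.na(zeta))
    return(list(step = step, eps_minus_zeta = NA_real_,
                state = NA_character_))
  emz <- wrap180(eps - zeta)
  list(step = step, eps_minus_zeta = emz,
       state = if (emz > BII_THRESHOLD) "BII" else "BI")
}

#' Per-step epsilon-zeta table for a chain
#'
#' @param s a [dna_structure()].
#' @param chain chain identifier.
#' @param model model index, or `NULL` for all models.
#' @return Data frame with `model`, `chain`, `step`, `epsilon`, `zeta`,
#'   `eps_minus_zeta`, `state` for every classifiable step (the machine
#'   twin of a per-step BI/BII profile).
#' @export
step_calls <- function(s, chain = "A", model = NULL) {
  res <- residues(s, chain)
  models <- if (is.null(model)) seq_len(n_models(s)) else model
  rows <- list()
  for (m in models) {
    for (k in res$resi[-length(res$resi)]) {
      ts <- backbone_torsions(s, m, chain, k)
      cl <- classify_step(ts)
      rows[[length(rows) + 1]] <- data.frame(
        model = m, chain = chain, step = k,
        epsilon = unname(ts$angles["epsilon"]),
        zeta = unname(ts$angles["zeta"]),
        eps_minus_zeta = cl$eps_minus_zeta,
        state = if (is.na(cl$state)) NA_character_ else cl$state,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' BII frequency per step across an ensemble
#'
#' @param s a [dna_structure()].
#' @param chain chain identifier.
#' @param step step index, or `NULL` for the whole per-step profile.
#' @return For one step, the fraction of classifiable models in BII (`NA`
#'   with a zero count when none classify); otherwise a data frame with
#'   `step`, `n_models`, `bii_frequency`.
#' @export
bii_frequency <- function(s, chain = "A", step = NULL) {
  calls <- step_calls(s, chain)
  agg <- lapply(split(calls, calls$step), function(d) {
    ok <- !is.na(d$state)
    data.frame(step = d$step[1], n_models = sum(ok),
               bii_frequency = if (any(ok)) mean(d$state[ok] == "BII")
                               else NA_real_)
  })
  prof <- do.call(rbind, agg)
  rownames(prof) <- NULL
  if (is.null(step)) return(prof)
  i <- match(step, prof$step)
  if (is.na(i)) stop("no classifiable step ", step, call. = FALSE)
  prof$bii_frequency[i]
}

#' Sugar pseudorotation phase and amplitude
#'
#' Computes the pseudorotation phase P and puckering amplitude tau_m from
#' the five sugar ring torsions using
#' `tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin 72))` and
#' `tau_m = nu2 / cos P`.
#'
#' @param nu numeric vector of the five ring torsions nu0-nu4 (degrees).
#' @return List with `P` in [0, 360), `tau_m` (>= 0), the conformer `label`
#'   (e.g. `"C2'-endo"`), and `ambiguous` (`TRUE` when nu2 is about 0 and
#'   phase is taken from the numerator alone).
#' @export
pseudorotation <- function(nu) {
  stopifnot(length(nu) == 5)
  if (anyNA(nu)) stop("all five sugar torsions are required", call. = FALSE)
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  den <- 2 * nu[3] * (sin(deg2rad(36)) + sin(deg2rad(72)))
  ambiguous <- abs(den) < 1e-8
  P <- wrap360(rad2deg(atan2(num, den)))
  tau_m <- if (ambiguous) abs(num) / (2 * (sin(deg2rad(36)) +
                                             sin(deg2rad(72))))
           else nu[3] / cos(deg2rad(P))
  list(P = P, tau_m = tau_m, label = pucker_label(P), ambiguous = ambiguous)
}

.PUCKER_LABELS <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo",
                    "C2'-endo", "C3'-exo", "C4'-endo", "O4'-exo",
                    "C1'-endo", "C2'-exo")

pucker_label <- function(P) .PUCKER_LABELS[floor(wrap360(P) / 36) + 1]

#' Sugar pucker of a residue
#'
#' @param s a [dna_structure()].
#' @param model,chain,resi residue address.
#' @return See [pseudorotation()].
#' @export
sugar_pucker <- function(s, model = 1, chain = "A", resi) {
  ts <- backbone_torsions(s, model, chain, resi)
  pseudorotation(unname(ts$nu))
}
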