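## NOESY restraint compilation and violation scoring.
##
## The compilation pipeline mirrors standard solution-NMR practice for
## nucleic-acid duplexes: volume-to-distance calibration within each
## mixing-time set against the cytosine H5-H6 distance, merging across
## mixing times ("averaged" when reliably present in every set, otherwise
## the single most reliable peak), grouping by length with group-specific
## no-penalty tolerances, symmetry duplication onto the second strand of a
## self-complementary duplex, plus canonical Watson-Crick distance
## restraints and BI/BII backbone dihedral restraints.

#' Default per-group bound tolerances (angstrom)
#'
#' Package defaults, deliberately config-overridable: 0.4 for short
#' (< 3 A), 0.7 for medium (3-5 A), 1.0 for long (> 5 A) restraints, applied
#' on both sides; methyl-containing restraints additionally widen the upper
#' bound by the 1.0 A pseudoatom correction.
#' @export
restraint_tolerances <- function(short = c(0.4, 0.4), medium = c(0.7, 0.7),
                                 long = c(1.0, 1.0), methyl_extra = 1.0) {
  list(short = short, medium = medium, long = long,
       methyl_extra = methyl_extra)
}

.pair_key <- function(res_i, atom_i, res_j, atom_j) {
  a <- paste(res_i, atom_i, sep = ":")
  b <- paste(res_j, atom_j, sep = ":")
  ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

#' Volume-to-distance calibration of NOESY peaks
#'
#' Applies the isolated-spin-pair r^-6 law within each mixing-time set
#' independently: `r_i = r_ref * (V_ref / V_i)^(1/6)`, with the cytosine
#' H5-H6 distance as the calibration standard.
#'
#' @param peaks peak-list data frame (see [synth_peaklist()] /
#'   [read_peaklist()]).
#' @param ref reference proton pair: list or vector with `res_i`, `atom_i`,
#'   `res_j`, `atom_j`.
#' @param r_ref reference distance in angstrom. Default 2.45 (the fixed
#'   cytosine H5-H6 covalent geometry; config-overridable).
#' @return The peak list with a `distance` column appended.
#' @export
calibrate <- function(peaks, ref, r_ref = 2.45) {
  stopifnot(all(peaks$volume > 0), r_ref > 0)
  refkey <- .pair_key(ref$res_i, ref$atom_i, ref$res_j, ref$atom_j)
  key <- .pair_key(peaks$res_i, peaks$atom_i, peaks$res_j, peaks$atom_j)
  out <- peaks
  out$distance <- NA_real_
  for (mt in unique(peaks$mixing_time_ms)) {
    in_set <- peaks$mixing_time_ms == mt
    vref <- peaks$volume[in_set & key == refkey]
    if (length(vref) == 0)
      stop("calibration error: reference peak absent from the ", mt,
           " ms mixing-time set", call. = FALSE)
    vref <- mean(vref)
    out$distance[in_set] <- r_ref * (vref / peaks$volume[in_set])^(1 / 6)
  }
  out
}

#' Merge calibrated distances across mixing-time sets
#'
#' A proton pair reliably present in every mixing-time set becomes one
#' "averaged" restraint (arithmetic mean of its per-set distances); any
#' other pair is taken from its single most reliable cross-peak,
#' operationalized as the highest-volume record ("non-averaged").
#'
#' @param calibrated output of [calibrate()].
#' @return Data frame with one row per unique proton pair: `res_i`,
#'   `atom_i`, `res_j`, `atom_j`, `distance`, `provenance`.
#' @export
merge_mixing_times <- function(calibrated) {
  n_sets <- length(unique(calibrated$mixing_time_ms))
  key <- .pair_key(calibrated$res_i, calibrated$atom_i, calibrated$res_j,
                   calibrated$atom_j)
  groups <- split(calibrated, key)
  rows <- lapply(groups, function(d) {
    complete <- length(unique(d$mixing_time_ms)) == n_sets
    out <- d[1, c("res_i", "atom_i", "res_j", "atom_j")]
    if (complete) {
      out$distance <- mean(d$distance)
      out$provenance <- "averaged"
    } else {
      out$distance <- d$distance[which.max(d$volume)]
      out$provenance <- "non-averaged"
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

group_by_length <- function(distance) {
  ifelse(distance < 3.0, "short", ifelse(distance <= 5.0, "medium", "long"))
}

#' Length group and bounds for one restraint distance
#'
#' Groups by the < 3 / 3-5 / > 5 angstrom rule; a methyl-containing
#' restraint is re-labelled `"methyl"` and its upper bound widened by the
#' pseudoatom correction.
#'
#' @param distance target distance, angstrom (> 0).
#' @param involves_methyl logical.
#' @param tolerances see [restraint_tolerances()].
#' @return List with `target`, `lower`, `upper`, `group`.
#' @export
assign_bounds <- function(distance, involves_methyl = FALSE,
                          tolerances = restraint_tolerances()) {
  if (!is.finite(distance) || distance <= 0)
    stop("input error: non-positive restraint distance", call. = FALSE)
  g <- group_by_length(distance)
  tol <- tolerances[[g]]
  lower <- max(0, distance - tol[1])
  upper <- distance + tol[2]
  if (involves_methyl) {
    g <- "methyl"
    upper <- upper + tolerances$methyl_extra
  }
  list(target = distance, lower = lower, upper = upper, group = g)
}

.METHYL_H <- c("H71", "H72", "H73")

#' Compile a peak list into distance restraints
#'
#' Runs calibration, mixing-time merging and bound assignment; methyl
#' protons (thymine H71/H72/H73) flag a restraint as methyl-containing. Peak
#' lists carry no chain, so compiled restraints live on `chain` (default
#' "A") until [duplicate_symmetry()] maps them onto the partner strand.
#'
#' @param peaks peak-list data frame.
#' @param ref reference proton pair for [calibrate()]; `NULL` picks the
#'   shortest-distance cytosine H5-H6 peak present.
#' @param r_ref reference distance, angstrom.
#' @param tolerances see [restraint_tolerances()].
#' @param chain chain label for the compiled restraints.
#' @return Restraint data frame: `chain_i`, `res_i`, `atom_i`, `chain_j`,
#'   `res_j`, `atom_j`, `target`, `lower`, `upper`, `group`, `provenance`.
#' @export
compile_restraints <- function(peaks, ref = NULL, r_ref = 2.45,
                               tolerances = restraint_tolerances(),
                               chain = "A") {
  if (is.null(ref)) {
    cand <- peaks[(peaks$atom_i == "H5" & peaks$atom_j == "H6" |
                     peaks$atom_i == "H6" & peaks$atom_j == "H5") &
                    peaks$res_i == peaks$res_j, ]
    if (nrow(cand) == 0)
      stop("calibration error: no cytosine H5-H6 reference peak found",
           call. = FALSE)
    ref <- as.list(cand[1, c("res_i", "atom_i", "res_j", "atom_j")])
  }
  merged <- merge_mixing_times(calibrate(peaks, ref, r_ref))
  rows <- lapply(seq_len(nrow(merged)), function(i) {
    m <- merged[i, ]
    methyl <- m$atom_i %in% .METHYL_H || m$atom_j %in% .METHYL_H
    b <- assign_bounds(m$distance, methyl, tolerances)
    data.frame(chain_i = chain, res_i = m$res_i, atom_i = m$atom_i,
               chain_j = chain, res_j = m$res_j, atom_j = m$atom_j,
               target = b$target, lower = b$lower, upper = b$upper,
               group = b$group, provenance = m$provenance,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Restraint ledger
#'
#' Counts compiled restraints by category. Methyl-containing restraints are
#' one category; all others split into averaged and non-averaged, so
#' `averaged + non_averaged + methyl = total` always holds.
#'
#' @param restraints compiled restraint data frame.
#' @return List with `averaged`, `non_averaged`, `methyl`, `total`.
#' @export
restraint_ledger <- function(restraints) {
  methyl <- restraints$group == "methyl"
  list(averaged = sum(!methyl & restraints$provenance == "averaged"),
       non_averaged = sum(!methyl & restraints$provenance == "non-averaged"),
       methyl = sum(methyl),
       total = nrow(restraints))
}

#' Duplicate restraints onto the symmetry-related strand
#'
#' For a self-complementary duplex, every restraint measured on one strand
#' holds equally at the sequence-equivalent position of the other: atom keys
#' are mapped through the palindromic dyad (chain A residue i to chain B
#' residue i, which sits at pair position N+1-i). Duplicates carry
#' provenance `"symmetry-copy"`; a restraint that maps onto itself is
#' emitted once and flagged.
#'
#' @param restraints compiled restraint data frame.
#' @param map duplex map from [pair_duplex()]; the duplex must be
#'   self-complementary.
#' @return The restraints plus their symmetry copies, with a
#'   `self_symmetric` column.
#' @export
duplicate_symmetry <- function(restraints, map) {
  if (!identical(map$code_a, rev(map$code_b)) &&
      !identical(unname(map$code_a),
                 unname(map$code_b[order(map$res_b)])))
    stop("duplication error: duplex is not self-complementary",
         call. = FALSE)
  n <- nrow(map)
  ca <- attr(map, "chain_a")
  cb <- attr(map, "chain_b")
  other <- function(ch) ifelse(ch == ca, cb, ca)
  bad <- !(restraints$res_i %in% seq_len(n)) |
    !(restraints$res_j %in% seq_len(n))
  if (any(bad))
    stop("duplication error: restraint references unpaired residue(s): ",
         paste(unique(c(restraints$res_i[bad], restraints$res_j[bad])),
               collapse = ", "), call. = FALSE)
  copy <- restraints
  copy$chain_i <- other(restraints$chain_i)
  copy$chain_j <- other(restraints$chain_j)
  copy$provenance <- "symmetry-copy"
  ukey <- function(r) {
    a <- paste(r$chain_i, r$res_i, r$atom_i, sep = ":")
    b <- paste(r$chain_j, r$res_j, r$atom_j, sep = ":")
    ifelse(a < b, paste(a, b), paste(b, a))
  }
  selfsym <- ukey(copy) == ukey(restraints)
  orig <- restraints
  orig$self_symmetric <- selfsym
  copies <- copy[!selfsym, , drop = FALSE]
  copies$self_symmetric <- rep(FALSE, nrow(copies))
  out <- rbind(orig, copies)
  rownames(out) <- NULL
  out
}

## canonical Watson-Crick heavy-atom bonds, purine atom first
.WC_BONDS <- list(
  `DG:DC` = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2")),
  `8OG:DC` = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2")),
  `DA:DT` = list(c("N6", "O4"), c("N1", "N3")))

#' Watson-Crick hydrogen-bond distance restraints
#'
#' Emits canonical heavy-atom restraints (target 2.9 angstrom, bounds
#' +/- 0.2 by default) for every non-terminal base pair: three per G:C or
#' 8OG:C pair, two per A:T pair. 8-oxoguanine keeps the full guanine
#' Watson-Crick edge.
#'
#' @param map duplex map from [pair_duplex()].
#' @param target,tol target distance and symmetric tolerance, angstrom.
#' @return Restraint data frame in the same dialect as
#'   [compile_restraints()], provenance `"wc-hbond"`.
#' @export
wc_restraints <- function(map, target = 2.9, tol = 0.2) {
  ca <- attr(map, "chain_a")
  cb <- attr(map, "chain_b")
  rows <- list()
  for (i in which(!map$terminal)) {
    a <- map$code_a[i]
    b <- map$code_b[i]
    purine_a <- a %in% c("DA", "DG", "8OG")
    key <- if (purine_a) paste(a, b, sep = ":") else paste(b, a, sep = ":")
    bonds <- .WC_BONDS[[key]]
    if (is.null(bonds)) next
    for (bd in bonds) {
      rows[[length(rows) + 1]] <- data.frame(
        chain_i = if (purine_a) ca else cb,
        res_i = if (purine_a) map$res_a[i] else map$res_b[i],
        atom_i = bd[1],
        chain_j = if (purine_a) cb else ca,
        res_j = if (purine_a) map$res_b[i] else map$res_a[i],
        atom_j = bd[2],
        target = target, lower = target - tol, upper = target + tol,
        group = "wc-hbond", provenance = "wc-hbond",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## default allowed ranges for backbone torsions in the BI well (degrees);
## alpha-delta are centered (+/- 30) on the idealized B-form template's
## torsions so the package's own ideal builds satisfy their own restraints
.BI_RANGES <- list(alpha = c(278, 338), beta = c(136, 196),
                   gamma = c(22, 82), delta = c(93, 153),
                   epsilon = c(155, 245), zeta = c(235, 325))
.OXO_RANGES <- list(epsilon = c(215, 295), zeta = c(155, 205))

.DIHEDRAL_ATOMS <- function(chain, i) list(
  alpha = list(c(chain, i - 1, "O3'"), c(chain, i, "P"), c(chain, i, "O5'"),
               c(chain, i, "C5'")),
  beta = list(c(chain, i, "P"), c(chain, i, "O5'"), c(chain, i, "C5'"),
              c(chain, i, "C4'")),
  gamma = list(c(chain, i, "O5'"), c(chain, i, "C5'"), c(chain, i, "C4'"),
               c(chain, i, "C3'")),
  delta = list(c(chain, i, "C5'"), c(chain, i, "C4'"), c(chain, i, "C3'"),
               c(chain, i, "O3'")),
  epsilon = list(c(chain, i, "C4'"), c(chain, i, "C3'"), c(chain, i, "O3'"),
                 c(chain, i + 1, "P")),
  zeta = list(c(chain, i, "C3'"), c(chain, i, "O3'"), c(chain, i + 1, "P"),
              c(chain, i + 1, "O5'")))

.dih_row <- function(chain, resi, torsion, lo, hi, label) {
  atoms <- .DIHEDRAL_ATOMS(chain, resi)[[torsion]]
  keys <- vapply(atoms, function(a) paste(a[1], a[2], a[3], sep = ":"),
                 character(1))
  data.frame(chain = chain, resi = resi, torsion = torsion,
             atom1 = keys[1], atom2 = keys[2], atom3 = keys[3],
             atom4 = keys[4], lo = lo, hi = hi, label = label,
             stringsAsFactors = FALSE)
}

#' Backbone dihedral restraints for a duplex strand
#'
#' Restrains epsilon and zeta of every internal linkage to the standard BI
#' ranges, switches the 8-oxoguanine linkage to the BII ranges (epsilon
#' 215-295, zeta 155-205), and lets the two dihedrals on either side of that
#' epsilon/zeta pair (gamma and delta before, alpha and beta of the next
#' nucleotide after) sample their parent ranges broadened by +/- 20 degrees.
#'
#' @param sequence strand sequence (A/C/G/T/X), 5' to 3'.
#' @param oxo_positions 1-based lesion positions; `NULL` derives them from
#'   the X symbols in `sequence`.
#' @param chain chain label. Default "A".
#' @param bi_ranges,oxo_ranges named lists of allowed ranges
#'   (config-overridable).
#' @return Data frame of dihedral restraints: residue, torsion name, the 4
#'   atom keys, `lo`, `hi`, `label` in `{"BI-standard", "oxoG-epsilon",
#'   "oxoG-zeta", "neighbor-broadened"}`.
#' @export
backbone_dihedral_restraints <- function(sequence, oxo_positions = NULL,
                                         chain = "A",
                                         bi_ranges = .BI_RANGES,
                                         oxo_ranges = .OXO_RANGES) {
  codes <- parse_duplex_sequence(sequence)$a
  n <- length(codes)
  if (is.null(oxo_positions)) oxo_positions <- which(codes == "8OG")
  if (any(oxo_positions < 1 | oxo_positions > n))
    stop("input error: oxo position out of range", call. = FALSE)
  rows <- list()
  for (k in seq_len(n - 1)) {
    if (k %in% oxo_positions) {
      rows[[length(rows) + 1]] <- .dih_row(chain, k, "epsilon",
                                           oxo_ranges$epsilon[1],
                                           oxo_ranges$epsilon[2],
                                           "oxoG-epsilon")
      rows[[length(rows) + 1]] <- .dih_row(chain, k, "zeta",
                                           oxo_ranges$zeta[1],
                                           oxo_ranges$zeta[2], "oxoG-zeta")
    } else {
      rows[[length(rows) + 1]] <- .dih_row(chain, k, "epsilon",
                                           bi_ranges$epsilon[1],
                                           bi_ranges$epsilon[2],
                                           "BI-standard")
      rows[[length(rows) + 1]] <- .dih_row(chain, k, "zeta",
                                           bi_ranges$zeta[1],
                                           bi_ranges$zeta[2], "BI-standard")
    }
  }
  for (k in oxo_positions) {
    nb <- list(list("gamma", k), list("delta", k))
    if (k + 1 <= n) nb <- c(nb, list(list("alpha", k + 1),
                                     list("beta", k + 1)))
    for (x in nb) {
      parent <- bi_ranges[[x[[1]]]]
      rows[[length(rows) + 1]] <- .dih_row(chain, x[[2]], x[[1]],
                                           parent[1] - 20, parent[2] + 20,
                                           "neighbor-broadened")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## circular distance of angle a (degrees) outside the arc [lo, hi]
arc_violation <- function(a, lo, hi) {
  a <- wrap360(a)
  lo0 <- wrap360(lo)
  width <- (hi - lo) %% 360
  offset <- (a - lo0) %% 360
  if (offset <= width) return(0)
  min((offset - width) %% 360, (360 - offset) %% 360)
}

#' Score restraint violations on a structure
#'
#' For every model: the distance violation of a restraint is
#' `max(0, d - upper, lower - d)`; the dihedral violation is the angular
#' distance outside the allowed arc. Restraints naming atoms absent from
#' the structure are excluded with a warning and listed.
#'
#' @param s a [dna_structure()].
#' @param dr distance restraints ([compile_restraints()] dialect), or
#'   `NULL`.
#' @param dh dihedral restraints ([backbone_dihedral_restraints()]), or
#'   `NULL`.
#' @return Object of class `violation_report`: per-model
#'   `max_distance_violation` (angstrom), `max_dihedral_violation`
#'   (degrees), offending restraint descriptions, and the unresolved
#'   restraints.
#' @export
violation_report <- function(s, dr = NULL, dh = NULL) {
  nm <- n_models(s)
  resolve <- function(chain, resi, atom)
    atom_index(s, chain, as.integer(resi), atom)
  unresolved <- character()

  d_idx <- NULL
  if (!is.null(dr) && nrow(dr) > 0) {
    i1 <- mapply(resolve, dr$chain_i, dr$res_i, dr$atom_i)
    i2 <- mapply(resolve, dr$chain_j, dr$res_j, dr$atom_j)
    ok <- i1 > 0 & i2 > 0
    if (any(!ok)) {
      miss <- unique(c(
        paste(dr$chain_i, dr$res_i, dr$atom_i, sep = ":")[i1 == 0],
        paste(dr$chain_j, dr$res_j, dr$atom_j, sep = ":")[i2 == 0]))
      warning("excluding ", sum(!ok),
              " distance restraint(s) with unresolvable atoms: ",
              paste(utils::head(miss, 5), collapse = ", "))
      unresolved <- c(unresolved, miss)
    }
    d_idx <- list(i1 = i1[ok], i2 = i2[ok], dr = dr[ok, , drop = FALSE])
  }
  h_idx <- NULL
  if (!is.null(dh) && nrow(dh) > 0) {
    km <- sapply(c("atom1", "atom2", "atom3", "atom4"), function(cn)
      vapply(strsplit(dh[[cn]], ":"), function(p)
        resolve(p[1], p[2], p[3]), numeric(1)))
    km <- matrix(km, nrow = nrow(dh))
    ok <- apply(km > 0, 1, all)
    if (any(!ok)) {
      miss <- unique(unlist(dh[!ok, c("atom1", "atom2", "atom3", "atom4")])
                     [as.vector(km[!ok, ] == 0)])
      warning("excluding ", sum(!ok),
              " dihedral restraint(s) with unresolvable atoms")
      unresolved <- c(unresolved, miss)
    }
    h_idx <- list(idx = km[ok, , drop = FALSE], dh = dh[ok, , drop = FALSE])
  }

  per_model <- lapply(seq_len(nm), function(m) {
    xyz <- s$xyz[[m]]
    dmax <- 0
    dworst <- NA_character_
    if (!is.null(d_idx) && nrow(d_idx$dr) > 0) {
      d <- sqrt(rowSums((xyz[d_idx$i1, , drop = FALSE] -
                           xyz[d_idx$i2, , drop = FALSE])^2))
      v <- pmax(0, d - d_idx$dr$upper, d_idx$dr$lower - d)
      dmax <- max(v)
      if (dmax > 0) {
        w <- which.max(v)
        dworst <- paste0(d_idx$dr$chain_i[w], ":", d_idx$dr$res_i[w], ":",
                         d_idx$dr$atom_i[w], " - ", d_idx$dr$chain_j[w],
                         ":", d_idx$dr$res_j[w], ":", d_idx$dr$atom_j[w])
      }
    }
    hmax <- 0
    hworst <- NA_character_
    if (!is.null(h_idx) && nrow(h_idx$dh) > 0) {
      v <- vapply(seq_len(nrow(h_idx$dh)), function(i) {
        pts <- lapply(1:4, function(k) xyz[h_idx$idx[i, k], ])
        a <- dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]], "unsigned")
        arc_violation(a, h_idx$dh$lo[i], h_idx$dh$hi[i])
      }, numeric(1))
      hmax <- max(v)
      if (hmax > 0) {
        w <- which.max(v)
        hworst <- paste0(h_idx$dh$chain[w], ":", h_idx$dh$resi[w], ":",
                         h_idx$dh$torsion[w])
      }
    }
    list(model = m, max_distance_violation = dmax,
         max_dihedral_violation = hmax,
         worst_distance_restraint = dworst, worst_dihedral = hworst)
  })

  structure(list(per_model = per_model,
                 max_distance_violation =
                   max(vapply(per_model, `[[`, 0, "max_distance_violation")),
                 max_dihedral_violation =
                   max(vapply(per_model, `[[`, 0, "max_dihedral_violation")),
                 unresolved = unresolved),
            class = "violation_report")
}

#' @export
print.violation_report <- function(x, ...) {
  cat("<violation_report> ", length(x$per_model), " model(s)\n",
      "  max distance violation: ",
      signif(x$max_distance_violation, 4), " A\n",
      "  max dihedral violation: ",
      signif(x$max_dihedral_violation, 4), " deg\n", sep = "")
  if (length(x$unresolved) > 0)
    cat("  unresolved atoms: ", length(x$unresolved), "\n", sep = "")
  invisible(x)
}

#' Write a violation report as JSON
#' @param vr a `violation_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_violation_report <- function(vr, path) {
  jsonlite::write_json(unclass(vr), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

## --- flat-file dialects -----------------------------------------------------

#' Read/write the peak-list TSV dialect
#'
#' Columns: `peak_id`, `res_i`, `atom_i`, `res_j`, `atom_j`, `volume`,
#' `mixing_time_ms`.
#' @param path file path.
#' @return Data frame (`read_peaklist`) or `path` (`write_peaklist`).
#' @export
read_peaklist <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_peaklist
#' @param peaks peak-list data frame.
#' @export
write_peaklist <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write the flat restraint TSV dialect
#'
#' Columns: `chain_i`, `res_i`, `atom_i`, `chain_j`, `res_j`, `atom_j`,
#' `lower`, `target`, `upper`, `group`, `provenance`.
#' @param path file path.
#' @return Data frame (`read_restraints`) or `path` (`write_restraints`).
#' @export
read_restraints <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_restraints
#' @param restraints restraint data frame.
#' @export
write_restraints <- function(restraints, path) {
  utils::write.table(restraints, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write restraints in CYANA-style .upl format
#'
#' One upper-limit line per restraint: residue number, residue name
#' placeholder, atom name for both partners, then the upper bound.
#'
#' @param restraints restraint data frame.
#' @param path output file.
#' @param codes optional residue-code vector (1-based) for the name column.
#' @return `path`, invisibly.
#' @export
write_upl <- function(restraints, path, codes = NULL) {
  nm <- function(res) {
    if (is.null(codes)) "NT" else codes[res]
  }
  lines <- vapply(seq_len(nrow(restraints)), function(i) {
    r <- restraints[i, ]
    sprintf("%4d %-4s %-5s %4d %-4s %-5s %8.2f", r$res_i, nm(r$res_i),
            r$atom_i, r$res_j, nm(r$res_j), r$atom_j, r$upper)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
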