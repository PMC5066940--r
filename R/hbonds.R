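## Geometric hydrogen-bond detection and per-ensemble occupancy.

#' Default hydrogen-bond criteria
#'
#' Heavy-atom donor-acceptor distance cutoff of 3.5 angstrom and a
#' donor-H-acceptor angle of at least 120 degrees (checked only when the
#' donor hydrogen is present), following common MD-analysis practice.
#' @export
hbond_criteria <- function(max_DA = 3.5, min_angle = 120) {
  stopifnot(max_DA > 0, min_angle >= 0, min_angle <= 180)
  list(max_DA = max_DA, min_angle = min_angle)
}

#' Detect hydrogen bonds in one model
#'
#' Enumerates base donor/acceptor pairs across different residues (embedded
#' typing: e.g. guanine donates from N1 and N2 and accepts at O6, N3 and N7;
#' 8-oxoguanine additionally donates from N7 and accepts at O8) and keeps
#' pairs within the distance cutoff. When the donor hydrogen exists the
#' D-H...A angle must also pass; bonds whose angle could not be checked are
#' flagged.
#'
#' @param s a [dna_structure()].
#' @param model model index.
#' @param criteria see [hbond_criteria()].
#' @return Data frame sorted by donor residue then distance: `donor`,
#'   `hydrogen`, `acceptor` (atom keys `chain:resi:atom`), `distance_A`,
#'   `angle_deg` (`NA` when no hydrogen), `angle_checked`.
#' @export
detect_hbonds <- function(s, model = 1, criteria = hbond_criteria()) {
  at <- s$atoms
  xyz <- s$xyz[[model]]
  don <- which(mapply(function(rn, a) rn %in% names(.HB_DONORS) &&
                        a %in% .HB_DONORS[[rn]], at$resn, at$atom))
  acc <- which(mapply(function(rn, a) rn %in% names(.HB_ACCEPTORS) &&
                        a %in% .HB_ACCEPTORS[[rn]], at$resn, at$atom))
  rows <- list()
  for (d in don) {
    hyd_names <- .DONOR_H[[at$atom[d]]]
    hyd_idx <- vapply(hyd_names, function(h)
      atom_index(s, at$chain[d], at$resi[d], h), integer(1))
    hyd_idx <- hyd_idx[hyd_idx > 0]
    for (a in acc) {
      if (at$chain[a] == at$chain[d] && at$resi[a] == at$resi[d]) next
      dist <- vnorm(xyz[d, ] - xyz[a, ])
      if (dist > criteria$max_DA) next
      ang <- NA_real_
      hname <- NA_character_
      if (length(hyd_idx) > 0) {
        angs <- vapply(hyd_idx, function(h) {
          v1 <- xyz[d, ] - xyz[h, ]
          v2 <- xyz[a, ] - xyz[h, ]
          rad2deg(acos(pmin(1, pmax(-1, sum(unitv(v1) * unitv(v2))))))
        }, numeric(1))
        best <- which.max(angs)
        ang <- angs[best]
        hname <- paste(at$chain[d], at$resi[d], names(hyd_idx)[best],
                       sep = ":")
        if (ang < criteria$min_angle) next
      }
      rows[[length(rows) + 1]] <- data.frame(
        donor = paste(at$chain[d], at$resi[d], at$atom[d], sep = ":"),
        hydrogen = hname,
        acceptor = paste(at$chain[a], at$resi[a], at$atom[a], sep = ":"),
        distance_A = dist, angle_deg = ang,
        angle_checked = length(hyd_idx) > 0,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(donor = character(), hydrogen = character(),
                      acceptor = character(), distance_A = numeric(),
                      angle_deg = numeric(), angle_checked = logical()))
  out <- do.call(rbind, rows)
  key <- sub(":[^:]+$", "", out$donor)
  out[order(key, out$distance_A), , drop = FALSE]
}

#' Hydrogen-bond occupancy across models
#'
#' Detects bonds in every model and reports, per donor/acceptor identity,
#' the fraction of models in which the bond is present and its mean length.
#' The analysis can be restricted to a site given as residue keys
#' (`"chain:resi"`); a bond is in-site when both partners are.
#'
#' @param s a [dna_structure()].
#' @param site character vector of `"chain:resi"` keys, or `NULL` for all.
#' @param criteria see [hbond_criteria()].
#' @return Data frame with `donor`, `acceptor`, `fraction`, `mean_length_A`,
#'   sorted by descending fraction; zero rows for an empty site.
#' @export
hbond_occupancy <- function(s, site = NULL, criteria = hbond_criteria()) {
  if (!is.null(site) && length(site) == 0)
    return(data.frame(donor = character(), acceptor = character(),
                      fraction = numeric(), mean_length_A = numeric()))
  nm <- n_models(s)
  per_model <- lapply(seq_len(nm), function(m) {
    hb <- detect_hbonds(s, m, criteria)
    if (!is.null(site) && nrow(hb) > 0) {
      rkey <- function(k) sub(":[^:]+$", "", k)
      hb <- hb[rkey(hb$donor) %in% site & rkey(hb$acceptor) %in% site, ,
               drop = FALSE]
    }
    hb
  })
  all_b <- do.call(rbind, per_model)
  if (nrow(all_b) == 0)
    return(data.frame(donor = character(), acceptor = character(),
                      fraction = numeric(), mean_length_A = numeric()))
  id <- paste(all_b$donor, all_b$acceptor, sep = " -> ")
  agg <- lapply(split(all_b, id), function(d) {
    data.frame(donor = d$donor[1], acceptor = d$acceptor[1],
               fraction = nrow(d) / nm, mean_length_A = mean(d$distance_A),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(-out$fraction, out$donor), , drop = FALSE]
}

#' Residue keys of the base pairs spanning given pair positions
#'
#' Convenience for site-restricted occupancy: expands pair positions (e.g.
#' the GAATTC hexamer, positions 4-9 of the dodecamer) into the
#' `"chain:resi"` keys of both strands.
#'
#' @param map a duplex map from [pair_duplex()].
#' @param positions pair positions along strand A.
#' @return Character vector of residue keys.
#' @export
site_keys <- function(map, positions) {
  i <- match(positions, map$pair)
  if (anyNA(i)) stop("position(s) outside the duplex: ",
                     paste(positions[is.na(i)], collapse = ", "),
                     call. = FALSE)
  c(paste(attr(map, "chain_a"), map$res_a[i], sep = ":"),
    paste(attr(map, "chain_b"), map$res_b[i], sep = ":"))
}
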