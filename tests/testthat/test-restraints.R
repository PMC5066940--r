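make_peaks <- function(rows) {
  cbind(peak_id = seq_len(nrow(rows)), rows)
}

test_that("calibration follows the r^-6 law and is scale-invariant", {
  ref <- list(res_i = 3, atom_i = "H5", res_j = 3, atom_j = "H6")
  pk <- make_peaks(data.frame(
    res_i = c(3, 5, 6), atom_i = c("H5", "H1'", "H1'"),
    res_j = c(3, 5, 6), atom_j = c("H6", "H8", "H6"),
    volume = c(8, 8, 8 / 64), mixing_time_ms = 140))
  cal <- calibrate(pk, ref, r_ref = 2.45)
  expect_equal(cal$distance[1], 2.45)           # V = V_ref
  expect_equal(cal$distance[2], 2.45)
  expect_equal(cal$distance[3], 2 * 2.45)       # V_ref / 64 doubles r

  for (c0 in c(0.01, 3, 1e5)) {
    pk2 <- pk
    pk2$volume <- pk2$volume * c0
    expect_equal(calibrate(pk2, ref, 2.45)$distance, cal$distance,
                 tolerance = 1e-12)
  }

  pk3 <- pk[-1, ]
  expect_error(calibrate(pk3, ref, 2.45), "calibration error")
})

test_that("mixing-time merging averages complete pairs and falls back otherwise", {
  ref <- list(res_i = 3, atom_i = "H5", res_j = 3, atom_j = "H6")
  base <- data.frame(
    res_i = c(3, 4, 5), atom_i = c("H5", "H1'", "H2'"),
    res_j = c(3, 4, 5), atom_j = c("H6", "H8", "H6"),
    volume = NA, mixing_time_ms = NA)
  pk <- do.call(rbind, lapply(c(70, 140, 200), function(mt) {
    d <- base
    d$mixing_time_ms <- mt
    d$volume <- c(10, 2.45^6 * 10 / c(3.0, 3.2, 3.4)[match(mt, c(70, 140, 200))]^6, 5)
    d
  }))
  # drop the third pair from two sets so it must fall back to one peak
  pk <- pk[!(pk$res_i == 5 & pk$mixing_time_ms %in% c(70, 200)), ]
  pk <- make_peaks(pk)
  merged <- merge_mixing_times(calibrate(pk, ref, 2.45))
  m4 <- merged[merged$res_i == 4, ]
  expect_identical(m4$provenance, "averaged")
  expect_equal(m4$distance, mean(c(3.0, 3.2, 3.4)), tolerance = 1e-9)
  m5 <- merged[merged$res_i == 5, ]
  expect_identical(m5$provenance, "non-averaged")
})

test_that("bounds and grouping follow the length rule with methyl override", {
  tol <- restraint_tolerances()
  b <- assign_bounds(2.5, FALSE, tol)
  expect_identical(b$group, "short")
  expect_equal(c(b$lower, b$upper), c(2.1, 2.9))
  expect_identical(assign_bounds(4.0, FALSE, tol)$group, "medium")
  expect_identical(assign_bounds(6.2, FALSE, tol)$group, "long")
  bm <- assign_bounds(3.5, TRUE, tol)
  expect_identical(bm$group, "methyl")
  expect_equal(bm$upper, 3.5 + 0.7 + 1.0)   # group tolerance + pseudoatom
  expect_error(assign_bounds(-1), "input error")
})

test_that("compiled restraints partition into the ledger identity", {
  s <- build_torsion_exact(ddd_seq)
  pk <- synth_peaklist(s, noise = 0.1, seed = 31)
  # thin some pairs out of single mixing-time sets to create non-averaged
  drop <- with(pk, (res_i %% 5 == 0 & mixing_time_ms == 70) |
                 (res_j %% 4 == 0 & mixing_time_ms == 200))
  dr <- compile_restraints(pk[!drop, ],
                           ref = list(res_i = 3, atom_i = "H5",
                                      res_j = 3, atom_j = "H6"),
                           r_ref = true_ref_distance(s))
  led <- restraint_ledger(dr)
  expect_gt(led$averaged, 0)
  expect_gt(led$non_averaged, 0)
  expect_gt(led$methyl, 0)
  expect_equal(led$averaged + led$non_averaged + led$methyl, led$total)
  # grouping is a partition
  expect_true(all(dr$group %in% c("short", "medium", "long", "methyl")))
  with_g <- table(dr$group)
  expect_equal(sum(with_g), nrow(dr))
})

test_that("symmetry duplication doubles counts, maps indices, and involutes", {
  map <- pair_duplex(NULL, ddd_seq)
  r <- data.frame(chain_i = "A", res_i = 2, atom_i = "H1'",
                  chain_j = "A", res_j = 3, atom_j = "H6",
                  target = 3, lower = 2.6, upper = 3.4,
                  group = "medium", provenance = "averaged")
  dup <- duplicate_symmetry(r, map)
  expect_equal(nrow(dup), 2)
  copy <- dup[dup$provenance == "symmetry-copy", ]
  expect_identical(copy$chain_i, "B")
  expect_equal(c(copy$res_i, copy$res_j), c(2, 3))
  # chain B residues 2-3 sit at pair positions 11-10 of the duplex
  expect_equal(map$pair[match(c(copy$res_i, copy$res_j), map$res_b)],
               c(11L, 10L))

  # 189 unique restraints duplicate to 378
  many <- do.call(rbind, replicate(189, r, simplify = FALSE))
  many$res_i <- rep(2:7, length.out = 189)
  expect_equal(nrow(duplicate_symmetry(many, map)), 378)

  # involution up to provenance: duplicating the copies reproduces the
  # original atom-pair multiset
  dup2 <- duplicate_symmetry(dup[names(r)], map)
  key <- function(d) sort(paste(d$chain_i, d$res_i, d$atom_i,
                                d$chain_j, d$res_j, d$atom_j))
  expect_identical(unique(key(dup2)), unique(key(dup)))

  # a self-symmetric restraint is emitted once and flagged
  rs <- r
  rs$chain_j <- "B"
  rs$res_j <- 2
  rs$atom_j <- "H1'"
  dups <- duplicate_symmetry(rs, map)
  expect_equal(nrow(dups), 1)
  expect_true(dups$self_symmetric)

  r_bad <- r
  r_bad$res_j <- 40
  expect_error(duplicate_symmetry(r_bad, map), "duplication error")
})

test_that("Watson-Crick restraints cover non-terminal pairs only", {
  map <- pair_duplex(NULL, ddd_seq)
  wc <- wc_restraints(map)
  # 10 non-terminal pairs: 6 G:C-type x 3 + 4 A:T x 2 = 26
  expect_equal(nrow(wc), 26)
  expect_false(any(wc$res_i %in% c(1, 12) & wc$chain_i == "A"))
  expect_true(all(wc$target == 2.9))

  # the lesion pair still gets its 3 restraints
  mo <- pair_duplex(NULL, oxog4_seq)
  wco <- wc_restraints(mo)
  lesion <- wco[wco$chain_i == "A" & wco$res_i == 4, ]
  expect_equal(nrow(lesion), 3)
  expect_setequal(lesion$atom_i, c("O6", "N1", "N2"))
})

test_that("backbone dihedral restraints encode the lesion's BII ranges", {
  dh <- backbone_dihedral_restraints(oxog4_seq)
  oe <- dh[dh$label == "oxoG-epsilon", ]
  expect_equal(nrow(oe), 1)
  expect_equal(c(oe$lo, oe$hi), c(215, 295))
  expect_equal(oe$resi, 4)
  oz <- dh[dh$label == "oxoG-zeta", ]
  expect_equal(c(oz$lo, oz$hi), c(155, 205))
  # neighbors sample their parent range broadened by 20 on each side
  nb <- dh[dh$label == "neighbor-broadened", ]
  expect_setequal(paste(nb$torsion, nb$resi),
                  c("gamma 4", "delta 4", "alpha 5", "beta 5"))
  par_g <- dh[dh$label == "neighbor-broadened" & dh$torsion == "gamma", ]
  expect_equal(c(par_g$lo, par_g$hi), c(22 - 20, 82 + 20))

  # the package's own ideal lesion build satisfies the full restraint set
  s_ok <- build_torsion_exact(oxog4_seq, bii_at = 4)
  expect_equal(violation_report(s_ok, NULL, dh)$max_dihedral_violation, 0)

  # no lesion: all labels BI-standard
  dh0 <- backbone_dihedral_restraints(ddd_seq)
  expect_identical(unique(dh0$label), "BI-standard")
  expect_error(backbone_dihedral_restraints(ddd_seq, oxo_positions = 40),
               "input error")
})

test_that("violation scoring measures distance and arc excursions", {
  s <- build_torsion_exact(ddd_seq)
  x <- model_xyz(s, 1)
  d0 <- sqrt(sum((x["A:4:H1'", ] - x["A:5:H8", ])^2))
  r <- data.frame(chain_i = "A", res_i = 4, atom_i = "H1'",
                  chain_j = "A", res_j = 5, atom_j = "H8",
                  target = d0, lower = d0 - 0.4, upper = d0 + 0.4,
                  group = "short", provenance = "averaged")
  vr <- violation_report(s, r, NULL)
  expect_equal(vr$max_distance_violation, 0)

  # shrink the upper bound so the true distance exceeds it by 0.25
  r2 <- r
  r2$upper <- d0 - 0.25
  r2$lower <- d0 - 0.45
  vr2 <- violation_report(s, r2, NULL)
  expect_equal(vr2$max_distance_violation, 0.25, tolerance = 0.01)

  # epsilon forced to 310 against [215, 295] violates by 15 degrees
  sb <- build_torsion_exact(ddd_seq, eps = 310, zeta = 180)
  dh <- backbone_dihedral_restraints(oxog4_seq)
  vr3 <- violation_report(sb, NULL, dh[dh$label == "oxoG-epsilon", ])
  expect_equal(vr3$max_dihedral_violation, 15, tolerance = 0.01)

  # a satisfied lesion build has zero dihedral violation
  sg <- build_torsion_exact(oxog4_seq, eps = 255, zeta = 180)
  vr4 <- violation_report(sg, NULL, dh[dh$resi == 4 & dh$torsion %in%
                                         c("epsilon", "zeta"), ])
  expect_equal(vr4$max_dihedral_violation, 0)

  # unresolvable atoms are excluded with a warning and listed
  r3 <- r
  r3$atom_j <- "H99"
  expect_warning(vr5 <- violation_report(s, r3, NULL), "unresolvable")
  expect_true(length(vr5$unresolved) == 1)
})

test_that("peak list to violation round trip closes at zero noise", {
  s <- build_torsion_exact(ddd_seq)
  pk <- synth_peaklist(s, noise = 0)
  dr <- compile_restraints(pk, ref = list(res_i = 3, atom_i = "H5",
                                          res_j = 3, atom_j = "H6"),
                           r_ref = true_ref_distance(s))
  # recovered distances equal the true interproton distances
  x <- model_xyz(s, 1)
  truth <- sqrt(rowSums((x[paste("A", dr$res_i, dr$atom_i, sep = ":"), ] -
                           x[paste("A", dr$res_j, dr$atom_j, sep = ":"), ])^2))
  expect_lt(max(abs(dr$target - truth)), 1e-6)
  vr <- violation_report(s, dr, NULL)
  expect_equal(vr$max_distance_violation, 0)
})

test_that("restraint and peak-list files round trip through their dialects", {
  s <- build_torsion_exact(ddd_seq)
  pk <- synth_peaklist(s, noise = 0.05, seed = 3)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_peaklist(pk, f1)
  expect_equal(read_peaklist(f1), pk, tolerance = 1e-9)

  dr <- compile_restraints(pk, ref = list(res_i = 3, atom_i = "H5",
                                          res_j = 3, atom_j = "H6"))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_restraints(dr, f2)
  expect_equal(read_restraints(f2), dr, tolerance = 1e-9)

  f3 <- withr::local_tempfile(fileext = ".upl")
  write_upl(dr, f3)
  expect_equal(length(readLines(f3)), nrow(dr))
})
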