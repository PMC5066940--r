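test_that("sequence parsing handles the lesion alphabet and self-annealing", {
  p <- parse_duplex_sequence(oxog4_seq)
  expect_identical(p$a[4], "8OG")
  # the lesion-bearing palindrome derivative anneals with itself, so the
  # second strand is the same oligo (one lesion per strand)
  expect_identical(p$b[4], "8OG")
  # a non-self-annealing sequence falls back to the reverse complement
  q <- parse_duplex_sequence("AACGT")
  expect_identical(q$b, c("DA", "DC", "DG", "DT", "DT"))
  expect_error(parse_duplex_sequence("ACGU"), "invalid sequence symbol")
})

test_that("helix builder realizes its spec and embeds the lesion atoms", {
  bh <- build_helix(oxog4_seq)
  s <- bh$structure
  expect_equal(n_models(s), 1)
  expect_identical(residues(s, "A")$resn[4], "8OG")
  expect_gt(atom_index(s, "A", 4, "O8"), 0)
  expect_gt(atom_index(s, "A", 4, "H7"), 0)
  # 5' termini carry no phosphate
  expect_equal(atom_index(s, "A", 1, "P"), 0)
  expect_equal(atom_index(s, "B", 1, "P"), 0)
  expect_gt(atom_index(s, "A", 2, "P"), 0)
  expect_error(build_helix("ACGQ"), "invalid sequence symbol")
})

test_that("torsion-exact builder hits requested epsilon/zeta to 0.1 degree", {
  eps <- rep(188.886, 12); zeta <- rep(253.887, 12)
  eps[7] <- 262; zeta[7] <- 193
  s <- build_torsion_exact(ddd_seq, eps = eps, zeta = zeta)
  for (i in c(3, 7, 10)) {
    ts <- backbone_torsions(s, 1, "A", i)
    expect_lt(abs(ts$angles[["epsilon"]] - eps[i]), 0.1)
    expect_lt(abs(ts$angles[["zeta"]] - zeta[i]), 0.1)
  }
  expect_error(build_torsion_exact(ddd_seq, eps = 400), "\\[0, 360\\)")
  expect_error(build_torsion_exact(ddd_seq, bii_at = 12), "bii_at")
})

test_that("lesion built at the restraint midpoints satisfies its restraints", {
  s <- build_torsion_exact(oxog4_seq, eps = c(rep(188.886, 3), 255,
                                              rep(188.886, 8)),
                           zeta = c(rep(253.887, 3), 180,
                                    rep(253.887, 8)))
  dh <- backbone_dihedral_restraints(oxog4_seq)
  vr <- violation_report(s, NULL, dh[dh$resi == 4 & dh$torsion %in%
                                       c("epsilon", "zeta"), ])
  expect_equal(vr$max_dihedral_violation, 0)
})

test_that("ensembles are seeded, deterministic, and leave the caller's RNG alone", {
  s <- build_helix("CGCG")$structure
  e1 <- make_ensemble(s, 0.1, 5, seed = 99)
  e2 <- make_ensemble(s, 0.1, 5, seed = 99)
  expect_identical(e1$xyz, e2$xyz)
  e3 <- make_ensemble(s, 0.1, 5, seed = 100)
  expect_false(identical(e1$xyz, e3$xyz))
  # sigma = 0 reproduces the parent exactly
  e0 <- make_ensemble(s, 0, 3, seed = 1)
  for (m in 1:3) expect_identical(e0$xyz[[m]], s$xyz[[1]])

  set.seed(123)
  before <- rnorm(5)
  set.seed(123)
  invisible(make_ensemble(s, 0.1, 2, seed = 7))
  expect_identical(rnorm(5), before)
})

test_that("synthetic peaks follow the r^-6 law with the reference included", {
  s <- build_torsion_exact(ddd_seq)
  pk <- synth_peaklist(s, noise = 0, mixing_times = c(140))
  x <- model_xyz(s, 1)
  # every volume is c * r^-6 exactly at zero noise
  r <- sqrt(rowSums((x[paste("A", pk$res_i, pk$atom_i, sep = ":"), ] -
                       x[paste("A", pk$res_j, pk$atom_j, sep = ":"), ])^2))
  expect_lt(max(abs(pk$volume * r^6 - 1)), 1e-9)
  expect_true(all(r <= 5))
  # cytosine H5-H6 reference pairs are present
  has_ref <- any(pk$res_i == pk$res_j &
                   ((pk$atom_i == "H5" & pk$atom_j == "H6") |
                      (pk$atom_i == "H6" & pk$atom_j == "H5")))
  expect_true(has_ref)
  # one record per mixing time
  pk3 <- synth_peaklist(s, noise = 0)
  expect_equal(nrow(pk3), 3 * nrow(pk))

  # a structure without hydrogens cannot generate peaks
  heavy <- select_atoms(s, "all-heavy")
  s_h <- dna_structure(s$atoms[heavy, ], s$xyz[[1]][heavy, ])
  expect_error(synth_peaklist(s_h), "no hydrogens")
})

test_that("a proton pair at twice the reference distance yields V_ref / 64", {
  s <- build_torsion_exact(ddd_seq)
  pk <- synth_peaklist(s, noise = 0, mixing_times = 140)
  x <- model_xyz(s, 1)
  r <- sqrt(rowSums((x[paste("A", pk$res_i, pk$atom_i, sep = ":"), ] -
                       x[paste("A", pk$res_j, pk$atom_j, sep = ":"), ])^2))
  i <- which.min(abs(r - 2 * r[1]))
  expect_equal(pk$volume[i], unname(pk$volume[1] * (r[1] / r[i])^6),
               tolerance = 1e-9)
})
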