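test_that("dihedral reproduces cis/trans and matches the brute-force oracle", {
  p1 <- c(1, 1, 0); p2 <- c(1, 0, 0); p3 <- c(-1, 0, 0)
  expect_equal(dihedral(p1, p2, p3, c(-1, 1, 0)), 0)
  expect_equal(abs(dihedral(p1, p2, p3, c(-1, -1, 0))), 180)
  expect_error(dihedral(p1, p1, p3, c(-1, -1, 0)), "degenerate")
  expect_error(dihedral(c(2, 0, 0), p2, p3, c(-1, -1, 0)), "collinear")

  set.seed(41)
  for (k in 1:200) {
    p <- matrix(rnorm(12), 4, 3)
    expect_equal(dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-6)
  }
  # unsigned range maps the same geometry into [0, 360)
  set.seed(42)
  p <- matrix(rnorm(12), 4, 3)
  expect_equal(wrap180(dihedral(p[1, ], p[2, ], p[3, ], p[4, ], "unsigned")),
               dihedral(p[1, ], p[2, ], p[3, ], p[4, ]))
})

test_that("angle wrapping is idempotent and periodic", {
  x <- seq(-720, 720, by = 7.3)
  expect_true(all(wrap180(x) > -180 & wrap180(x) <= 180))
  expect_equal(wrap180(x + 360), wrap180(x))
  expect_true(all(wrap360(x) >= 0 & wrap360(x) < 360))
  expect_equal(wrap180(180), 180)
  expect_equal(wrap180(-180), 180)
})

test_that("backbone torsions recover the generator's exact ground truth", {
  s <- build_torsion_exact(ddd_seq, eps = 270, zeta = 180)
  for (i in c(2, 5, 9)) {
    ts <- backbone_torsions(s, 1, "A", i)
    expect_equal(unname(ts$angles["epsilon"]), 270, tolerance = 1e-4)
    expect_equal(unname(ts$angles["zeta"]), 180, tolerance = 1e-4)
  }
  # 3'-terminal nucleotide has no epsilon/zeta; 5'-terminal has no alpha/beta
  tend <- backbone_torsions(s, 1, "A", 12)
  expect_true(is.na(tend$angles["epsilon"]))
  expect_true(is.na(tend$angles["zeta"]))
  expect_false(tend$available[["epsilon"]])
  t1 <- backbone_torsions(s, 1, "A", 1)
  expect_true(is.na(t1$angles["alpha"]))

  # the ideal fiber build sits in the canonical BI well
  sh <- build_helix(ddd_seq)$structure
  ts <- backbone_torsions(sh, 1, "A", 6)
  emz <- wrap180(ts$angles[["epsilon"]] - ts$angles[["zeta"]])
  expect_lt(emz, -40)
  expect_gt(emz, -120)
  expect_identical(classify_step(ts)$state, "BI")
})

test_that("a missing internal backbone atom is an error naming it", {
  s <- build_helix("CGCG")$structure
  drop <- !(s$atoms$chain == "A" & s$atoms$resi == 2 &
              s$atoms$atom == "C5'")
  s2 <- dna_structure(s$atoms[drop, ], s$xyz[[1]][drop, ])
  expect_error(backbone_torsions(s2, 1, "A", 2), "C5'.*A:2")
})

test_that("BI/BII classification follows the 20-degree rule exactly", {
  expect_identical(classify_step(c(epsilon = 190, zeta = 270))$state, "BI")
  expect_identical(classify_step(c(epsilon = 270, zeta = 180))$state, "BII")
  # midpoints of the lesion restraint ranges (255, 180) are BII
  cl <- classify_step(c(epsilon = 255, zeta = 180))
  expect_equal(cl$eps_minus_zeta, 75)
  expect_identical(cl$state, "BII")
  # boundary goes to BI; just above goes to BII
  expect_identical(classify_step(c(epsilon = 200, zeta = 180))$state, "BI")
  expect_identical(classify_step(c(epsilon = 200.01, zeta = 180))$state,
                   "BII")
  expect_true(is.na(classify_step(c(epsilon = NA, zeta = 100))$state))
})

test_that("classifier agrees with direct rule enumeration on a 1-degree grid", {
  eps <- rep(seq(0, 359, by = 1), times = 360)
  zet <- rep(seq(0, 359, by = 1), each = 360)
  got <- vapply(seq_along(eps), function(i)
    classify_step(c(epsilon = eps[i], zeta = zet[i]))$state, character(1))
  # oracle: angular difference via the complex-plane route, rule as stated
  d <- atan2(sin((eps - zet) * pi / 180), cos((eps - zet) * pi / 180)) *
    180 / pi
  d[d == -180] <- 180
  want <- ifelse(d > 20, "BII", "BI")
  expect_identical(got, want)
})

test_that("pseudorotation inverts its defining relations and flags symmetry", {
  nu <- 38 * cos(pi / 180 * (162 + (0:4 - 2) * 144))
  p <- pseudorotation(nu)
  expect_equal(p$P, 162, tolerance = 0.01)
  expect_equal(p$tau_m, 38, tolerance = 0.01)
  expect_identical(p$label, "C2'-endo")
  # negating every nu advances the phase by 180 and keeps the amplitude
  p2 <- pseudorotation(-nu)
  expect_equal(wrap360(p2$P - p$P), 180, tolerance = 1e-6)
  expect_equal(p2$tau_m, p$tau_m, tolerance = 1e-9)
  # the built sugar template itself sits in the C2'-endo range
  sh <- build_helix(ddd_seq)$structure
  pk <- sugar_pucker(sh, 1, "A", 6)
  expect_gte(pk$P, 144)
  expect_lt(pk$P, 180)
})

test_that("BII frequency counts models correctly", {
  s0 <- build_torsion_exact(ddd_seq)
  es <- make_ensemble(s0, 0.05, 10, seed = 5)
  prof <- bii_frequency(es, "A")
  expect_true(all(prof$bii_frequency == 0))
  expect_true(all(prof$n_models == 10))

  # 3 of 10 models carry the BII linkage at step 4
  sb <- build_torsion_exact(ddd_seq, bii_at = 4)
  mixed <- bind_models(make_ensemble(s0, 0, 7, seed = 1),
                       make_ensemble(sb, 0, 3, seed = 2))
  expect_equal(bii_frequency(mixed, "A", step = 4), 0.3)
  expect_true(all(bii_frequency(mixed, "A")$bii_frequency[-4] == 0))

  # single-model BII structure
  expect_equal(bii_frequency(sb, "A", step = 4), 1.0)
})

test_that("exactly one step turns BII when injected 3' of one position", {
  s <- build_torsion_exact(oxog4_seq, bii_at = 4)
  calls <- step_calls(s, "A", 1)
  expect_identical(calls$step[calls$state == "BII"], 4L)
  expect_true(all(calls$state[calls$step != 4] == "BI"))
})
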