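test_that("superposition recovers rigid motions and matches the quaternion oracle", {
  set.seed(13)
  A <- matrix(rnorm(60), 20, 3)
  sp <- superpose(A, A)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$R, diag(3), tolerance = 1e-8)

  R <- random_rotation()
  t0 <- c(4, -2, 7)
  B <- sweep(A %*% t(R), 2, t0, "+")
  sp2 <- superpose(A, B)
  expect_equal(sp2$rmsd, 0, tolerance = 1e-8)
  expect_equal(sp2$R, R, tolerance = 1e-8)
  expect_equal(sp2$t, t0, tolerance = 1e-8)

  for (k in 1:100) {
    A <- matrix(rnorm(45), 15, 3)
    B <- sweep(A %*% t(random_rotation()), 2, rnorm(3), "+") +
      matrix(rnorm(45, 0, 0.3), 15, 3)
    expect_equal(superpose(A, B)$rmsd, oracle_superpose_rmsd(A, B),
                 tolerance = 1e-6)
  }

  # second independent route: bio3d's fitted rmsd
  set.seed(71)
  A <- matrix(rnorm(60), 20, 3)
  B <- sweep(A %*% t(random_rotation()), 2, rnorm(3), "+") +
    matrix(rnorm(60, 0, 0.4), 20, 3)
  b3 <- bio3d::rmsd(as.numeric(t(A)), as.numeric(t(B)), fit = TRUE)
  expect_equal(superpose(A, B)$rmsd, as.numeric(b3), tolerance = 1e-3)
})

test_that("structure selections drive correspondence and errors", {
  s <- build_torsion_exact(ddd_seq)
  es <- make_ensemble(s, 0.2, 2, seed = 3)
  sp <- superpose(es, es, selection = "backbone", model_a = 1, model_b = 2)
  expect_gt(sp$rmsd, 0)
  expect_lt(sp$rmsd, 1)
  # hydrogens are excluded from all-heavy
  expect_lt(superpose(es, es, "all-heavy")$n_atoms,
            superpose(es, es, "all")$n_atoms)
  s2 <- build_helix("CGCG")$structure
  expect_error(superpose(s, s2), "correspondence error")
})

test_that("rmsd behaves as a metric on the rigid-motion quotient", {
  s <- build_torsion_exact(ddd_seq)
  es <- make_ensemble(s, 0.15, 4, seed = 17)
  pr <- pairwise_rmsd(es, "all")
  expect_equal(pr$rmsd, t(pr$rmsd))
  expect_true(all(diag(pr$rmsd) == 0))
  # triangle inequality on all triples
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    expect_lte(pr$rmsd[i, j], pr$rmsd[i, k] + pr$rmsd[k, j] + 1e-9)
  # congruent selections give zero
  x <- es$xyz[[1]]
  moved <- dna_structure(es$atoms, sweep(x %*% t(random_rotation()), 2,
                                         c(1, 2, 3), "+"))
  two <- bind_models(dna_structure(es$atoms, x), moved)
  expect_lt(pairwise_rmsd(two, "all")$max, 1e-8)

  # invariance under a common rigid motion
  R <- random_rotation()
  es2 <- dna_structure(es$atoms, lapply(es$xyz, function(m)
    sweep(m %*% t(R), 2, c(5, 5, 5), "+")))
  pr2 <- pairwise_rmsd(es2, "all")
  expect_equal(pr2$rmsd, pr$rmsd, tolerance = 1e-8)
})

test_that("jittered ensembles have the expected rmsd scale", {
  s <- build_torsion_exact(ddd_seq)
  sigma <- 0.1
  es <- make_ensemble(s, sigma, 20, seed = 29)
  pr <- pairwise_rmsd(es, "all")
  # independent jitter of sd sigma per coordinate on both models: the
  # per-atom rmsd concentrates near sigma * sqrt(6) (2 sigma^2 per
  # coordinate, 3 coordinates per atom), slightly below after the refit
  expect_lt(abs(pr$mean - sigma * sqrt(6)), 0.1 * sigma * sqrt(6))
  expect_equal(pairwise_rmsd(make_ensemble(s, 0, 2, seed = 1), "all")$max, 0)
})

test_that("representative selection averages or picks the medoid", {
  s <- build_torsion_exact(ddd_seq)
  x <- s$xyz[[1]]
  # two mirror-jittered models: the mean is the midpoint geometry
  set.seed(37)
  d <- matrix(rnorm(length(x), 0, 0.1), nrow(x), 3)
  two <- bind_models(dna_structure(s$atoms, x + d),
                     dna_structure(s$atoms, x - d))
  mc <- representative(two, "mean-coordinates", "all")
  expect_lt(superpose(mc$xyz[[1]], x)$rmsd, 0.02)

  # the medoid is never a gross outlier
  es <- make_ensemble(s, 0.1, 9, seed = 41)
  far <- dna_structure(s$atoms,
                       x + matrix(rnorm(length(x), 0, 1.5), nrow(x), 3))
  with_outlier <- bind_models(es, far)
  med <- representative(with_outlier, "medoid", "all")
  expect_lt(attr(med, "model"), 10)

  # single model: itself under both modes
  one <- dna_structure(s$atoms, x)
  expect_equal(representative(one, "medoid")$xyz[[1]], x)
  expect_equal(representative(one, "mean-coordinates")$xyz[[1]], x)
})
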