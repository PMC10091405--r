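# Global shape descriptors and their summaries.

two_atom_ens <- function(xyz, masses = c(12.011, 12.011)) {
  top <- data.frame(name = c("C1", "C4"), element = "C", mass = masses,
                    residue_index = 1L, residue_name = "PYR",
                    residue_seq = 1L)
  conformer_ensemble(top, xyz)
}

test_that("end-to-end distance is plain euclidean distance per frame", {
  ens <- two_atom_ens(matrix(c(0, 0, 0, 3, 4, 0), 2L, 3L, byrow = TRUE))
  expect_equal(end_to_end_distance(ens, c(1L, 2L))$values, 5)
  same <- two_atom_ens(matrix(c(1, 2, 3, 1, 2, 3), 2L, 3L, byrow = TRUE))
  expect_equal(end_to_end_distance(same, c(1L, 2L))$values, 0)
  expect_error(end_to_end_distance(ens, c(2L, 2L)), "distinct")
})

test_that("radius of gyration matches hand-computed cases", {
  # equal masses at (+-1, 0, 0) -> 1
  e1 <- two_atom_ens(matrix(c(-1, 0, 0, 1, 0, 0), 2L, 3L, byrow = TRUE))
  expect_equal(radius_of_gyration(e1)$values, 1)
  # four equal masses at (+-1, +-1, 0) -> sqrt(2)
  top4 <- data.frame(name = paste0("C", 1:4), element = "C", mass = 12,
                     residue_index = 1L, residue_name = "PYR",
                     residue_seq = 1L)
  e4 <- conformer_ensemble(top4, matrix(c(1, 1, 0, 1, -1, 0, -1, 1, 0,
                                          -1, -1, 0), 4L, 3L, byrow = TRUE))
  expect_equal(radius_of_gyration(e4)$values, sqrt(2))
  # masses 1 and 3 at x = 0 and 4: centroid x = 3, Rg = sqrt(3)
  ew <- two_atom_ens(matrix(c(0, 0, 0, 4, 0, 0), 2L, 3L, byrow = TRUE),
                     masses = c(1, 3))
  expect_equal(radius_of_gyration(ew)$values, sqrt(3))
  # unweighted flag ignores masses
  expect_equal(radius_of_gyration(ew, mass_weighted = FALSE)$values, 2)
})

test_that("summaries use population SD and replicate aggregation follows", {
  s <- function(v) new_descriptor_series_for_test(v)
  expect_equal(unclass(summarize_series(s(c(2, 2, 2))))[c("mean", "sd")],
               list(mean = 2, sd = 0))
  expect_equal(summarize_series(s(c(1, 3)))$sd, 1)
  su <- summarize_series(s(c(0, 0, 0, 4)))
  expect_equal(su$mean, 1)
  expect_equal(su$sd, sqrt(3))

  runs <- lapply(c(8, 12), function(m) summarize_series(s(c(m, m))))
  agg <- aggregate_runs(runs)
  expect_equal(agg$mean, 10); expect_equal(agg$sd, 2); expect_equal(agg$n, 2L)
  runs5 <- lapply(1:5, function(m) summarize_series(s(rep(m, 3L))))
  agg5 <- aggregate_runs(runs5)
  expect_equal(agg5$mean, 3); expect_equal(agg5$sd, sqrt(2))
  ident <- aggregate_runs(lapply(1:5, function(i) summarize_series(s(c(10)))))
  expect_equal(ident$sd, 0)
  expect_error(aggregate_runs(list()), "no summaries")
})

test_that("all four descriptors are invariant under global rigid motion", {
  ens <- generate_arc_chain(n_units = 6L, noise_sigma = 0.3, n_frames = 4L,
                            seed = 11L)
  R <- with_seed_for_test(99L, random_rotation_for_test())
  tr <- c(7, -3, 12)
  moved <- ens
  for (f in seq_len(n_frames(ens)))
    moved$coords[f, , ] <- sweep(frame_coords(ens, f) %*% R, 2L, tr, "+")
  rel <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-12))
  expect_lt(rel(end_to_end_distance(moved)$values,
                end_to_end_distance(ens)$values), 1e-9)
  expect_lt(rel(radius_of_gyration(moved)$values,
                radius_of_gyration(ens)$values), 1e-9)
  expect_lt(max(abs(rmsd_series(moved)$values - rmsd_series(ens)$values)),
            1e-6)
  f_a <- atomic_fluctuations(ens)$rmsf
  f_b <- atomic_fluctuations(moved)$rmsf
  expect_lt(max(abs(f_a - f_b)), 1e-6)
  # geometric bounds: EED and Rg never exceed the max pairwise distance
  d <- as.matrix(stats::dist(frame_coords(ens, 1L)))
  expect_lte(end_to_end_distance(ens)$values[1L], max(d))
  expect_lte(radius_of_gyration(ens)$values[1L], max(d))
})

test_that("rmsd series is zero for rigid copies and grows with arc curvature", {
  base <- generate_arc_chain(n_units = 8L, seed = 5L)
  ref <- frame_coords(base, 1L)
  nf <- 5L
  coords <- array(NA_real_, dim = c(nf, nrow(ref), 3L))
  with_seed_for_test(42L, {
    for (f in seq_len(nf)) {
      R <- random_rotation_for_test()
      coords[f, , ] <- sweep(ref %*% R, 2L, stats::rnorm(3L, sd = 10), "+")
    }
  })
  rigid <- conformer_ensemble(base$topology, coords)
  expect_lt(max(rmsd_series(rigid, reference = ref)$values), 1e-6)

  single <- conformer_ensemble(base$topology, ref)
  expect_equal(rmsd_series(single, reference = ref)$values, 0,
               tolerance = 1e-9)

  rms_at <- vapply(c(30, 90, 180), function(th) {
    arc <- generate_arc_chain(n_units = 8L, turn_angle = th, seed = 5L)
    kabsch_superpose(frame_coords(arc, 1L), ref)$rmsd
  }, numeric(1L))
  expect_true(all(rms_at > 0))
  expect_true(all(diff(rms_at) > 0))
})

test_that("atomic fluctuations recover planted per-atom amplitudes", {
  # identical frames -> all zero
  still <- generate_arc_chain(n_units = 5L, n_frames = 3L, seed = 1L)
  expect_lt(max(atomic_fluctuations(still)$rmsf), 1e-9)
  expect_error(atomic_fluctuations(generate_arc_chain(n_units = 5L)),
               "single frame")

  # one atom alternating +-d along x among 20 anchored atoms -> RMSF ~ d
  n_at <- 21L; d <- 0.4; nf <- 200L
  base <- with_seed_for_test(3L, random_points(n_at, scale = 4))
  top <- data.frame(name = paste0("C", seq_len(n_at)), element = "C",
                    mass = 12, residue_index = 1L, residue_name = "PYR",
                    residue_seq = 1L)
  cc <- array(rep(base, each = nf), dim = c(nf, n_at, 3L))
  cc[, n_at, 1L] <- cc[, n_at, 1L] + d * rep_len(c(1, -1), nf)
  fl <- atomic_fluctuations(conformer_ensemble(top, cc))
  # the fit removes the centroid, coupling 1/N of the motion into the rest
  expect_equal(fl$rmsf[n_at], d * (1 - 1 / n_at), tolerance = 0.02)
  expect_lt(max(fl$rmsf[-n_at]), 0.05)

  # isotropic jitter sigma on every atom -> RMSF ~ sigma * sqrt(3)
  sigma <- 0.1; n_big <- 60L; nf2 <- 2000L
  base2 <- with_seed_for_test(4L, random_points(n_big, scale = 6))
  cc2 <- array(rep(base2, each = nf2), dim = c(nf2, n_big, 3L))
  cc2 <- cc2 + with_seed_for_test(5L,
    array(stats::rnorm(length(cc2), sd = sigma), dim = dim(cc2)))
  fl2 <- atomic_fluctuations(conformer_ensemble(
    data.frame(name = paste0("C", seq_len(n_big)), element = "C", mass = 12,
               residue_index = 1L, residue_name = "PYR", residue_seq = 1L),
    cc2))
  expect_equal(fl2$summary$mean, sigma * sqrt(3), tolerance = 0.05)
})
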