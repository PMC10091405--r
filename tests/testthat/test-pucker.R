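# Torsion geometry, Cremer-Pople round trips, and pucker classification.

test_that("dihedral angle follows the sign convention on planar anchors", {
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, -1, 0)), 180)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), 0)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 0, 1)), 90)
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), "collinear")
})

ring_idx <- list(o5 = 1L, c1 = 2L, c2 = 3L, c3 = 4L, c4 = 5L, c5 = 6L)

test_that("canonical Cremer-Pople vertices classify to their named states", {
  r4c1 <- gagshape:::ring_template(0.57, 0, 0)
  t1 <- pucker_torsions(r4c1, ring_idx)
  expect_lt(t1[["tau1"]], -20); expect_gt(t1[["tau2"]], 20)
  expect_equal(classify_pucker(t1[1L], t1[2L]), "4C1")

  r1c4 <- gagshape:::ring_template(0.57, 180, 0)
  t2 <- pucker_torsions(r1c4, ring_idx)
  # chair inversion flips both torsion signs
  expect_equal(unname(t2), -unname(t1), tolerance = 1e-9)
  expect_equal(classify_pucker(t2[1L], t2[2L]), "1C4")

  r2so <- gagshape:::ring_template(0.63, 90, 150)
  t3 <- pucker_torsions(r2so, ring_idx)
  expect_equal(classify_pucker(t3[1L], t3[2L]), "2SO")
  # ... and C2 sits above the mean plane, O5 below (the 2SO signature)
  z <- cremer_pople(r2so)$z
  expect_gt(z[3L], 0.1); expect_lt(z[1L], -0.1)

  # the OS2 mirror skew and the planar hexagon are no canonical state
  ros2 <- gagshape:::ring_template(0.63, 90, 330)
  t4 <- pucker_torsions(ros2, ring_idx)
  expect_equal(classify_pucker(t4[1L], t4[2L]), "OTHER")
  flat <- gagshape:::ring_template(0, 0, 0)
  tf <- pucker_torsions(flat, ring_idx)
  expect_equal(unname(tf), c(0, 0), tolerance = 1e-9)
  expect_equal(classify_pucker(tf[1L], tf[2L]), "OTHER")
})

test_that("generated rings round-trip through Cremer-Pople analysis", {
  for (theta in c(5, 30, 60, 90, 120, 150, 175)) {
    for (phi in c(0, 45, 150, 290)) {
      ring <- gagshape:::ring_template(0.57, theta, phi)
      cp <- cremer_pople(ring)
      expect_equal(cp$Q, 0.57, tolerance = 0.01)
      expect_equal(cp$theta, theta, tolerance = 1)
      if (theta > 5 && theta < 175)
        expect_lt(min(abs(cp$phi - phi), 360 - abs(cp$phi - phi)), 1)
    }
  }
  # generate_ring exposes the same geometry through the ensemble interface
  ens <- generate_ring(q = 0.57, theta = 180, n_frames = 2L, seed = 9L)
  tt <- pucker_torsions(frame_coords(ens, 1L), ring_idx)
  expect_equal(classify_pucker(tt[1L], tt[2L]), "1C4")
})

test_that("classification is invariant under rigid motion", {
  ens <- generate_ring(theta = 90, phi = 150, n_frames = 1L)
  fr <- frame_coords(ens, 1L)
  R <- with_seed_for_test(20L, random_rotation_for_test())
  moved <- sweep(fr %*% R, 2L, c(4, 4, -2), "+")
  t_a <- pucker_torsions(fr, ring_idx)
  t_b <- pucker_torsions(moved, ring_idx)
  expect_equal(t_a, t_b, tolerance = 1e-9)
})

test_that("noisy canonical rings classify correctly at least 99% of the time", {
  for (spec in list(c(0, 0, "4C1"), c(180, 0, "1C4"), c(90, 150, "2SO"))) {
    ens <- generate_ring(theta = as.numeric(spec[1L]),
                         phi = as.numeric(spec[2L]),
                         noise_sigma = 0.05, n_frames = 2000L, seed = 31L)
    occ <- pucker_occupancy(ens)
    expect_gte(occ[[paste0("frac_", spec[3L])]], 0.99)
  }
})

test_that("planted pucker mixtures are recovered as occupancy fractions", {
  # 70/30 alternation, constructed frame labels: fractions exact
  a <- generate_ring(theta = 0, n_frames = 1L)
  b <- generate_ring(theta = 180, n_frames = 1L)
  cc <- array(NA_real_, dim = c(1000L, 6L, 3L))
  for (f in 1:700) cc[f, , ] <- frame_coords(a, 1L)
  for (f in 701:1000) cc[f, , ] <- frame_coords(b, 1L)
  ens <- conformer_ensemble(a$topology, cc)
  occ <- pucker_occupancy(ens)
  expect_equal(occ$frac_4C1, 0.7)
  expect_equal(occ$frac_1C4, 0.3)
  expect_equal(occ$frac_4C1 + occ$frac_1C4 + occ$frac_2SO + occ$frac_other, 1)

  # same mixture with coordinate jitter: within +-0.02
  cc2 <- cc + with_seed_for_test(8L,
    array(stats::rnorm(length(cc), sd = 0.05), dim = dim(cc)))
  occ2 <- pucker_occupancy(conformer_ensemble(a$topology, cc2))
  expect_equal(occ2$frac_4C1, 0.7, tolerance = 0.02)
  expect_equal(occ2$frac_1C4, 0.3, tolerance = 0.03)
})

test_that("occupancy fractions always sum to one per ring", {
  ens <- generate_arc_chain(n_units = 4L, noise_sigma = 0.4, n_frames = 25L,
                            seed = 77L)
  occ <- pucker_occupancy(ens)
  expect_equal(occ$frac_4C1 + occ$frac_1C4 + occ$frac_2SO + occ$frac_other,
               rep(1, nrow(occ)))
})
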