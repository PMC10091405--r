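# Synthetic generators: determinism, closed-form geometry, planted truth.

test_that("generators are bit-reproducible from their seed", {
  a <- generate_arc_chain(n_units = 6L, noise_sigma = 0.2, n_frames = 4L,
                          seed = 42L)
  b <- generate_arc_chain(n_units = 6L, noise_sigma = 0.2, n_frames = 4L,
                          seed = 42L)
  expect_identical(a$coords, b$coords)
  c_ <- generate_arc_chain(n_units = 6L, noise_sigma = 0.2, n_frames = 4L,
                           seed = 43L)
  expect_false(identical(a$coords, c_$coords))

  d1 <- generate_dihedral_samples(
    data.frame(mu_phi = -80, mu_psi = 100, kappa = 10, weight = 1),
    500L, seed = 7L)
  d2 <- generate_dihedral_samples(
    data.frame(mu_phi = -80, mu_psi = 100, kappa = 10, weight = 1),
    500L, seed = 7L)
  expect_identical(d1, d2)

  # the caller's RNG stream is untouched
  set.seed(1); before <- .Random.seed
  invisible(generate_ring(noise_sigma = 0.1, n_frames = 2L, seed = 99L))
  expect_identical(.Random.seed, before)
})

test_that("arc-chain end-to-end distance follows the chord closed form", {
  ext <- generate_arc_chain(n_units = 10L, spacing = 5, turn_angle = 0)
  expect_equal(end_to_end_distance(ext)$values, 45)

  L <- 9 * 5
  u <- generate_arc_chain(n_units = 10L, spacing = 5, turn_angle = 180)
  expect_equal(end_to_end_distance(u)$values, 2 * L / pi, tolerance = 1e-9)

  th <- 330 * pi / 180
  o <- generate_arc_chain(n_units = 10L, spacing = 5, turn_angle = 330)
  chord <- 2 * (L / th) * sin(th / 2)
  expect_equal(end_to_end_distance(o)$values, chord, tolerance = 1e-9)
  expect_lt(end_to_end_distance(o)$values,
            0.5 * end_to_end_distance(u)$values)

  # monotone decrease of EED with turn angle (the shape taxonomy ordering)
  eeds <- vapply(c(0, 90, 180, 330), function(t)
    end_to_end_distance(generate_arc_chain(turn_angle = t))$values,
    numeric(1L))
  expect_true(all(diff(eeds) < 0))

  expect_error(generate_arc_chain(n_units = 1L), "invalid")
  expect_error(generate_arc_chain(turn_angle = 400), "invalid")
})

test_that("von Mises sampling concentrates and mixes as specified", {
  tight <- generate_dihedral_samples(
    data.frame(mu_phi = -80, mu_psi = 100, kappa = 1e4, weight = 1),
    5000L, seed = 3L)
  expect_lt(circular_sd(tight$phi), 2)
  expect_lt(circular_sd(tight$psi), 2)
  expect_lt(abs(circular_mean(tight$phi) - -80), 0.2)
  expect_lt(abs(circular_mean(tight$psi) - 100), 0.2)

  one_mode <- generate_dihedral_samples(
    data.frame(mu_phi = c(-80, 60), mu_psi = c(100, -50), kappa = 10,
               weight = c(1, 0)), 200L, seed = 4L)
  expect_true(all(one_mode$mode == 1L))

  equal <- generate_dihedral_samples(
    data.frame(mu_phi = c(-80, 60), mu_psi = c(100, -50), kappa = 100,
               weight = c(0.5, 0.5)), 1e4, seed = 5L)
  expect_equal(mean(equal$mode == 1L), 0.5, tolerance = 0.02)

  expect_error(generate_dihedral_samples(
    data.frame(mu_phi = 0, mu_psi = 0, kappa = -1, weight = 1), 10L),
    "kappa")
})

test_that("ring generator honors its spec and degenerate amplitude", {
  ens <- generate_ring(q = 0, n_frames = 1L)
  tt <- pucker_torsions(frame_coords(ens, 1L),
                        list(o5 = 1L, c1 = 2L, c2 = 3L, c3 = 4L, c4 = 5L,
                             c5 = 6L))
  expect_equal(classify_pucker(tt[1L], tt[2L]), "OTHER")
  expect_error(generate_ring(theta = 200), "invalid")
})

test_that("hbond toggle spec validation and extremes", {
  expect_error(generate_hbond_toggle(1.2), "occupancy")
  ens <- generate_hbond_toggle(0.4, n_frames = 100L, seed = 8L)
  expect_equal(n_frames(ens), 100L)
  expect_equal(mean(attr(ens, "planted_frames")), 0.4, tolerance = 0.15)
})

test_that("the synthetic heparin helix has the documented architecture", {
  hp <- synthetic_heparin_dp12()
  expect_equal(n_frames(hp), 2L)
  expect_equal(n_residues(hp), 12L)
  expect_equal(unique(hp$topology$residue_name[hp$topology$residue_index %% 2L == 1L]),
               "IDS")
  rings <- identify_rings(hp$topology)
  expect_equal(nrow(rings), 12L)

  # frame 2 carries 1C4 iduronates, frame 1 the 2SO variant
  occ1 <- pucker_occupancy(conformer_ensemble(hp$topology,
                                              frame_coords(hp, 1L)))
  occ2 <- pucker_occupancy(conformer_ensemble(hp$topology,
                                              frame_coords(hp, 2L)))
  ido <- occ1$residue_name == "IDS"
  expect_true(all(occ1$frac_2SO[ido] == 1))
  expect_true(all(occ2$frac_1C4[ido] == 1))
  expect_true(all(occ2$frac_4C1[!ido] == 1))

  # dp10 construction picks the 1C4 model and keeps 10 residues
  dp10 <- build_dp10(hp)
  expect_equal(n_residues(dp10), 10L)
  expect_equal(dp10$frame_labels, "model_1C4")
  # nonreducing end kept: residue 1 is an iduronate
  expect_equal(dp10$topology$residue_name[1L], "IDS")
})
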