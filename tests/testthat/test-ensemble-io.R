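# Ensemble I/O, atom selection, chain windows, ring and linkage detection.

mini_model <- function(shift = 0) {
  list(name = c("C1", "O5", "C2", "N2", "H1"),
       element = c("C", "O", "C", "N", "H"),
       resid = rep("SGN", 5L), resno = rep(1L, 5L),
       xyz = matrix(c(0, 0, 0, 1.4, 0, 0, 2.1, 1.2, 0, 3.5, 1.2, 0.5,
                      -0.5, 0.9, 0.3), 5L, 3L, byrow = TRUE) + shift)
}

test_that("single- and multi-model PDB files map to frames", {
  f1 <- tempfile(fileext = ".pdb")
  write_mini_pdb(f1, list(mini_model()))
  ens <- read_structure(f1)
  expect_equal(n_frames(ens), 1L)
  expect_equal(n_atoms(ens), 5L)
  expect_equal(ens$topology$element, c("C", "O", "C", "N", "H"))
  expect_true(all(ens$topology$mass > 0))

  f2 <- tempfile(fileext = ".pdb")
  write_mini_pdb(f2, list(mini_model(), mini_model(0.25)))
  ens2 <- read_structure(f2)
  expect_equal(n_frames(ens2), 2L)
  expect_equal(frame_coords(ens2, 2L) - frame_coords(ens2, 1L),
               matrix(0.25, 5L, 3L), tolerance = 1e-9)
})

test_that("unequal atom counts across models raise a format error naming the model", {
  f <- tempfile(fileext = ".pdb")
  bad <- mini_model()
  bad$name <- bad$name[1:4]; bad$element <- bad$element[1:4]
  bad$resid <- bad$resid[1:4]; bad$resno <- bad$resno[1:4]
  bad$xyz <- bad$xyz[1:4, ]
  write_mini_pdb(f, list(mini_model(), bad))
  expect_error(read_structure(f), "model 2")
})

test_that("PDB and XYZ round trips preserve coordinates to field precision", {
  ens <- generate_arc_chain(n_units = 4L, noise_sigma = 0.1, n_frames = 3L,
                            seed = 7L)
  fp <- tempfile(fileext = ".pdb")
  write_ensemble(ens, fp)
  back <- read_structure(fp)
  expect_equal(n_frames(back), 3L)
  expect_equal(back$topology$name, ens$topology$name)
  expect_lt(max(abs(back$coords - ens$coords)), 1e-3 + 1e-9)

  fx <- tempfile(fileext = ".xyz")
  write_ensemble(ens, fx)
  backx <- read_structure(fx)
  expect_equal(n_frames(backx), 3L)
  expect_lt(max(abs(backx$coords - ens$coords)), 1e-6)
})

test_that("select_atoms filters by name, element and residue", {
  ens <- generate_arc_chain(n_units = 10L, seed = 1L)
  top <- ens$topology
  expect_length(select_atoms(top, name = "C1"), 10L)
  expect_true(all(diff(select_atoms(top, name = "C1")) > 0))
  expect_equal(select_atoms(top, residue_index = 1L),
               which(top$residue_index == 1L))
  n_h <- sum(top$element == "H")
  expect_length(heavy_atoms <- select_atoms(
    top, predicate = function(t) t$element != "H"), nrow(top) - n_h)
  expect_error(select_atoms(top, name = "XX"), "empty")
  expect_length(select_atoms(top, name = "XX", allow_empty = TRUE), 0L)
})

test_that("extract_chain_window slices residues and matches a manual slice", {
  ens <- synthetic_heparin_dp12()
  expect_equal(n_residues(ens), 12L)
  w <- extract_chain_window(ens, 1L, 10L)
  expect_equal(n_residues(w), 10L)
  w2 <- extract_chain_window(ens, 3L, 10L)
  expect_equal(n_residues(w2), 10L)
  # window 3..12 must equal the manual coordinate slice
  idx <- which(ens$topology$residue_index %in% 3:12)
  expect_equal(w2$coords, ens$coords[, idx, , drop = FALSE])
  expect_equal(sort(unique(w2$topology$residue_index)), 1:10)
  # descriptor on the window equals descriptor on manually sliced coords
  manual <- conformer_ensemble(
    transform(ens$topology[idx, ],
              residue_index = residue_index - 2L),
    ens$coords[, idx, , drop = FALSE])
  expect_equal(radius_of_gyration(w2)$values,
               radius_of_gyration(manual)$values, tolerance = 1e-12)
  # identity window is a copy
  expect_equal(extract_chain_window(ens, 1L, 12L)$coords, ens$coords)
  expect_error(extract_chain_window(ens, 4L, 10L), "exceeds")
})

test_that("ring identification finds pyranose name patterns and skips others", {
  ens <- generate_arc_chain(n_units = 10L, seed = 2L)
  rings <- identify_rings(ens$topology)
  expect_equal(nrow(rings), 10L)
  expect_equal(rings$terminal, c(TRUE, rep(FALSE, 8L), TRUE))
  # drop O5 from residue 4: that residue disappears with a warning
  top <- ens$topology
  drop <- which(top$residue_index == 4L & top$name == "O5")
  expect_warning(r2 <- identify_rings(top[-drop, ]), "O5")
  expect_equal(nrow(r2), 9L)
  expect_false(4L %in% r2$residue_index)
  # topology without any ring names -> empty
  plain <- data.frame(name = c("X1", "X2"), element = "C", mass = 12,
                      residue_index = 1L, residue_name = "XXX",
                      residue_seq = 1L)
  expect_equal(nrow(suppressWarnings(identify_rings(plain))), 0L)
})

test_that("linkage identification yields n-1 specs with ordered type counts", {
  ens10 <- generate_arc_chain(n_units = 10L, seed = 3L)
  lk <- identify_glycosidic_linkages(ens10$topology)
  expect_equal(nrow(lk), 9L)
  # alternating ARA/ARB copolymer: ordered types split 5/4
  tc <- table(lk$linkage_type)
  expect_equal(sort(as.integer(tc)), c(4L, 5L))
  expect_lte(abs(diff(as.integer(tc))), 1L)
  # dp2 -> a single linkage; phi/psi share the central atom triple
  ens2 <- generate_arc_chain(n_units = 2L, seed = 3L)
  lk2 <- identify_glycosidic_linkages(ens2$topology)
  expect_equal(nrow(lk2), 1L)
  expect_equal(unlist(lk2[, c("phi2", "phi3", "phi4")], use.names = FALSE),
               unlist(lk2[, c("psi1", "psi2", "psi3")], use.names = FALSE))
  # aliasing maps codes to display names
  hp <- synthetic_heparin_dp12()
  lkh <- identify_glycosidic_linkages(hp$topology, heparin_aliases())
  expect_equal(nrow(lkh), 11L)
  expect_setequal(unique(lkh$linkage_type),
                  c("GlcNS6S->IdoA2S", "IdoA2S->GlcNS6S"))
})
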