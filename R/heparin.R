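# Synthetic heparin helix: an idealized, atomically decorated dp12 model of
# the heparin NMR fiber geometry, used as an offline stand-in for the
# experimental dodecasaccharide entry.  Built once from published structural
# knowledge -- two-fold helix symmetry with ~8.4 Angstrom rise per
# disaccharide, 4C1 GlcNS6S and 1C4 (or 2SO) IdoA2S rings, standard bond
# lengths -- not fitted to any target descriptor value.

.bond <- list(CH = 1.09, CO = 1.43, CN = 1.47, CC = 1.52, OS = 1.60,
              NS = 1.65, SO = 1.45, CO2 = 1.25, OH = 0.97)

#' Residue-code aliases for heparin
#'
#' Maps the PDB chemical-component codes used by the synthetic heparin
#' builder to the display names conventional in the glycosaminoglycan
#' literature.
#'
#' @return named character vector suitable for the `aliases` argument of
#'   [identify_glycosidic_linkages()].
#' @export
heparin_aliases <- function() c(SGN = "GlcNS6S", IDS = "IdoA2S")

# the two exocyclic substituent directions at ring atom i, split into the
# axial (largest |projection on ring normal|) and equatorial slot
exocyclic_dirs <- function(X, i, nb1, nb2, normal) {
  u1 <- unit(X[nb1, ] - X[i, ]); u2 <- unit(X[nb2, ] - X[i, ])
  bi <- -unit(u1 + u2)
  p <- unit(cross3(u1, u2))
  a <- 54.75 * pi / 180
  d1 <- unit(cos(a) * bi + sin(a) * p)
  d2 <- unit(cos(a) * bi - sin(a) * p)
  if (abs(sum(d1 * normal)) >= abs(sum(d2 * normal)))
    list(ax = d1, eq = d2) else list(ax = d2, eq = d1)
}

# terminal sulfate oxygens around S, given the bridge-atom -> S direction
sulfate_oxygens <- function(s_pos, dir_in) {
  e1 <- unit(dir_in)
  ref <- if (abs(e1[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- unit(cross3(e1, ref)); e3 <- cross3(e1, e2)
  a <- 70.53 * pi / 180
  t(vapply(0:2, function(k) {
    d <- cos(a) * e1 + sin(a) * (cos(2 * pi * k / 3) * e2 +
                                 sin(2 * pi * k / 3) * e3)
    s_pos + .bond$SO * d
  }, numeric(3L)))
}

# Build one residue of the helix in its local frame: ring centroid at the
# origin, C1 -> C4 along +z, ring normal along +x.  Returns name/element/xyz.
heparin_residue <- function(type = c("SGN", "IDS"), ido_theta = 180,
                            ido_phi = 150) {
  type <- match.arg(type)
  ring <- if (type == "SGN") ring_template(0.57, 0, 0)
          else ring_template(0.57, ido_theta, ido_phi)
  # orient: C1 -> C4 along z, normal along x (ring order O5,C1,C2,C3,C4,C5)
  nrm <- unit(cross3(ring[3L, ] - ring[1L, ], ring[5L, ] - ring[1L, ]))
  e3 <- unit(ring[5L, ] - ring[2L, ])
  e1 <- unit(nrm - sum(nrm * e3) * e3)
  e2 <- cross3(e3, e1)
  B <- cbind(e1, e2, e3)
  X <- sweep(ring, 2L, colMeans(ring)) %*% B
  nrm_l <- drop(unit(cross3(X[3L, ] - X[1L, ], X[5L, ] - X[1L, ])))
  names <- c("O5", "C1", "C2", "C3", "C4", "C5")
  elements <- c("O", "C", "C", "C", "C", "C")
  xyz <- X
  add <- function(name, element, pos) {
    names <<- c(names, name); elements <<- c(elements, element)
    xyz <<- rbind(xyz, pos)
  }
  # ring neighbor table in template row order O5(1) C1(2) .. C5(6)
  nbr <- list(c(2L, 6L), c(1L, 3L), c(2L, 4L), c(3L, 5L), c(4L, 6L),
              c(5L, 1L))
  slot <- function(i) exocyclic_dirs(X, i, nbr[[i]][1L], nbr[[i]][2L], nrm_l)
  # C1: equatorial H; the axial slot points to the previous residue's O4
  s1 <- slot(2L); add("H1", "H", X[2L, ] + .bond$CH * s1$eq)
  # C3: hydroxyl (equatorial), H axial
  s3 <- slot(4L)
  o3 <- X[4L, ] + .bond$CO * s3$eq
  add("O3", "O", o3); add("H3", "H", X[4L, ] + .bond$CH * s3$ax)
  add("HO3", "H", o3 + .bond$OH * unit(unit(o3 - X[4L, ]) + 0.4 * nrm_l))
  # C4: glycosidic oxygen (equatorial), H axial
  s4 <- slot(5L)
  add("O4", "O", X[5L, ] + .bond$CO * s4$eq)
  add("H4", "H", X[5L, ] + .bond$CH * s4$ax)
  s2 <- slot(3L); s5 <- slot(6L)
  if (type == "SGN") {
    # C2: N-sulfate (equatorial)
    n2 <- X[3L, ] + .bond$CN * s2$eq
    add("N2", "N", n2); add("H2", "H", X[3L, ] + .bond$CH * s2$ax)
    sn <- n2 + .bond$NS * unit(n2 - X[3L, ])
    add("HN2", "H", n2 + 1.01 * unit(unit(n2 - X[3L, ]) + 1.2 * nrm_l))
    add("SN", "S", sn)
    os <- sulfate_oxygens(sn, sn - n2)
    add("O1S", "O", os[1L, ]); add("O2S", "O", os[2L, ])
    add("O3S", "O", os[3L, ])
    # C5: C6-O6-sulfate arm (equatorial)
    c6 <- X[6L, ] + .bond$CC * s5$eq
    add("C6", "C", c6); add("H5", "H", X[6L, ] + .bond$CH * s5$ax)
    o6 <- c6 + .bond$CO * unit(unit(c6 - X[6L, ]) + 0.6 * nrm_l)
    add("O6", "O", o6)
    h6 <- exocyclic_dirs(rbind(X[6L, ], c6, o6), 2L, 1L, 3L, nrm_l)
    add("H61", "H", c6 + .bond$CH * h6$ax)
    add("H62", "H", c6 + .bond$CH * h6$eq)
    s6 <- o6 + .bond$OS * unit(o6 - c6)
    add("S6", "S", s6)
    os6 <- sulfate_oxygens(s6, s6 - o6)
    add("O61", "O", os6[1L, ]); add("O62", "O", os6[2L, ])
    add("O63", "O", os6[3L, ])
  } else {
    # C2: 2-O-sulfate (equatorial)
    o2 <- X[3L, ] + .bond$CO * s2$eq
    add("O2", "O", o2); add("H2", "H", X[3L, ] + .bond$CH * s2$ax)
    s2s <- o2 + .bond$OS * unit(o2 - X[3L, ])
    add("S2", "S", s2s)
    os <- sulfate_oxygens(s2s, s2s - o2)
    add("O1S", "O", os[1L, ]); add("O2S", "O", os[2L, ])
    add("O3S", "O", os[3L, ])
    # C5: carboxylate (equatorial)
    c6 <- X[6L, ] + .bond$CC * s5$eq
    add("C6", "C", c6); add("H5", "H", X[6L, ] + .bond$CH * s5$ax)
    out <- unit(c6 - X[6L, ])
    perp <- unit(cross3(out, nrm_l))
    add("O6A", "O", c6 + .bond$CO2 * unit(out + 1.1 * perp))
    add("O6B", "O", c6 + .bond$CO2 * unit(out - 1.1 * perp))
  }
  list(name = names, element = elements, xyz = xyz)
}

#' Synthetic heparin dodecasaccharide helix (two models)
#'
#' An idealized stand-in for the experimental heparin dodecasaccharide NMR
#' entry, for use where the real coordinates are not at hand: 12 alternating
#' IdoA2S/GlcNS6S residues (PDB component codes IDS/SGN, IdoA2S at the
#' nonreducing end) on a helix with `rise` Angstrom rise per residue and 90
#' degrees of twist per residue -- the two-fold screw relating successive
#' disaccharides (180 degrees and 8.4 Angstrom per disaccharide, two
#' disaccharides per full turn) -- with GlcNS6S rings in 4C1 throughout.  Two
#' frames mirror the two deposited NMR models: frame 1 carries the IdoA2S
#' rings in the 2SO skew-boat, frame 2 in the 1C4 chair.  Fully
#' deterministic.
#'
#' This is a synthetic model, not the deposited entry: substituent
#' placement is idealized (heavy substituents equatorial, hydrogens axial,
#' standard bond lengths) and the glycosidic geometry is implied by the
#' screw symmetry rather than refined against NMR restraints.
#'
#' @param n_units number of residues (default 12).
#' @param rise helix rise per residue in Angstrom (default 4.2, i.e. 8.4
#'   per disaccharide).
#' @return a 2-frame [conformer_ensemble()].
#' @export
synthetic_heparin_dp12 <- function(n_units = 12L, rise = 4.2) {
  build_model <- function(ido_theta, ido_phi) {
    xyz <- NULL; top <- NULL
    for (k in seq_len(n_units)) {
      type <- if (k %% 2L == 1L) "IDS" else "SGN"
      res <- heparin_residue(type, ido_theta, ido_phi)
      Rz <- rotation_about(c(0, 0, 1), 90 * (k - 1L))
      pos <- res$xyz %*% t(Rz)
      pos[, 3L] <- pos[, 3L] + rise * (k - 1L)
      xyz <- rbind(xyz, pos)
      top <- rbind(top, data.frame(
        name = res$name, element = res$element,
        mass = element_mass(res$element), residue_index = k,
        residue_name = type, residue_seq = k, stringsAsFactors = FALSE))
    }
    list(top = top, xyz = xyz)
  }
  m_2so <- build_model(90, 150)
  m_1c4 <- build_model(180, 150)
  coords <- array(NA_real_, dim = c(2L, nrow(m_2so$xyz), 3L))
  coords[1L, , ] <- m_2so$xyz
  coords[2L, , ] <- m_1c4$xyz
  conformer_ensemble(m_2so$top, coords,
                     frame_labels = c("model_2SO", "model_1C4"))
}

#' Build the dp10 analysis construct from a dodecasaccharide ensemble
#'
#' Reproduces the decasaccharide construction used for descriptor
#' comparison against the experimental entry: pick the model whose IdoA2S
#' rings are in the 1C4 chair (the conformation chosen for simulation
#' starting structures), then keep `n_units` residues counting from the
#' nonreducing end.  Both the model index and the window are overridable.
#'
#' @param ensemble a multi-model [conformer_ensemble()] (e.g. the
#'   experimental dodecasaccharide entry read with [read_structure()], or
#'   [synthetic_heparin_dp12()]).
#' @param n_units residues to keep (default 10).
#' @param start_residue first residue of the window, counting from the
#'   nonreducing end (default 1).
#' @param model frame index to use; `NULL` (default) picks the frame with
#'   the most rings classified 1C4.
#' @return a single-frame [conformer_ensemble()] of `n_units` residues.
#' @export
build_dp10 <- function(ensemble, n_units = 10L, start_residue = 1L,
                       model = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (is.null(model)) {
    rings <- identify_rings(ensemble$topology, warn = FALSE)
    if (!nrow(rings)) stop("no rings found; cannot auto-select model",
                           call. = FALSE)
    score <- vapply(seq_len(n_frames(ensemble)), function(f) {
      fr <- frame_coords(ensemble, f)
      labs <- vapply(seq_len(nrow(rings)), function(k) {
        tt <- pucker_torsions(fr, rings[k, ])
        classify_pucker(tt[1L], tt[2L])
      }, "")
      sum(labs == "1C4")
    }, numeric(1L))
    model <- which.max(score)
  }
  one <- conformer_ensemble(ensemble$topology,
                            frame_coords(ensemble, model),
                            ensemble$frame_labels[model])
  extract_chain_window(one, start_residue, n_units)
}
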