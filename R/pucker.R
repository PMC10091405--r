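# Pyranose ring puckering: Cremer-Pople coordinates, the two-torsion
# descriptor, and classification into the named states 4C1 / 1C4 / 2SO.
#
# Convention, stated once and used everywhere: ring atoms are ordered
# O5, C1, C2, C3, C4, C5; for D-pyranoses theta ~ 0 is the 4C1 chair and
# theta ~ 180 the 1C4 chair.  The 2SO skew-boat sits on the theta = 90
# equator at the pseudorotation phase where C2 lies above and O5 below the
# mean plane.

#' Cremer-Pople puckering coordinates of a six-membered ring
#'
#' @param ring_coords numeric 6 x 3 matrix, atoms ordered O5, C1..C5.
#' @return list with amplitude `Q` (Angstrom), `theta` (degrees, 0..180),
#'   `phi` (degrees, 0..360), the component amplitudes `q2`, `q3`, and the
#'   out-of-plane displacements `z`.
#' @export
cremer_pople <- function(ring_coords) {
  X <- as.matrix(ring_coords)
  if (nrow(X) != 6L || ncol(X) != 3L) stop("need a 6 x 3 matrix", call. = FALSE)
  Xc <- sweep(X, 2L, colMeans(X))
  j <- 0:5
  R1 <- colSums(Xc * sin(2 * pi * j / 6))
  R2 <- colSums(Xc * cos(2 * pi * j / 6))
  nrm <- cross3(R1, R2)
  if (vnorm(nrm) < 1e-10) stop("degenerate ring geometry", call. = FALSE)
  nrm <- unit(nrm)
  z <- drop(Xc %*% nrm)
  q2c <- sqrt(1 / 3) * sum(z * cos(4 * pi * j / 6))
  q2s <- -sqrt(1 / 3) * sum(z * sin(4 * pi * j / 6))
  q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
  q2 <- sqrt(q2c^2 + q2s^2)
  Q <- sqrt(q2^2 + q3^2)
  theta <- atan2(q2, q3) * 180 / pi
  phi <- (atan2(q2s, q2c) * 180 / pi) %% 360
  list(Q = Q, theta = theta, phi = phi, q2 = q2, q3 = q3, z = z)
}

#' Ring-pucker torsions
#'
#' The two dihedral angles carrying the chair/skew classification:
#' `tau1 = C1-C2-C3-C4` and `tau2 = C1-O5-C5-C4`.
#'
#' @param frame numeric `n_atoms x 3` coordinate matrix.
#' @param ring one row of [identify_rings()] output (or a list with fields
#'   `o5`, `c1` .. `c5`).
#' @return named numeric vector `c(tau1, tau2)` in degrees.
#' @export
pucker_torsions <- function(frame, ring) {
  g <- function(i) frame[i, ]
  c(tau1 = dihedral_angle(g(ring$c1), g(ring$c2), g(ring$c3), g(ring$c4)),
    tau2 = dihedral_angle(g(ring$c1), g(ring$o5), g(ring$c5), g(ring$c4)))
}

#' Default pucker classification windows
#'
#' Angular window (degrees) mapping the two ring torsions to the named
#' states, validated against the Cremer-Pople generator on ideal ring
#' geometries.  Ideal values of (tau1, tau2): 4C1 gives (-54, +54), 1C4
#' gives (+54, -54), the 2SO equator point (theta = 90, phi = 150, C2 above
#' / O5 below the mean plane) gives (-48, -48), and its mirror OS2 gives
#' (+48, +48) -- so the sign pattern of the pair separates the four cases
#' with ~30 degrees of margin to every window edge.
#'
#' @return named list with element `chair = c(lo, hi)`, the magnitude
#'   window applied to both torsions.
#' @export
pucker_windows <- function() {
  list(chair = c(20, 80))
}

#' Classify a ring conformation from its two torsions
#'
#' Deterministic sign-pattern rule on the magnitude window `(lo, hi)`
#' (default (20, 80)): `4C1` if `tau1 in (-hi, -lo)` and `tau2 in (lo, hi)`;
#' `1C4` for the opposite signs; `2SO` if both torsions fall in
#' `(-hi, -lo)`; everything else -- including the planar ring (0, 0), which
#' is no canonical state, and the OS2 mirror skew with both torsions
#' positive -- is `OTHER`.  Vectorized over tau1/tau2.
#'
#' @param tau1,tau2 torsions in degrees (see [pucker_torsions()]).
#' @param windows classification windows, see [pucker_windows()].
#' @return character vector with levels `"4C1"`, `"1C4"`, `"2SO"`, `"OTHER"`.
#' @export
classify_pucker <- function(tau1, tau2, windows = pucker_windows()) {
  lo <- windows$chair[1L]; hi <- windows$chair[2L]
  neg1 <- tau1 > -hi & tau1 < -lo; pos1 <- tau1 > lo & tau1 < hi
  neg2 <- tau2 > -hi & tau2 < -lo; pos2 <- tau2 > lo & tau2 < hi
  out <- rep("OTHER", length(tau1))
  out[neg1 & pos2] <- "4C1"
  out[pos1 & neg2] <- "1C4"
  out[neg1 & neg2] <- "2SO"
  out
}

#' Per-ring pucker state occupancies over an ensemble
#'
#' For every ring, the fraction of frames classified into each pucker state.
#' Terminal rings are flagged, never filtered: force fields are known to
#' disrupt ring conformation at chain termini and the artifact should stay
#' visible in reports.
#'
#' @param ensemble a [conformer_ensemble()].
#' @param rings rings table from [identify_rings()] (default: identified
#'   from the ensemble topology).
#' @param windows classification windows, see [pucker_windows()].
#' @return data.frame with columns `residue_index`, `residue_name`,
#'   `terminal`, `frac_4C1`, `frac_1C4`, `frac_2SO`, `frac_other`; fractions
#'   sum to 1 per ring.
#' @export
pucker_occupancy <- function(ensemble, rings = NULL,
                             windows = pucker_windows()) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  rings <- rings %||% identify_rings(ensemble$topology)
  if (!nrow(rings)) stop("no pyranose rings identified", call. = FALSE)
  rows <- lapply(seq_len(nrow(rings)), function(k) {
    r <- rings[k, ]
    tau1 <- dihedral_series_raw(ensemble, c(r$c1, r$c2, r$c3, r$c4))
    tau2 <- dihedral_series_raw(ensemble, c(r$c1, r$o5, r$c5, r$c4))
    lab <- classify_pucker(tau1, tau2, windows)
    nf <- length(lab)
    data.frame(residue_index = r$residue_index,
               residue_name = r$residue_name, terminal = r$terminal,
               frac_4C1 = sum(lab == "4C1") / nf,
               frac_1C4 = sum(lab == "1C4") / nf,
               frac_2SO = sum(lab == "2SO") / nf,
               frac_other = sum(lab == "OTHER") / nf,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export a pucker occupancy table as TSV
#'
#' @param occupancy output of [pucker_occupancy()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pucker_tsv <- function(occupancy, path) {
  utils::write.table(occupancy, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
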