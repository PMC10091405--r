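# Synthetic conformer-ensemble generators with known ground truth.
#
# Every generator draws all randomness from a single integer seed through a
# private RNG stream (the caller's .Random.seed is untouched), so identical
# spec + seed gives bit-identical ensembles.

# The decorated arc-chain unit motif, documented so expected descriptor
# values stay computable in closed form.  Local offsets (Angstrom) are
# relative to the unit anchor in the frame (tangent, in-plane normal,
# out-of-plane z).  The anchor atom is C1 -- except in the last unit, whose
# motif is mirrored so that C4 sits exactly on the terminal anchor (the
# reducing end terminates differently); the default end-to-end endpoints
# (C1 of the first unit, C4 of the last) therefore span exactly the
# first-to-last anchor chord.
.arc_motif <- function() {
  data.frame(
    name = c("C1", "C2", "C3", "C4", "C5", "O5", "O4", "O3", "HO3"),
    element = c("C", "C", "C", "C", "C", "O", "O", "O", "H"),
    t = c(0.00, 0.77, 2.10, 2.60, 1.90, 0.60, 3.40, 0.50, -0.45),
    n = c(0.00, 1.30, 1.30, 0.00, -1.20, -1.20, 0.20, 2.40, 2.30),
    z = c(0.00, 0.00, 0.40, 0.00, 0.20, -0.20, -0.50, 0.90, 0.90),
    stringsAsFactors = FALSE)
}

#' Generate an arc-shaped saccharide-like chain ensemble
#'
#' Unit anchors are placed on a planar circular arc of total turn angle
#' `turn_angle` (degrees) and arc length `(n_units - 1) * spacing`:
#' 0 is an extended chain, ~180 a "U" shape, ~330 an "O" shape.  Each unit
#' carries a fixed 9-atom motif (C1..C5, O5, O4, O3, HO3 -- enough for the
#' end-to-end, linkage and hydrogen-bond stages to run); the last unit's
#' motif is mirrored so C4 sits on the terminal anchor, making the default
#' end-to-end distance exactly the first-to-last anchor chord:
#' `2 r sin(turn/2)` with `r = L / turn` (and `(n_units-1) * spacing` for a
#' straight chain).  Isotropic Gaussian noise of SD `noise_sigma` is added
#' to every atom, independently per frame.
#'
#' @param n_units number of units (>= 2).
#' @param spacing arc length between consecutive anchors (Angstrom).
#' @param turn_angle total in-plane curvature, degrees in [0, 360).
#' @param noise_sigma per-coordinate Gaussian noise SD (Angstrom).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param residue_names recycled residue names (default alternating
#'   `"ARA"`/`"ARB"`, giving an alternating copolymer).
#' @return a [conformer_ensemble()].
#' @export
generate_arc_chain <- function(n_units = 10L, spacing = 5, turn_angle = 0,
                               noise_sigma = 0, n_frames = 1L, seed = 1L,
                               residue_names = c("ARA", "ARB")) {
  if (n_units < 2L || spacing <= 0 || turn_angle < 0 || turn_angle >= 360 ||
      noise_sigma < 0 || n_frames < 1L)
    stop("invalid arc-chain spec", call. = FALSE)
  motif <- .arc_motif()
  L <- (n_units - 1L) * spacing
  theta_tot <- turn_angle * pi / 180
  anchor_at <- function(s) {
    # arc length parameter s in [0, L], arc in the xy-plane
    if (theta_tot == 0) return(c(s, 0, 0))
    r <- L / theta_tot
    a <- s / r
    c(r * sin(a), r * (1 - cos(a)), 0)
  }
  tangent_at <- function(s) {
    if (theta_tot == 0) return(c(1, 0, 0))
    a <- s / (L / theta_tot)
    c(cos(a), sin(a), 0)
  }
  base <- NULL
  top_rows <- NULL
  for (k in seq_len(n_units)) {
    s <- (k - 1L) * spacing
    anc <- anchor_at(s); tg <- tangent_at(s)
    nv <- c(-tg[2L], tg[1L], 0)           # in-plane normal
    zv <- c(0, 0, 1)
    mo <- motif
    if (k == n_units) {                   # mirrored terminal unit: C4 on anchor
      mo$t <- -mo$t
      mo$name[mo$name == "C1"] <- "tmp"
      mo$name[mo$name == "C4"] <- "C1"
      mo$name[mo$name == "tmp"] <- "C4"
    }
    xyz <- t(vapply(seq_len(nrow(mo)), function(i)
      anc + mo$t[i] * tg + mo$n[i] * nv + mo$z[i] * zv, numeric(3L)))
    base <- rbind(base, xyz)
    top_rows <- rbind(top_rows, data.frame(
      name = mo$name, element = mo$element,
      mass = element_mass(mo$element),
      residue_index = k,
      residue_name = residue_names[(k - 1L) %% length(residue_names) + 1L],
      residue_seq = k, stringsAsFactors = FALSE))
  }
  nat <- nrow(base)
  coords <- with_seed(seed, {
    cc <- array(NA_real_, dim = c(n_frames, nat, 3L))
    for (f in seq_len(n_frames))
      cc[f, , ] <- base + if (noise_sigma > 0)
        matrix(stats::rnorm(nat * 3L, sd = noise_sigma), nat, 3L) else 0
    cc
  })
  conformer_ensemble(top_rows, coords)
}

#' Generate a pyranose ring at prescribed Cremer-Pople coordinates
#'
#' Six ring atoms (ordered O5, C1..C5) are placed as a regular planar
#' hexagon of circumradius `bond_length` with out-of-plane displacements
#' from the Cremer-Pople amplitudes: `theta = 0` yields the 4C1 chair under
#' the package conventions, `theta = 180` the 1C4 chair, and the
#' `(theta = 90, phi = 150)` equator point the 2SO skew-boat.  Recomputing
#' Cremer-Pople coordinates from the noise-free output reproduces
#' `(q, theta, phi)` within 1 degree and 0.01 Angstrom.
#'
#' @param q total puckering amplitude (Angstrom; 0.57 is a typical chair).
#' @param theta,phi Cremer-Pople angles in degrees (`theta` in [0, 180],
#'   `phi` in [0, 360)).
#' @param bond_length ring bond length (Angstrom).
#' @param noise_sigma per-coordinate Gaussian noise SD (Angstrom).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return a single-residue [conformer_ensemble()] (residue name `"PYR"`).
#' @export
generate_ring <- function(q = 0.57, theta = 0, phi = 0, bond_length = 1.52,
                          noise_sigma = 0, n_frames = 1L, seed = 1L) {
  if (q < 0 || theta < 0 || theta > 180 || phi < 0 || phi >= 360 ||
      bond_length <= 0 || noise_sigma < 0 || n_frames < 1L)
    stop("invalid ring spec", call. = FALSE)
  base <- ring_template(q, theta, phi, bond_length)
  top <- data.frame(name = c("O5", "C1", "C2", "C3", "C4", "C5"),
                    element = c("O", "C", "C", "C", "C", "C"),
                    mass = element_mass(c("O", "C", "C", "C", "C", "C")),
                    residue_index = 1L, residue_name = "PYR",
                    residue_seq = 1L, stringsAsFactors = FALSE)
  coords <- with_seed(seed, {
    cc <- array(NA_real_, dim = c(n_frames, 6L, 3L))
    for (f in seq_len(n_frames))
      cc[f, , ] <- base + if (noise_sigma > 0)
        matrix(stats::rnorm(18L, sd = noise_sigma), 6L, 3L) else 0
    cc
  })
  conformer_ensemble(top, coords)
}

# Noise-free ring coordinates: regular hexagon + Cremer-Pople displacements.
# Atom j = 0..5 maps to O5, C1..C5.  The hexagon winds clockwise when seen
# from +z so that the measured mean-plane normal (Cremer-Pople R1 x R2
# convention) is +z and theta = 0 comes out as 4C1.
ring_template <- function(q, theta, phi, bond_length = 1.52) {
  j <- 0:5
  th <- theta * pi / 180; ph <- phi * pi / 180
  q2 <- q * sin(th); q3 <- q * cos(th)
  z <- sqrt(1 / 3) * q2 * cos(ph + 4 * pi * j / 6) +
    sqrt(1 / 6) * q3 * (-1)^j
  ang <- -2 * pi * j / 6
  cbind(bond_length * cos(ang), bond_length * sin(ang), z)
}

#' Sample glycosidic angle pairs from a von Mises mixture
#'
#' Draws `(phi, psi)` pairs from a mixture of independent von Mises modes;
#' mode membership is multinomial in the mode weights.  Sampling uses the
#' Best-Fisher (1979) rejection algorithm.
#'
#' @param modes data.frame with columns `mu_phi`, `mu_psi` (degrees),
#'   `kappa` (> 0) and `weight` (summing to 1).
#' @param n_samples number of pairs.
#' @param seed integer seed.
#' @return data.frame with `phi`, `psi` (degrees in (-180, 180]) and the
#'   generating `mode` index.
#' @export
generate_dihedral_samples <- function(modes, n_samples, seed = 1L) {
  req <- c("mu_phi", "mu_psi", "kappa", "weight")
  if (!is.data.frame(modes) || !all(req %in% names(modes)))
    stop("modes needs columns ", paste(req, collapse = ", "), call. = FALSE)
  if (any(modes$kappa <= 0) || abs(sum(modes$weight) - 1) > 1e-9)
    stop("kappa must be positive and weights must sum to 1", call. = FALSE)
  with_seed(seed, {
    mode <- sample.int(nrow(modes), n_samples, replace = TRUE,
                       prob = modes$weight)
    phi <- psi <- numeric(n_samples)
    for (k in seq_len(nrow(modes))) {
      sel <- which(mode == k)
      if (!length(sel)) next
      phi[sel] <- rvonmises(length(sel), modes$mu_phi[k], modes$kappa[k])
      psi[sel] <- rvonmises(length(sel), modes$mu_psi[k], modes$kappa[k])
    }
    data.frame(phi = phi, psi = psi, mode = mode)
  })
}

# von Mises sampler, Best & Fisher (1979); mu in degrees, returns degrees
# in (-180, 180].
rvonmises <- function(n, mu, kappa) {
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    todo <- n - got
    u1 <- stats::runif(todo); u2 <- stats::runif(todo); u3 <- stats::runif(todo)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nacc <- sum(ok)
    if (nacc) {
      ang <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1L):(got + nacc)] <- ang
      got <- got + nacc
    }
  }
  wrap180(mu + out * 180 / pi)
}

#' Generate a two-residue ensemble with a planted hydrogen-bond occupancy
#'
#' A donor residue (hydroxyl O1-HO1 on a carbon stub) faces an acceptor
#' residue (carbonyl-like O2 on a carbon stub).  In a Bernoulli(`occupancy`)
#' subset of frames the donor-acceptor geometry satisfies the default
#' criterion (D-A 2.8 Angstrom, D-H-A ~ 180 degrees); in the remaining
#' frames the acceptor residue is displaced far beyond the distance cutoff.
#'
#' @param occupancy target bond fraction in [0, 1].
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return a [conformer_ensemble()] with attribute `"planted_frames"` (the
#'   logical bonded-frame vector).
#' @export
generate_hbond_toggle <- function(occupancy, n_frames = 1000L, seed = 1L) {
  if (occupancy < 0 || occupancy > 1)
    stop("occupancy must be in [0, 1]", call. = FALSE)
  top <- data.frame(
    name = c("C1", "O1", "HO1", "C2", "O2"),
    element = c("C", "O", "H", "C", "O"),
    mass = element_mass(c("C", "O", "H", "C", "O")),
    residue_index = c(1L, 1L, 1L, 2L, 2L),
    residue_name = c("DNR", "DNR", "DNR", "ACC", "ACC"),
    residue_seq = c(1L, 1L, 1L, 2L, 2L), stringsAsFactors = FALSE)
  # donor geometry: O1 at origin, H on the +x axis toward the acceptor
  base_on <- rbind(c(-1.4, 0.3, 0), c(0, 0, 0), c(0.97, 0, 0),
                   c(4.0, 0.8, 0), c(2.8, 0, 0))      # O2 at D-A 2.8 A
  base_off <- base_on
  base_off[4:5, 1L] <- base_off[4:5, 1L] + 4          # D-A 6.8 A: no bond
  bonded <- with_seed(seed, stats::runif(n_frames) < occupancy)
  coords <- array(NA_real_, dim = c(n_frames, 5L, 3L))
  for (f in seq_len(n_frames))
    coords[f, , ] <- if (bonded[f]) base_on else base_off
  ens <- conformer_ensemble(top, coords)
  attr(ens, "planted_frames") <- bonded
  ens
}
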