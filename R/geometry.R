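# Torsion geometry and rigid-body superposition.

#' Dihedral angle of four points
#'
#' IUPAC sign convention: looking along the p2 -> p3 bond, a clockwise
#' rotation of the far bond relative to the near bond is positive.  The
#' result is wrapped to (-180, 180] degrees.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("undefined torsion: collinear atom triple", call. = FALSE)
  b2u <- b2 / vnorm(b2)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2u)
  wrap180(atan2(y, x) * 180 / pi)
}

# Vectorized per-frame dihedral for an ensemble and a 4-atom index vector.
dihedral_series_raw <- function(ensemble, idx4) {
  cc <- ensemble$coords
  p1 <- cc[, idx4[1L], , drop = FALSE]; dim(p1) <- c(dim(cc)[1L], 3L)
  p2 <- cc[, idx4[2L], , drop = FALSE]; dim(p2) <- c(dim(cc)[1L], 3L)
  p3 <- cc[, idx4[3L], , drop = FALSE]; dim(p3) <- c(dim(cc)[1L], 3L)
  p4 <- cc[, idx4[4L], , drop = FALSE]; dim(p4) <- c(dim(cc)[1L], 3L)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  crossm <- function(a, b) cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
                                 a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
                                 a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  n1 <- crossm(b1, b2); n2 <- crossm(b2, b3)
  bn <- sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(crossm(n1, n2) * (b2 / bn))
  bad <- sqrt(rowSums(n1^2)) < 1e-9 | sqrt(rowSums(n2^2)) < 1e-9
  if (any(bad))
    stop("undefined torsion (collinear atoms) in frame ", which(bad)[1L],
         call. = FALSE)
  wrap180(atan2(y, x) * 180 / pi)
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the (weighted)
#' root-mean-square distance between `mobile` and `reference`.  The rotation
#' is constrained to determinant +1, so a mirror image of a chiral point set
#' retains a strictly positive RMSD.
#'
#' @param mobile,reference numeric `n x 3` matrices with equal `n >= 3`.
#' @param weights optional non-negative per-point weights.
#' @return list with `rotation` (3x3, applied as `mobile %*% rotation`),
#'   `translation` (3-vector), and `rmsd` (Angstrom):
#'   `sweep(mobile %*% rotation, 2, translation, "+")` superposes onto
#'   `reference`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3L ||
      ncol(reference) != 3L)
    stop("mobile and reference must be n x 3 with equal n", call. = FALSE)
  n <- nrow(mobile)
  if (n < 3L) stop("degenerate geometry: need at least 3 points", call. = FALSE)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0)
    stop("weights must be non-negative with positive sum", call. = FALSE)
  w <- w / sum(w)
  mu_m <- colSums(w * mobile); mu_r <- colSums(w * reference)
  M <- sweep(mobile, 2L, mu_m); R <- sweep(reference, 2L, mu_r)
  sv_ref <- svd(R)$d
  if (sv_ref[2L] < 1e-8 * max(sv_ref[1L], 1e-12))
    stop("degenerate geometry: reference points are collinear", call. = FALSE)
  H <- t(M) %*% (w * R)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- M %*% rot
  rmsd <- sqrt(sum(w * rowSums((fitted - R)^2)))
  list(rotation = rot, translation = drop(mu_r - mu_m %*% rot), rmsd = rmsd)
}

# Apply a fitted superposition to an n x 3 matrix.
apply_superposition <- function(coords, fit) {
  sweep(coords %*% fit$rotation, 2L, fit$translation, "+")
}
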