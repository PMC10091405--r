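# Minimum-volume enclosing ellipsoid (Loewner ellipsoid) and the derived
# molecular volume descriptor.
#
# Algorithm: Khachiyan-style multiplicative weights on the lifted
# (d+1)-dimensional problem, with Wolfe-Atwood away/drop steps for linear
# local convergence.  Deterministic; no randomness, no silent
# regularization of degenerate input.

#' Minimum-volume enclosing ellipsoid of a point set
#'
#' Computes the smallest ellipsoid `{x : (x - c)' A (x - c) <= 1}` containing
#' all points.  Iterates until the KKT gap (both the maximum violation
#' `max_i M_i/(d+1) - 1` and the complementary gap on active points) drops
#' below `tolerance`; every input point then satisfies
#' `(x - c)' A (x - c) <= 1 + 10 * tolerance`, and at least one point lies on
#' the boundary to within the same gap (the minimality witness).
#'
#' Coplanar or collinear input is an error: a silently regularized flat
#' ellipsoid would report volume ~0 and corrupt descriptor summaries.
#'
#' @param points numeric `m x 3` matrix, `m >= 4`, spanning 3 dimensions.
#' @param tolerance relative KKT gap at convergence (default 1e-7).
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   achieved gap.
#' @return object of class `ellipsoid`: list with `center` (3-vector, A),
#'   `shape` (3x3 symmetric positive definite, 1/A^2), and `support_weights`
#'   (the converged point weights).
#' @references Khachiyan (1996); Todd & Yildirim (2007) on away steps.
#' @export
minimum_volume_ellipsoid <- function(points, tolerance = 1e-7,
                                     max_iter = 100000L) {
  P <- as.matrix(points)
  if (ncol(P) != 3L) stop("points must be m x 3", call. = FALSE)
  m <- nrow(P)
  if (m < 4L) stop("degenerate geometry: need at least 4 points", call. = FALSE)
  sv <- svd(sweep(P, 2L, colMeans(P)))$d
  if (sv[3L] < 1e-8 * max(sv[1L], 1e-12))
    stop("degenerate geometry: points are coplanar or collinear", call. = FALSE)
  d <- 3L
  Q <- t(cbind(P, 1))                     # (d+1) x m lifted points
  u <- rep(1 / m, m)
  gap <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    X <- Q %*% (u * t(Q))
    Minv <- tryCatch(solve(X), error = function(e)
      stop("degenerate geometry: singular moment matrix", call. = FALSE))
    Mdist <- colSums(Q * (Minv %*% Q))
    jp <- which.max(Mdist); Mp <- Mdist[jp]
    act <- which(u > 1e-12)
    jm <- act[which.min(Mdist[act])]; Mm <- Mdist[jm]
    gap_p <- Mp / (d + 1) - 1
    gap_m <- 1 - Mm / (d + 1)
    gap <- max(gap_p, gap_m)
    if (gap <= tolerance) { converged <- TRUE; break }
    if (gap_p >= gap_m) {               # add step toward the worst point
      j <- jp
      beta <- (Mp - d - 1) / ((d + 1) * (Mp - 1))
    } else {                            # away (possibly drop) step
      j <- jm
      beta <- max((Mm - d - 1) / ((d + 1) * (Mm - 1)), -u[jm] / (1 - u[jm]))
    }
    u <- (1 - beta) * u
    u[j] <- u[j] + beta
    u[u < 0] <- 0
    u <- u / sum(u)
  }
  if (!converged)
    stop(sprintf("MVEE did not converge in %d iterations (KKT gap %.3g)",
                 max_iter, gap), call. = FALSE)
  center <- drop(crossprod(P, u))
  S <- crossprod(P, u * P) - tcrossprod(center)
  A <- solve(S) / d
  A <- (A + t(A)) / 2
  new_ellipsoid(center, A, support_weights = u)
}

new_ellipsoid <- function(center, shape, support_weights = NULL) {
  if (max(abs(shape - t(shape))) > 1e-10)
    stop("ellipsoid shape matrix must be symmetric", call. = FALSE)
  ev <- eigen(shape, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("ellipsoid shape matrix must be positive definite", call. = FALSE)
  structure(list(center = center, shape = shape,
                 support_weights = support_weights),
            class = "ellipsoid")
}

#' Volume of an ellipsoid
#'
#' `(4 pi / 3) * det(A)^(-1/2)` for shape matrix A, in cubic Angstrom.
#'
#' @param e an `ellipsoid`.
#' @return volume in cubic Angstrom.
#' @export
ellipsoid_volume <- function(e) {
  stopifnot(inherits(e, "ellipsoid"))
  ev <- eigen(e$shape, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("shape matrix is not positive definite", call. = FALSE)
  (4 * pi / 3) / sqrt(prod(ev))
}

#' Semi-axes of an ellipsoid
#'
#' @param e an `ellipsoid`.
#' @return list with `lengths` (decreasing semi-axis lengths, Angstrom) and
#'   `directions` (columns are the corresponding unit axes).
#' @export
ellipsoid_axes <- function(e) {
  stopifnot(inherits(e, "ellipsoid"))
  dec <- eigen(e$shape, symmetric = TRUE)
  ord <- order(dec$values)               # smallest eigenvalue = longest axis
  list(lengths = 1 / sqrt(dec$values[ord]),
       directions = dec$vectors[, ord, drop = FALSE])
}

#' @export
print.ellipsoid <- function(x, ...) {
  ax <- ellipsoid_axes(x)
  cat("ellipsoid: semi-axes", paste(format(ax$lengths, digits = 4L),
                                    collapse = " x "),
      "A, volume", format(ellipsoid_volume(x), digits = 6L), "A^3\n")
  invisible(x)
}

#' Per-frame MVEE volume series
#'
#' The molecular volume descriptor: the minimum-volume enclosing ellipsoid
#' of the selected atoms, per frame.  All atoms including hydrogens are used
#' by default -- the natural reading of "space occupied by the molecule's
#' atoms"; pass a heavy-atom selection to compare against heavy-only
#' conventions.
#'
#' @param ensemble a [conformer_ensemble()].
#' @param selection atom indices (default: all atoms).
#' @param tolerance,max_iter passed to [minimum_volume_ellipsoid()].
#' @return a `descriptor_series` named `"volume"`, units cubic Angstrom.
#' @export
volume_series <- function(ensemble, selection = NULL, tolerance = 1e-7,
                          max_iter = 100000L) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  selection <- selection %||% seq_len(n_atoms(ensemble))
  vals <- vapply(seq_len(n_frames(ensemble)), function(f) {
    e <- tryCatch(
      minimum_volume_ellipsoid(frame_coords(ensemble, f)[selection, ,
                                                         drop = FALSE],
                               tolerance = tolerance, max_iter = max_iter),
      error = function(err)
        stop("frame ", f, ": ", conditionMessage(err), call. = FALSE))
    ellipsoid_volume(e)
  }, numeric(1L))
  new_descriptor_series("volume", vals, ensemble$frame_labels, units = "A^3")
}
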