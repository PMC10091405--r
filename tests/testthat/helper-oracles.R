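# Independent oracles used to cross-check the package implementations.
# These deliberately take different algorithmic routes than the package:
# Horn's closed-form quaternion method vs the SVD Kabsch path, and direct
# penalized log-det optimization vs the Khachiyan multiplicative-weights
# iteration.

# Minimum RMSD over proper rigid motions via Horn's quaternion eigenvalue
# method (closed form, no SVD).
rmsd_horn <- function(mobile, reference) {
  n <- nrow(mobile)
  M <- sweep(mobile, 2L, colMeans(mobile))
  R <- sweep(reference, 2L, colMeans(reference))
  S <- t(M) %*% R
  K <- matrix(0, 4L, 4L)
  K[1L, 1L] <- S[1L, 1L] + S[2L, 2L] + S[3L, 3L]
  K[1L, 2L] <- K[2L, 1L] <- S[2L, 3L] - S[3L, 2L]
  K[1L, 3L] <- K[3L, 1L] <- S[3L, 1L] - S[1L, 3L]
  K[1L, 4L] <- K[4L, 1L] <- S[1L, 2L] - S[2L, 1L]
  K[2L, 2L] <- S[1L, 1L] - S[2L, 2L] - S[3L, 3L]
  K[2L, 3L] <- K[3L, 2L] <- S[1L, 2L] + S[2L, 1L]
  K[2L, 4L] <- K[4L, 2L] <- S[1L, 3L] + S[3L, 1L]
  K[3L, 3L] <- -S[1L, 1L] + S[2L, 2L] - S[3L, 3L]
  K[3L, 4L] <- K[4L, 3L] <- S[2L, 3L] + S[3L, 2L]
  K[4L, 4L] <- -S[1L, 1L] - S[2L, 2L] + S[3L, 3L]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(M^2) + sum(R^2) - 2 * lam) / n))
}

# Direct MVEE oracle: minimize -log det(A) over SPD A (Cholesky
# parameterization) and center c, subject to enclosure, by interior-point
# log-barrier path following from the (feasible, shrunken) moment
# ellipsoid; the returned volume is that of the final iterate rescaled to
# exact feasibility.  Independent of the multiplicative-weights path;
# adequate for the small (m <= 10) instances it is used on.
mvee_volume_oracle <- function(P) {
  m <- nrow(P)
  c0 <- colMeans(P)
  S <- stats::cov(P) * (m - 1) / m
  Ainv0 <- solve(S)
  g0 <- max(colSums(t(sweep(P, 2L, c0)) *
                    (Ainv0 %*% t(sweep(P, 2L, c0)))))
  A0 <- Ainv0 / (1.05 * g0)           # strictly feasible start
  L0 <- t(chol(A0))
  pack <- function(L, cc) c(log(diag(L)), L[lower.tri(L)], cc)
  unpack <- function(p) {
    L <- diag(exp(p[1:3]))
    L[lower.tri(L)] <- p[4:6]
    list(L = L, c = p[7:9])
  }
  barrier <- function(p, t) {
    u <- unpack(p)
    A <- u$L %*% t(u$L)
    D <- sweep(P, 2L, u$c)
    quad <- rowSums((D %*% A) * D)
    slack <- 1 - quad
    if (any(!is.finite(slack))) return(1e12)
    if (any(slack <= 0)) return(1e10 * (1 + sum(pmax(0, -slack))))
    -2 * t * sum(p[1:3]) - sum(log(slack))
  }
  p <- pack(L0, c0)
  for (t in 10^(0:7)) {
    p <- stats::optim(p, barrier, t = t, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15,
                                     ndeps = rep(1e-7, 9L)))$par
  }
  u <- unpack(p)
  A <- u$L %*% t(u$L)
  D <- sweep(P, 2L, u$c)
  tmax <- max(rowSums((D %*% A) * D))
  A <- A / tmax                       # rescale to exact enclosure
  (4 * pi / 3) / sqrt(det(A))
}

# circular mean of angles in degrees
circular_mean <- function(deg) {
  r <- deg * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}

# circular SD (degrees) from mean resultant length
circular_sd <- function(deg) {
  r <- deg * pi / 180
  R <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  sqrt(-2 * log(R)) * 180 / pi
}

# convenience: a random well-spread 3-D point cloud
random_points <- function(m, scale = 5) {
  matrix(stats::rnorm(3 * m, sd = scale), m, 3L)
}

# write a minimal (possibly multi-model) PDB text fixture
write_mini_pdb <- function(path, models) {
  con <- file(path, "w"); on.exit(close(con))
  for (mi in seq_along(models)) {
    writeLines(sprintf("MODEL     %4d", mi), con)
    m <- models[[mi]]
    for (i in seq_len(nrow(m$xyz))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, m$name[i], m$resid[i], m$resno[i],
        m$xyz[i, 1L], m$xyz[i, 2L], m$xyz[i, 3L], m$element[i]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  path
}

# thin shims over package internals used across test files
with_seed_for_test <- function(seed, expr) gagshape:::with_seed(seed, expr)
random_rotation_for_test <- function() gagshape:::random_rotation()
new_descriptor_series_for_test <- function(v)
  gagshape:::new_descriptor_series("x", v)
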