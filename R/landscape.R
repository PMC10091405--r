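# Glycosidic phi/psi series, pooled 2-D histograms per ordered linkage type,
# and Boltzmann-inverted free-energy surfaces.

# gas constant, kcal mol^-1 K^-1
.Rgas <- 1.9872e-3

#' Glycosidic phi/psi torsion series for one linkage
#'
#' phi = O5(n+1)-C1(n+1)-O4(n)-C4(n), psi = C1(n+1)-O4(n)-C4(n)-C3(n),
#' per frame, degrees in (-180, 180].
#'
#' @param ensemble a [conformer_ensemble()].
#' @param linkage one row of [identify_glycosidic_linkages()] output.
#' @return object of class `angle_series`: list with `phi`, `psi` (numeric
#'   per frame) and `linkage_type`.
#' @export
phi_psi_series <- function(ensemble, linkage) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  phi <- dihedral_series_raw(ensemble,
                             c(linkage$phi1, linkage$phi2, linkage$phi3,
                               linkage$phi4))
  psi <- dihedral_series_raw(ensemble,
                             c(linkage$psi1, linkage$psi2, linkage$psi3,
                               linkage$psi4))
  structure(list(phi = phi, psi = psi,
                 linkage_type = linkage$linkage_type),
            class = "angle_series")
}

#' Pooled 2-D phi/psi histogram over linkages of one ordered type
#'
#' Counts are pooled over all supplied angle series (which must share the
#' same ordered linkage type -- populations of A->B linkages are never mixed
#' with B->A) and over all frames.  Bins are half-open `[low, high)` tiling
#' (-180, 180] wrap-consistently: +180 is binned with -180.
#'
#' @param series a single `angle_series` or a list of them.
#' @param linkage_type optional; checked against the series if supplied.
#' @param bin_width bin width in degrees; must divide 360 (default 5).
#' @return object of class `angle_histogram`: list with `counts`
#'   (phi x psi matrix), `bin_edges_phi`, `bin_edges_psi`, `n_total`,
#'   `linkage_type`.
#' @export
pooled_histogram <- function(series, linkage_type = NULL, bin_width = 5) {
  if (inherits(series, "angle_series")) series <- list(series)
  stopifnot(all(vapply(series, inherits, logical(1L), "angle_series")))
  if (360 %% bin_width != 0)
    stop("bin_width must divide 360", call. = FALSE)
  types <- unique(vapply(series, `[[`, "", "linkage_type"))
  if (length(types) > 1L)
    stop("mixed linkage types in pooled histogram: ",
         paste(types, collapse = ", "), call. = FALSE)
  if (!is.null(linkage_type) && !identical(types, linkage_type))
    stop("series are of type ", types, ", not ", linkage_type, call. = FALSE)
  edges <- seq(-180, 180, by = bin_width)
  nb <- length(edges) - 1L
  counts <- matrix(0L, nb, nb)
  bin_of <- function(a) {
    a <- ((a + 180) %% 360) - 180        # map to [-180, 180)
    pmin(floor((a + 180) / bin_width) + 1L, nb)
  }
  for (s in series) {
    i <- bin_of(s$phi); k <- bin_of(s$psi)
    t2 <- table(factor(i, levels = seq_len(nb)), factor(k, levels = seq_len(nb)))
    counts <- counts + unclass(t2)
  }
  structure(list(counts = counts, bin_edges_phi = edges, bin_edges_psi = edges,
                 n_total = sum(counts), linkage_type = types %||% NA_character_),
            class = "angle_histogram")
}

#' Boltzmann inversion of a phi/psi histogram into a free-energy surface
#'
#' `p_b = n_b / N`, `dG_b = -R T ln(p_b / p_max)` in kcal/mol
#' (R = 1.9872e-3 kcal/mol/K).  Empty bins cannot carry `-RT ln 0`; they are
#' assigned the free energy of a half count (n = 0.5) and flagged, so
#' heatmaps render finite while the minimum determination never considers
#' them.
#'
#' @param histogram an `angle_histogram` (or a raw count matrix).
#' @param temperature simulation temperature in Kelvin (default 300).
#' @return object of class `free_energy_grid`: list with `bin_edges_phi`,
#'   `bin_edges_psi`, `probabilities`, `delta_g` (kcal/mol, min over
#'   non-empty bins is 0), `empty` (logical flag matrix), `temperature`,
#'   `linkage_type`.
#' @export
free_energy_map <- function(histogram, temperature = 300) {
  if (inherits(histogram, "angle_histogram")) {
    counts <- histogram$counts
    edges_phi <- histogram$bin_edges_phi
    edges_psi <- histogram$bin_edges_psi
    ltype <- histogram$linkage_type
  } else {
    counts <- as.matrix(histogram)
    edges_phi <- seq(-180, 180, length.out = nrow(counts) + 1L)
    edges_psi <- seq(-180, 180, length.out = ncol(counts) + 1L)
    ltype <- NA_character_
  }
  N <- sum(counts)
  if (N <= 0) stop("all-zero counts: no populations to invert", call. = FALSE)
  p <- counts / N
  pmax_ <- max(p)
  empty <- counts == 0
  eff <- counts
  eff[empty] <- 0.5                      # flagged pseudo-count for rendering
  dg <- -.Rgas * temperature * log((eff / N) / pmax_)
  structure(list(bin_edges_phi = edges_phi, bin_edges_psi = edges_psi,
                 probabilities = p, delta_g = dg, empty = empty,
                 temperature = temperature, linkage_type = ltype),
            class = "free_energy_grid")
}

#' Locate the lowest-free-energy bins of a grid
#'
#' @param grid a `free_energy_grid`.
#' @param n number of lowest non-empty bins to return.
#' @return data.frame with bin-center `phi`, `psi`, and `delta_g`, ordered
#'   by increasing free energy.
#' @export
lowest_bins <- function(grid, n = 2L) {
  stopifnot(inherits(grid, "free_energy_grid"))
  dg <- grid$delta_g
  dg[grid$empty] <- Inf
  ord <- order(dg)[seq_len(n)]
  nb <- nrow(dg)
  i <- (ord - 1L) %% nb + 1L
  k <- (ord - 1L) %/% nb + 1L
  ctr <- function(edges, idx) (edges[idx] + edges[idx + 1L]) / 2
  data.frame(phi = ctr(grid$bin_edges_phi, i),
             psi = ctr(grid$bin_edges_psi, k),
             delta_g = dg[ord])
}

#' Export a free-energy grid
#'
#' Long-form TSV with columns `phi_low`, `psi_low`, `count`-equivalent
#' probability, `delta_g` and `empty_flag`, plus (optionally) a matrix-form
#' CSV of `delta_g` for direct heatmap plotting.
#'
#' @param grid a `free_energy_grid`.
#' @param path output TSV path.
#' @param matrix_path optional path for the matrix-form CSV.
#' @return `path`, invisibly.
#' @export
write_fe_grid <- function(grid, path, matrix_path = NULL) {
  stopifnot(inherits(grid, "free_energy_grid"))
  nb_phi <- nrow(grid$delta_g); nb_psi <- ncol(grid$delta_g)
  df <- data.frame(
    phi_low = rep(grid$bin_edges_phi[seq_len(nb_phi)], times = nb_psi),
    psi_low = rep(grid$bin_edges_psi[seq_len(nb_psi)], each = nb_phi),
    probability = as.vector(grid$probabilities),
    delta_g = as.vector(grid$delta_g),
    empty_flag = as.vector(grid$empty))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(matrix_path)) {
    m <- grid$delta_g
    dimnames(m) <- list(phi = grid$bin_edges_phi[seq_len(nb_phi)],
                        psi = grid$bin_edges_psi[seq_len(nb_psi)])
    utils::write.csv(m, matrix_path)
  }
  invisible(path)
}
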