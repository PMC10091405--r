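# Global shape descriptors: end-to-end distance, radius of gyration,
# RMSD series, atomic fluctuations, and mean +/- SD summaries.
#
# Summary convention used throughout: population SD (divide by n), the
# frame-statistics convention, echoed in exported metadata.

new_descriptor_series <- function(name, values, frame_labels = NULL,
                                  units = "A") {
  if (!all(is.finite(values))) stop("descriptor series contains non-finite values",
                                    call. = FALSE)
  structure(list(name = name, values = as.numeric(values),
                 frame_labels = frame_labels, units = units),
            class = "descriptor_series")
}

#' @export
print.descriptor_series <- function(x, ...) {
  cat("descriptor_series '", x$name, "': ", length(x$values), " frames, ",
      "mean ", format(mean(x$values), digits = 4L), " ", x$units, "\n", sep = "")
  invisible(x)
}

#' Default end-to-end endpoint atoms
#'
#' The chain-axis anchors: C1 of the first (nonreducing-end) residue and C4
#' of the last residue, the atoms that carry the 1->4 glycosidic chain.
#' Override by passing an explicit `endpoints` pair to
#' [end_to_end_distance()] when comparing against conventions that use other
#' termini.
#'
#' @param topology a topology data.frame.
#' @return integer vector of two atom indices.
#' @export
default_endpoints <- function(topology) {
  res <- sort(unique(topology$residue_index))
  a <- select_atoms(topology, name = "C1", residue_index = res[1L])[1L]
  b <- select_atoms(topology, name = "C4", residue_index = res[length(res)])
  b <- b[length(b)]
  if (a == b) stop("endpoint atoms coincide", call. = FALSE)
  c(a, b)
}

#' End-to-end distance series
#'
#' Per-frame Euclidean distance between two endpoint atoms, in Angstrom.
#'
#' @param ensemble a [conformer_ensemble()].
#' @param endpoints integer vector of two distinct atom indices; default
#'   [default_endpoints()].
#' @return a `descriptor_series` named `"dist"`.
#' @export
end_to_end_distance <- function(ensemble, endpoints = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  endpoints <- endpoints %||% default_endpoints(ensemble$topology)
  if (length(endpoints) != 2L || endpoints[1L] == endpoints[2L] ||
      any(endpoints < 1L | endpoints > n_atoms(ensemble)))
    stop("endpoints must be two distinct valid atom indices", call. = FALSE)
  d <- ensemble$coords[, endpoints[1L], ] - ensemble$coords[, endpoints[2L], ]
  if (n_frames(ensemble) == 1L) dim(d) <- c(1L, 3L)
  new_descriptor_series("dist", sqrt(rowSums(d^2)), ensemble$frame_labels)
}

#' Radius of gyration series
#'
#' Per frame, `sqrt(sum(m_i |x_i - xbar|^2) / sum(m_i))` with `xbar` the
#' (mass-weighted) centroid of the selected atoms.  Mass weighting over all
#' atoms including hydrogens is the default, matching the common
#' trajectory-toolkit convention.
#'
#' @param ensemble a [conformer_ensemble()].
#' @param selection atom indices (default: all atoms).
#' @param mass_weighted logical; unweighted uses unit masses.
#' @return a `descriptor_series` named `"radgyr"`.
#' @export
radius_of_gyration <- function(ensemble, selection = NULL,
                               mass_weighted = TRUE) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  selection <- selection %||% seq_len(n_atoms(ensemble))
  if (!length(selection)) stop("selection is empty", call. = FALSE)
  m <- if (mass_weighted) ensemble$topology$mass[selection]
       else rep(1, length(selection))
  if (sum(m) <= 0) stop("zero total mass", call. = FALSE)
  w <- m / sum(m)
  vals <- vapply(seq_len(n_frames(ensemble)), function(f) {
    x <- frame_coords(ensemble, f)[selection, , drop = FALSE]
    mu <- colSums(w * x)
    sqrt(sum(w * rowSums(sweep(x, 2L, mu)^2)))
  }, numeric(1L))
  new_descriptor_series("radgyr", vals, ensemble$frame_labels)
}

#' RMSD series against a fixed reference
#'
#' Per-frame minimum RMSD after optimal proper rigid superposition
#' ([kabsch_superpose()]) of the selected atoms onto a fixed reference
#' structure -- by default the first frame, the slot where the experimental
#' starting structure sits in a trajectory ensemble.  All non-hydrogen atoms
#' are used by default (hydrogen placement in NMR models is model-dependent).
#'
#' @param ensemble a [conformer_ensemble()].
#' @param reference either a frame index into `ensemble`, or an
#'   `n_atoms x 3` coordinate matrix.
#' @param selection atom indices (default: heavy atoms).
#' @return a `descriptor_series` named `"RMSD"`.
#' @export
rmsd_series <- function(ensemble, reference = 1L, selection = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  selection <- selection %||% heavy_atoms(ensemble$topology)
  ref <- if (is.matrix(reference)) reference else frame_coords(ensemble, reference)
  if (nrow(ref) != n_atoms(ensemble))
    stop("reference must have one row per ensemble atom", call. = FALSE)
  refs <- ref[selection, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(ensemble)), function(f) {
    kabsch_superpose(frame_coords(ensemble, f)[selection, , drop = FALSE],
                     refs)$rmsd
  }, numeric(1L))
  new_descriptor_series("RMSD", vals, ensemble$frame_labels)
}

#' Atomic fluctuations (RMSF) about the ensemble mean structure
#'
#' Frames are superposed onto the ensemble mean structure, iterating
#' mean -> fit -> re-mean until the mean structure moves less than `tol`
#' (RMS, Angstrom) or `max_iter` iterations, then per-atom
#' RMSF_i = sqrt(<|x_i - <x_i>|^2>) is computed over frames.  The summary is
#' mean +/- population SD over atoms (labelled as such in reports, since
#' per-atom and per-time-window conventions differ).
#'
#' @param ensemble a [conformer_ensemble()] with at least two frames.
#' @param selection atom indices (default: heavy atoms).
#' @param tol,max_iter convergence controls for the iterated mean fit.
#' @return list with `rmsf` (per selected atom, Angstrom), `selection`,
#'   and `summary` (a `descriptor_summary` named `"fluct"`).
#' @export
atomic_fluctuations <- function(ensemble, selection = NULL, tol = 1e-6,
                                max_iter = 10L) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (n_frames(ensemble) < 2L)
    stop("fluctuations are undefined for a single frame", call. = FALSE)
  selection <- selection %||% heavy_atoms(ensemble$topology)
  nf <- n_frames(ensemble)
  frames <- lapply(seq_len(nf), function(f)
    frame_coords(ensemble, f)[selection, , drop = FALSE])
  mean_struct <- Reduce(`+`, frames) / nf
  for (it in seq_len(max_iter)) {
    fitted <- lapply(frames, function(x)
      apply_superposition(x, kabsch_superpose(x, mean_struct)))
    new_mean <- Reduce(`+`, fitted) / nf
    shift <- sqrt(mean(rowSums((new_mean - mean_struct)^2)))
    mean_struct <- new_mean
    if (shift < tol) break
  }
  fitted <- lapply(frames, function(x)
    apply_superposition(x, kabsch_superpose(x, mean_struct)))
  mean_struct <- Reduce(`+`, fitted) / nf
  msd <- Reduce(`+`, lapply(fitted, function(x)
    rowSums((x - mean_struct)^2))) / nf
  rmsf <- sqrt(msd)
  list(rmsf = rmsf, selection = selection,
       summary = new_descriptor_summary("fluct", mean(rmsf), sd_pop(rmsf),
                                        length(rmsf)))
}

new_descriptor_summary <- function(name, mean, sd, n) {
  if (sd < 0 || n < 1L) stop("invalid descriptor summary", call. = FALSE)
  structure(list(name = name, mean = mean, sd = sd, n = n),
            class = "descriptor_summary")
}

#' @export
print.descriptor_summary <- function(x, ...) {
  cat(x$name, ": ", format(x$mean, digits = 4L), " +/- ",
      format(x$sd, digits = 3L), " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Summarize a descriptor series as mean +/- population SD
#'
#' @param series a `descriptor_series`.
#' @return a `descriptor_summary` (mean, population SD, n = frame count).
#' @export
summarize_series <- function(series) {
  stopifnot(inherits(series, "descriptor_series"))
  v <- series$values
  if (!length(v)) stop("empty descriptor series", call. = FALSE)
  new_descriptor_summary(series$name, mean(v), sd_pop(v), length(v))
}

#' Aggregate replicate-run summaries
#'
#' Replicate simulations are aggregated as mean of run means with SD equal
#' to the population SD of the run means (n = run count), the convention for
#' consistency checks across repeated short runs.
#'
#' @param summaries list of `descriptor_summary` objects for the same
#'   descriptor.
#' @return a `descriptor_summary`.
#' @export
aggregate_runs <- function(summaries) {
  if (!length(summaries)) stop("no summaries to aggregate", call. = FALSE)
  stopifnot(all(vapply(summaries, inherits, logical(1L), "descriptor_summary")))
  means <- vapply(summaries, `[[`, numeric(1L), "mean")
  new_descriptor_summary(summaries[[1L]]$name, mean(means), sd_pop(means),
                         length(means))
}

#' Export a descriptor series as TSV
#'
#' Columns `frame`, `value`; value units are Angstrom (cubic Angstrom for
#' MVEE volume series).
#'
#' @param series a `descriptor_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series_tsv <- function(series, path) {
  stopifnot(inherits(series, "descriptor_series"))
  df <- data.frame(frame = seq_along(series$values), value = series$values)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
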