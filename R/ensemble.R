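#' Conformer ensembles
#'
#' A `conformer_ensemble` couples a topology (per-atom metadata) with a block
#' of coordinates, one frame per conformer / trajectory snapshot / PDB MODEL.
#' It is the universal input of every analysis stage in this package.
#'
#' The topology is a plain `data.frame` with one row per atom and columns
#' `name` (PDB-style atom name, e.g. `"C1"`), `element`, `mass` (amu),
#' `residue_index` (1-based, non-decreasing), `residue_name` and
#' `residue_seq` (author residue number as read from the file).  Coordinates
#' are stored as an `n_frames x n_atoms x 3` array in Angstrom.
#'
#' @param topology data.frame as described above.
#' @param coords numeric array `n_frames x n_atoms x 3` (Angstrom).  A single
#'   `n_atoms x 3` matrix is promoted to a one-frame ensemble.
#' @param frame_labels optional character vector of frame names.
#' @return An object of class `conformer_ensemble`.
#' @examples
#' top <- data.frame(name = c("C1", "C4"), element = "C", mass = 12.011,
#'                   residue_index = 1L, residue_name = "PYR", residue_seq = 1L)
#' ens <- conformer_ensemble(top, matrix(c(0, 0, 0, 3, 4, 0), 2, 3, byrow = TRUE))
#' n_frames(ens)
#' @export
conformer_ensemble <- function(topology, coords, frame_labels = NULL) {
  topology <- validate_topology(topology)
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  if (length(dim(coords)) != 3L || dim(coords)[3L] != 3L)
    stop("coords must be an n_frames x n_atoms x 3 array", call. = FALSE)
  if (dim(coords)[2L] != nrow(topology))
    stop("coords atom dimension (", dim(coords)[2L],
         ") does not match topology (", nrow(topology), " atoms)", call. = FALSE)
  if (dim(coords)[1L] < 1L) stop("ensemble needs at least one frame", call. = FALSE)
  if (!all(is.finite(coords))) stop("all coordinates must be finite", call. = FALSE)
  if (!is.null(frame_labels) && length(frame_labels) != dim(coords)[1L])
    stop("frame_labels length must equal n_frames", call. = FALSE)
  structure(list(topology = topology, coords = coords,
                 frame_labels = frame_labels),
            class = "conformer_ensemble")
}

validate_topology <- function(topology) {
  req <- c("name", "element", "mass", "residue_index", "residue_name",
           "residue_seq")
  if (!is.data.frame(topology) || !all(req %in% names(topology)))
    stop("topology must be a data.frame with columns: ",
         paste(req, collapse = ", "), call. = FALSE)
  if (nrow(topology) == 0L) stop("topology has zero atoms", call. = FALSE)
  if (any(!nzchar(topology$name))) stop("atom names must be non-empty", call. = FALSE)
  if (any(!is.finite(topology$mass) | topology$mass <= 0))
    stop("atom masses must be positive", call. = FALSE)
  if (is.unsorted(topology$residue_index))
    stop("residue_index must be non-decreasing along the atom sequence",
         call. = FALSE)
  rownames(topology) <- NULL
  topology
}

#' @rdname conformer_ensemble
#' @param x a `conformer_ensemble`.
#' @export
n_frames <- function(x) dim(x$coords)[1L]

#' @rdname conformer_ensemble
#' @export
n_atoms <- function(x) dim(x$coords)[2L]

#' @rdname conformer_ensemble
#' @export
n_residues <- function(x) length(unique(x$topology$residue_index))

#' Extract one frame as an n_atoms x 3 coordinate matrix
#'
#' @param ensemble a `conformer_ensemble`.
#' @param i frame index (1-based).
#' @return numeric matrix `n_atoms x 3` (Angstrom).
#' @export
frame_coords <- function(ensemble, i) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (i < 1L || i > n_frames(ensemble))
    stop("frame index ", i, " out of range 1..", n_frames(ensemble), call. = FALSE)
  m <- ensemble$coords[i, , , drop = FALSE]
  dim(m) <- dim(ensemble$coords)[2:3]
  m
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("conformer_ensemble:", n_frames(x), "frame(s),", n_atoms(x), "atoms,",
      n_residues(x), "residue(s)\n")
  rn <- tapply(x$topology$residue_name, x$topology$residue_index,
               function(z) z[1L])
  cat("  residues:", paste(utils::head(rn, 12L), collapse = " "),
      if (length(rn) > 12L) "..." else "", "\n")
  invisible(x)
}

#' Subset an ensemble to a window of consecutive residues
#'
#' Returns a new ensemble containing `n_units` consecutive residues starting
#' at `start_residue` (1-based), with atoms and residues renumbered from 1.
#' Coordinates are copied frame-wise; descriptors computed on the result are
#' identical to descriptors computed on a manual coordinate slice.
#'
#' @param ensemble a `conformer_ensemble`.
#' @param start_residue 1-based index of the first residue to keep.
#' @param n_units number of consecutive residues to keep.
#' @return a `conformer_ensemble` with exactly `n_units` residues.
#' @export
extract_chain_window <- function(ensemble, start_residue, n_units) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  res <- sort(unique(ensemble$topology$residue_index))
  if (start_residue < 1L || n_units < 1L ||
      start_residue + n_units - 1L > length(res))
    stop("residue window [", start_residue, ", ",
         start_residue + n_units - 1L, "] exceeds the ", length(res),
         "-residue chain", call. = FALSE)
  keep_res <- res[start_residue:(start_residue + n_units - 1L)]
  idx <- which(ensemble$topology$residue_index %in% keep_res)
  top <- ensemble$topology[idx, , drop = FALSE]
  top$residue_index <- match(top$residue_index, keep_res)
  conformer_ensemble(top, ensemble$coords[, idx, , drop = FALSE],
                     ensemble$frame_labels)
}
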