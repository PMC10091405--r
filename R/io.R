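# Structure file I/O: multi-model PDB (via bio3d) and multi-frame XYZ.

.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, "NA" = 22.990, K = 39.098,
  MG = 24.305, CA = 40.078, FE = 55.845, ZN = 65.38
)

element_mass <- function(element) {
  m <- .element_masses[toupper(element)]
  m[is.na(m)] <- 12.011  # conservative fallback for exotic symbols
  unname(m)
}

# Element from the PDB element column when present, else from the first
# alphabetic character of the atom name (digits stripped).
infer_element <- function(name, elesy = NULL) {
  el <- if (!is.null(elesy)) trimws(elesy) else rep("", length(name))
  miss <- !nzchar(el) | is.na(el)
  if (any(miss)) {
    first <- sub("^[0-9']*", "", trimws(name[miss]))
    el[miss] <- substr(first, 1L, 1L)
  }
  toupper(el)
}

#' Read a structure file into a conformer ensemble
#'
#' Multi-model PDB files (MODEL/ENDMDL blocks, as deposited for NMR entries
#' such as 1HPN) become one frame per model; a file without MODEL records
#' yields a single-frame ensemble.  Multi-frame XYZ files are supported as a
#' lightweight exchange format.  Atom masses are assigned from the element
#' symbol, falling back to the first letter of the atom name.
#'
#' @param path path to the structure file.
#' @param format `"auto"` (by file extension), `"pdb"` or `"xyz"`.
#' @return a [conformer_ensemble()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "xyz") "xyz" else "pdb"
  }
  switch(format, pdb = read_pdb_ensemble(path), xyz = read_xyz_ensemble(path))
}

read_pdb_ensemble <- function(path) {
  # pre-scan MODEL blocks so unequal atom counts give a useful format error
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1L) {
    model_ends <- which(startsWith(lines, "ENDMDL"))
    counts <- vapply(seq_along(model_starts), function(k) {
      lo <- model_starts[k]
      hi <- if (k <= length(model_ends)) model_ends[k] else length(lines)
      sum(is_atom[lo:hi])
    }, integer(1L))
    if (length(unique(counts)) > 1L) {
      bad <- which(counts != counts[1L])[1L]
      stop("PDB format error: model ", bad, " has ", counts[bad],
           " atoms but model 1 has ", counts[1L], call. = FALSE)
    }
  }
  if (!any(is_atom)) stop("no atoms found in ", path, call. = FALSE)

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  nat <- nrow(at)
  element <- infer_element(at$elety, at$elesy)
  # residue boundaries follow author numbering + chain + insert changes
  res_key <- paste(at$chain, at$resno, at$insert, sep = "|")
  residue_index <- as.integer(factor(res_key, levels = unique(res_key)))
  top <- data.frame(
    name = trimws(at$elety), element = element, mass = element_mass(element),
    residue_index = residue_index, residue_name = trimws(at$resid),
    residue_seq = at$resno, stringsAsFactors = FALSE
  )
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nf, nat, 3L))
  for (f in seq_len(nf)) coords[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  conformer_ensemble(top, coords, frame_labels = paste0("model_", seq_len(nf)))
}

read_xyz_ensemble <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (!length(lines)) stop("no atoms found in ", path, call. = FALSE)
  frames <- list(); names_ref <- NULL; pos <- 1L; fi <- 0L
  while (pos <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat < 1L)
      stop("XYZ format error at line ", pos, ": expected an atom count",
           call. = FALSE)
    block <- lines[(pos + 2L):(pos + 1L + nat)]
    if (length(block) < nat || anyNA(block))
      stop("XYZ format error: truncated frame at line ", pos, call. = FALSE)
    parts <- strsplit(trimws(block), "[[:space:]]+")
    el <- vapply(parts, `[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3L)))
    fi <- fi + 1L
    if (is.null(names_ref)) names_ref <- el
    else if (length(el) != length(names_ref))
      stop("XYZ format error: frame ", fi, " has ", length(el),
           " atoms but frame 1 has ", length(names_ref), call. = FALSE)
    frames[[fi]] <- xyz
    pos <- pos + 2L + nat
  }
  element <- infer_element(names_ref)
  top <- data.frame(
    name = names_ref, element = element, mass = element_mass(element),
    residue_index = 1L, residue_name = "MOL", residue_seq = 1L,
    stringsAsFactors = FALSE
  )
  coords <- array(NA_real_, dim = c(length(frames), length(names_ref), 3L))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  conformer_ensemble(top, coords)
}

#' Write a conformer ensemble to disk
#'
#' PDB output is multi-model (one MODEL block per frame, coordinates at the
#' standard 3-decimal precision); XYZ output is a concatenation of frames.
#' `write_ensemble()` followed by [read_structure()] reproduces coordinates
#' to the PDB field precision (1e-3 Angstrom).
#'
#' @param ensemble a [conformer_ensemble()].
#' @param path output file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path, format = c("auto", "pdb", "xyz")) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "xyz") "xyz" else "pdb"
  }
  top <- ensemble$topology
  if (format == "pdb") {
    nf <- n_frames(ensemble); nat <- n_atoms(ensemble)
    xyz <- matrix(NA_real_, nrow = nf, ncol = 3L * nat)
    for (f in seq_len(nf)) xyz[f, ] <- t(frame_coords(ensemble, f))
    bio3d::write.pdb(file = path, xyz = xyz, elety = top$name,
                     resid = top$residue_name, resno = top$residue_seq,
                     eleno = seq_len(nat), elesy = top$element)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (f in seq_len(n_frames(ensemble))) {
      m <- frame_coords(ensemble, f)
      writeLines(c(as.character(nrow(m)), paste0("frame ", f)), con)
      writeLines(sprintf("%-3s %12.6f %12.6f %12.6f",
                         top$element, m[, 1L], m[, 2L], m[, 3L]), con)
    }
  }
  invisible(path)
}
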