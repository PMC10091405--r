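# Pyranose ring and glycosidic linkage identification.
#
# Residues are recognized as pyranoses by atom-name pattern (presence of
# O5, C1..C5), not by a residue-name whitelist: PDB and force-field naming
# dialects disagree on residue codes, while the ring atom names are stable.

.ring_atom_names <- c("O5", "C1", "C2", "C3", "C4", "C5")

#' Identify pyranose rings
#'
#' One ring per residue containing the six canonically named ring atoms
#' O5, C1, C2, C3, C4, C5.  Residues lacking any of the six names are
#' skipped with a warning.  Terminal residues (first and last of the chain)
#' are flagged: ring-pucker artifacts concentrate at chain termini and
#' reports keep them visible rather than filtered.
#'
#' @param topology a topology data.frame.
#' @param warn emit a warning for each skipped residue (default `TRUE`).
#' @return data.frame with one row per ring: `residue_index`,
#'   `residue_name`, `terminal`, and atom-index columns `o5`, `c1` .. `c5`.
#' @export
identify_rings <- function(topology, warn = TRUE) {
  res <- sort(unique(topology$residue_index))
  rows <- lapply(res, function(r) {
    in_res <- which(topology$residue_index == r)
    pos <- match(.ring_atom_names, topology$name[in_res])
    if (anyNA(pos)) {
      if (warn)
        warning("residue ", r, " (", topology$residue_name[in_res[1L]],
                ") lacks ring atoms ",
                paste(.ring_atom_names[is.na(pos)], collapse = ","),
                "; skipped", call. = FALSE)
      return(NULL)
    }
    idx <- in_res[pos]
    data.frame(residue_index = r,
               residue_name = topology$residue_name[in_res[1L]],
               terminal = r == res[1L] || r == res[length(res)],
               o5 = idx[1L], c1 = idx[2L], c2 = idx[3L], c3 = idx[4L],
               c4 = idx[5L], c5 = idx[6L], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows))
    return(data.frame(residue_index = integer(), residue_name = character(),
                      terminal = logical(), o5 = integer(), c1 = integer(),
                      c2 = integer(), c3 = integer(), c4 = integer(),
                      c5 = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Identify glycosidic linkages between adjacent residues
#'
#' For every adjacent residue pair (n, n+1) in chain order, builds the
#' 1->4 glycosidic torsion definitions
#' phi = O5(n+1)-C1(n+1)-O4(n)-C4(n) and psi = C1(n+1)-O4(n)-C4(n)-C3(n).
#' The linkage type is recorded as the ordered residue-name pair
#' `"<name(n+1)>-><name(n)>"` (e.g. `"GlcNS6S->IdoA2S"` after aliasing).
#' Pairs whose n-th residue lacks O4 or C3, or whose (n+1)-th residue lacks
#' O5 or C1, are skipped with a warning.
#'
#' @param topology a topology data.frame.
#' @param aliases optional named character vector mapping residue codes to
#'   display names, e.g. `c(SGN = "GlcNS6S", IDS = "IdoA2S")`.
#' @return data.frame with one row per linkage: `residue_prev`,
#'   `residue_next`, `linkage_type`, and atom-index columns `phi1..phi4`,
#'   `psi1..psi4`.  A linear n-residue chain yields n-1 rows.
#' @export
identify_glycosidic_linkages <- function(topology, aliases = NULL) {
  res <- sort(unique(topology$residue_index))
  disp <- function(code) {
    if (!is.null(aliases) && code %in% names(aliases)) aliases[[code]] else code
  }
  rows <- list()
  for (k in seq_len(length(res) - 1L)) {
    rn <- res[k]; rn1 <- res[k + 1L]
    in_n <- which(topology$residue_index == rn)
    in_n1 <- which(topology$residue_index == rn1)
    o4 <- in_n[match("O4", topology$name[in_n])]
    c4 <- in_n[match("C4", topology$name[in_n])]
    c3 <- in_n[match("C3", topology$name[in_n])]
    o5 <- in_n1[match("O5", topology$name[in_n1])]
    c1 <- in_n1[match("C1", topology$name[in_n1])]
    if (anyNA(c(o4, c4, c3, o5, c1))) {
      warning("linkage ", rn, "-", rn1,
              " skipped: missing O4/C4/C3 or O5/C1", call. = FALSE)
      next
    }
    name_n <- disp(topology$residue_name[in_n[1L]])
    name_n1 <- disp(topology$residue_name[in_n1[1L]])
    rows[[length(rows) + 1L]] <- data.frame(
      residue_prev = rn, residue_next = rn1,
      linkage_type = paste0(name_n1, "->", name_n),
      phi1 = o5, phi2 = c1, phi3 = o4, phi4 = c4,
      psi1 = c1, psi2 = o4, psi3 = c4, psi4 = c3,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(residue_prev = integer(), residue_next = integer(),
                      linkage_type = character(), phi1 = integer(),
                      phi2 = integer(), phi3 = integer(), phi4 = integer(),
                      psi1 = integer(), psi2 = integer(), psi3 = integer(),
                      psi4 = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
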