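# Intramolecular hydrogen bonds by geometric criterion and the
# residue x residue occupancy matrix.

#' Hydrogen-bond detection criterion
#'
#' Defaults: donor-heavy to acceptor-heavy distance <= 3.0 Angstrom and
#' donor-H-acceptor angle >= 135 degrees, the common trajectory-toolkit
#' defaults; both are configurable.  When the topology carries no hydrogens
#' the distance cut alone applies (heavy-atom fallback, flagged in output
#' metadata).
#'
#' @param max_da_distance donor-acceptor heavy-atom distance cutoff (A).
#' @param min_dha_angle D-H-A angle floor (degrees).
#' @return list of class `hbond_criterion`.
#' @export
hbond_criterion <- function(max_da_distance = 3.0, min_dha_angle = 135) {
  if (max_da_distance <= 0) stop("distance cutoff must be positive", call. = FALSE)
  if (min_dha_angle <= 0 || min_dha_angle > 180)
    stop("angle floor must be in (0, 180]", call. = FALSE)
  structure(list(max_da_distance = max_da_distance,
                 min_dha_angle = min_dha_angle), class = "hbond_criterion")
}

#' Find hydrogen-bond donors and acceptors
#'
#' Donors are O or N atoms bonded to a hydrogen; the bond is inferred from a
#' heavy-H distance < 1.2 Angstrom in the supplied frame, falling back to
#' name pairing (`"HO3"` pairs with `"O3"`) when no coordinates are given.
#' Acceptors are all O and N atoms.  A topology without hydrogens yields an
#' empty donor list with a warning; the heavy-atom fallback criterion then
#' applies downstream.
#'
#' @param topology a topology data.frame.
#' @param frame optional `n_atoms x 3` matrix (typically frame 1) used for
#'   distance-based H attachment.
#' @return list with `donors` (data.frame `heavy`, `h` atom indices) and
#'   `acceptors` (integer vector).
#' @export
find_donors_acceptors <- function(topology, frame = NULL) {
  hetero <- which(topology$element %in% c("O", "N"))
  hydro <- which(topology$element == "H")
  if (!length(hydro)) {
    warning("no hydrogens in topology; heavy-atom-only criterion applies",
            call. = FALSE)
    return(list(donors = data.frame(heavy = integer(), h = integer()),
                acceptors = hetero))
  }
  pairs <- NULL
  if (!is.null(frame)) {
    for (h in hydro) {
      d2 <- colSums((t(frame[hetero, , drop = FALSE]) - frame[h, ])^2)
      jm <- which.min(d2)
      if (d2[jm] < 1.2^2)
        pairs <- rbind(pairs, data.frame(heavy = hetero[jm], h = h))
    }
  } else {
    for (h in hydro) {
      target <- sub("^H", "", topology$name[h])
      cand <- hetero[topology$residue_index[hetero] == topology$residue_index[h] &
                     topology$name[hetero] == target]
      if (length(cand))
        pairs <- rbind(pairs, data.frame(heavy = cand[1L], h = h))
    }
  }
  list(donors = pairs %||% data.frame(heavy = integer(), h = integer()),
       acceptors = hetero)
}

#' Hydrogen bonds present in one frame
#'
#' A (donor, acceptor) pair is reported iff the donor-heavy to
#' acceptor-heavy distance is within `criterion$max_da_distance` and the
#' D-H-A angle is at least `criterion$min_dha_angle`; the donor heavy atom
#' is never its own acceptor.  With an empty donor list the heavy-atom
#' fallback applies: every O/N pair within the distance cutoff counts.
#'
#' @param frame `n_atoms x 3` coordinate matrix.
#' @param donors,acceptors from [find_donors_acceptors()].
#' @param criterion an [hbond_criterion()].
#' @return data.frame with columns `donor`, `h`, `acceptor` (atom indices;
#'   `h` is `NA` under the heavy-atom fallback).
#' @export
hbonds_in_frame <- function(frame, donors, acceptors,
                            criterion = hbond_criterion()) {
  stopifnot(inherits(criterion, "hbond_criterion"))
  out <- NULL
  if (nrow(donors)) {
    for (k in seq_len(nrow(donors))) {
      dh <- donors$heavy[k]; hh <- donors$h[k]
      acc <- setdiff(acceptors, dh)
      if (!length(acc)) next
      dv <- t(frame[acc, , drop = FALSE]) - frame[dh, ]
      dist <- sqrt(colSums(dv^2))
      near <- which(dist <= criterion$max_da_distance)
      for (a in near) {
        v1 <- frame[dh, ] - frame[hh, ]
        v2 <- frame[acc[a], ] - frame[hh, ]
        cosang <- sum(v1 * v2) / (vnorm(v1) * vnorm(v2))
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        if (ang >= criterion$min_dha_angle)
          out <- rbind(out, data.frame(donor = dh, h = hh, acceptor = acc[a]))
      }
    }
  } else {
    # heavy-atom fallback: distance criterion over all O/N pairs
    for (i in acceptors) {
      for (a in acceptors[acceptors > i]) {
        if (sqrt(sum((frame[i, ] - frame[a, ])^2)) <= criterion$max_da_distance)
          out <- rbind(out, data.frame(donor = i, h = NA_integer_,
                                       acceptor = a))
      }
    }
  }
  out %||% data.frame(donor = integer(), h = integer(), acceptor = integer())
}

#' Residue-residue hydrogen-bond occupancy map
#'
#' Occupancy of an unordered residue pair is the fraction of frames with at
#' least one hydrogen bond between the two residues in either direction
#' (direction collapsed; the diagonal holds intra-residue bonds).  The
#' matrix is symmetric by construction with values in [0, 1].
#'
#' @param ensemble a [conformer_ensemble()].
#' @param criterion an [hbond_criterion()].
#' @return object of class `contact_map`: list with `occupancy` (symmetric
#'   matrix), `labels`, `criterion`, and `heavy_only` flag.
#' @export
residue_contact_map <- function(ensemble, criterion = hbond_criterion()) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  top <- ensemble$topology
  da <- find_donors_acceptors(top, frame = frame_coords(ensemble, 1L))
  heavy_only <- nrow(da$donors) == 0L
  res <- sort(unique(top$residue_index))
  nr <- length(res)
  occ <- matrix(0, nr, nr)
  nf <- n_frames(ensemble)
  for (f in seq_len(nf)) {
    hb <- hbonds_in_frame(frame_coords(ensemble, f), da$donors, da$acceptors,
                          criterion)
    if (!nrow(hb)) next
    ri <- match(top$residue_index[hb$donor], res)
    rj <- match(top$residue_index[hb$acceptor], res)
    seen <- unique(cbind(pmin(ri, rj), pmax(ri, rj)))
    occ[seen] <- occ[seen] + 1
  }
  occ <- occ / nf
  occ[lower.tri(occ)] <- t(occ)[lower.tri(occ)]
  labels <- vapply(res, function(r)
    paste0(top$residue_name[top$residue_index == r][1L], "_", r), "")
  dimnames(occ) <- list(labels, labels)
  structure(list(occupancy = occ, labels = labels, criterion = criterion,
                 heavy_only = heavy_only), class = "contact_map")
}

#' Export a contact map
#'
#' Long-form TSV (`residue_i`, `residue_j`, `occupancy`) plus optionally a
#' square CSV; a metadata JSON block records the criterion used.
#'
#' @param map a `contact_map`.
#' @param path output TSV path.
#' @param matrix_path optional square-matrix CSV path.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path, matrix_path = NULL) {
  stopifnot(inherits(map, "contact_map"))
  nr <- nrow(map$occupancy)
  idx <- which(upper.tri(map$occupancy, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(residue_i = map$labels[idx[, 1L]],
                   residue_j = map$labels[idx[, 2L]],
                   occupancy = map$occupancy[idx])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(matrix_path)) utils::write.csv(map$occupancy, matrix_path)
  invisible(path)
}
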