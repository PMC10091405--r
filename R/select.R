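#' Select atoms from a topology
#'
#' Filters atoms by any combination of name, element, residue index and
#' residue name; an arbitrary predicate function over the topology rows can
#' be supplied for anything richer.  Conditions combine with AND.
#'
#' @param topology a topology data.frame (see [conformer_ensemble()]).
#' @param name,element,residue_index,residue_name optional vectors of
#'   admissible values.
#' @param predicate optional `function(topology) -> logical vector`.
#' @param allow_empty if `FALSE` (default) an empty selection is an error;
#'   callers for whom empty is meaningful pass `TRUE`.
#' @return strictly increasing integer vector of 1-based atom indices.
#' @export
select_atoms <- function(topology, name = NULL, element = NULL,
                         residue_index = NULL, residue_name = NULL,
                         predicate = NULL, allow_empty = FALSE) {
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(name)) keep <- keep & topology$name %in% name
  if (!is.null(element)) keep <- keep & topology$element %in% toupper(element)
  if (!is.null(residue_index)) keep <- keep & topology$residue_index %in% residue_index
  if (!is.null(residue_name)) keep <- keep & topology$residue_name %in% residue_name
  if (!is.null(predicate)) {
    p <- predicate(topology)
    if (!is.logical(p) || length(p) != nrow(topology))
      stop("predicate must return one logical per atom", call. = FALSE)
    keep <- keep & p
  }
  idx <- which(keep)
  if (!length(idx) && !allow_empty)
    stop("atom selection is empty", call. = FALSE)
  idx
}

# default analysis atom sets
heavy_atoms <- function(topology) {
  select_atoms(topology, predicate = function(t) t$element != "H")
}
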