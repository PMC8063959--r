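# Curated sugar-moiety library analysis: stereoisomer grouping,
# detectability classification under given settings, and stereo-insensitive
# substructure frequency counting in a target collection.

#' Group a moiety library by stereoisomers
#'
#' Entries whose stereo-erased canonical SMILES coincide are merged into one
#' representative (the first in input order) whose id is the concatenation of
#' the member ids, in input order.
#'
#' @param mols a `mol_collection`
#' @param sep separator for concatenated ids
#' @return a `mol_collection` of group representatives, with attribute
#'   `groups`: data.frame(entry_id, group_key, size)
#' @export
group_stereoisomers <- function(mols, sep = "_") {
  keys <- collection_keys(mols)
  grp <- split(seq_along(mols), keys$without_stereo)
  # preserve input order of first appearance
  first <- vapply(grp, min, integer(1))
  grp <- grp[order(first)]
  reps <- list(); rows <- list()
  for (g in grp) {
    rep_idx <- g[1]
    rep <- mols[[rep_idx]]
    rep$id <- paste(keys$id[g], collapse = sep)
    reps[[length(reps) + 1L]] <- rep
    rows[[length(rows) + 1L]] <- data.frame(
      entry_id = rep$id, group_key = keys$without_stereo[rep_idx],
      size = length(g), stringsAsFactors = FALSE)
  }
  structure(reps, class = "mol_collection",
            rejects = attr(mols, "rejects"),
            groups = do.call(rbind, rows))
}

#' Classify library entries by detectability
#'
#' An entry is positive when detection on the standalone moiety structure
#' returns at least one accepted sugar (circular or linear) under the given
#' settings.
#'
#' @param mols a (grouped) `mol_collection`
#' @param cs,ls circular / linear detection settings
#' @return logical vector along `mols`
#' @export
classify_detectability <- function(mols, cs = circular_settings(),
                                   ls = linear_settings()) {
  vapply(mols, function(m) {
    circ <- detect_circular_sugars(m, cs)
    if (length(circ)) return(TRUE)
    length(detect_linear_sugars(m, ls, circ)) > 0L
  }, logical(1))
}

# --- substructure matching --------------------------------------------------

elem_codes <- function(elems, universe) as.integer(factor(elems, levels = universe))

#' Test whether a pattern molecule occurs as a substructure of a target
#'
#' Monomorphism on the heavy-atom graph: every pattern atom maps to a
#' distinct target atom of the same element and every pattern bond to a
#' target bond of the same order; target atoms may carry additional
#' substituents (attachment points are unconstrained) and stereochemistry is
#' ignored (graphs are constitution-only).
#'
#' @param pattern,target `molecule` objects
#' @return logical
#' @export
is_substructure <- function(pattern, target) {
  if (length(pattern$atoms) > length(target$atoms)) return(FALSE)
  if (!all(pattern$atoms %in% target$atoms)) return(FALSE)
  universe <- unique(c(pattern$atoms, target$atoms))
  gp <- mol_igraph(pattern); gt <- mol_igraph(target)
  # vf2 color arguments follow graph.subisomorphic.vf2(graph1 = target,
  # graph2 = pattern)
  igraph::subgraph_isomorphic(
    gp, gt, method = "vf2",
    vertex.color1 = elem_codes(target$atoms, universe),
    vertex.color2 = elem_codes(pattern$atoms, universe),
    edge.color1 = if (nrow(target$bonds)) as.integer(target$bonds$order) else NULL,
    edge.color2 = if (nrow(pattern$bonds)) as.integer(pattern$bonds$order) else NULL)
}

#' Substructure frequencies of a moiety library in a collection
#'
#' Counts, per library entry, the number of collection molecules that contain
#' the entry as a stereo-insensitive substructure (presence per molecule, not
#' embeddings). Optionally classifies each entry's detectability and filters
#' the report to a minimum frequency.
#'
#' @param library a (grouped) `mol_collection` of moiety entries
#' @param collection target `mol_collection`
#' @param cs,ls settings used for the detectability column
#' @param min_frequency report only entries matched at least this often
#'   (0 reports everything)
#' @return data.frame(entry_id, group_key, detectable, frequency) sorted
#'   by descending frequency
#' @export
substructure_frequency <- function(library, collection,
                                   cs = circular_settings(),
                                   ls = linear_settings(),
                                   min_frequency = 0L) {
  det <- classify_detectability(library, cs, ls)
  grows <- attr(library, "groups")
  keys <- if (is.null(grows)) collection_keys(library)$without_stereo else grows$group_key
  freq <- vapply(library, function(entry) {
    sum(vapply(collection, function(tgt) is_substructure(entry, tgt), logical(1)))
  }, integer(1))
  out <- data.frame(entry_id = vapply(library, function(m) m$id, character(1)),
                    group_key = keys,
                    detectable = det,
                    frequency = freq,
                    stringsAsFactors = FALSE)
  out <- out[out$frequency >= min_frequency, , drop = FALSE]
  out <- out[order(-out$frequency, out$entry_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
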