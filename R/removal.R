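# Terminal/non-terminal classification and iterative sugar removal.
#
# A moiety is terminal when excising its atoms from the current structure
# does not split the remainder into two or more fragments that each reach
# the preservation threshold; sub-threshold fragments are discarded (and
# tallied). Removal iterates: detect, excise every currently-terminal
# moiety, drop sub-threshold fragments, re-detect, until nothing terminal
# remains.

#' Settings for sugar removal
#'
#' @param remove_only_terminal remove only terminal moieties (default TRUE);
#'   when FALSE non-terminal moieties are excised too and the multi-fragment
#'   remainder is kept (each fragment at or above the threshold)
#' @param preservation_threshold minimum heavy-atom count for a disconnected
#'   fragment to survive removal (default 5)
#' @return a `removal_settings` object
#' @export
removal_settings <- function(remove_only_terminal = TRUE,
                             preservation_threshold = 5L) {
  stopifnot(preservation_threshold >= 1L)
  structure(list(remove_only_terminal = isTRUE(remove_only_terminal),
                 preservation_threshold = as.integer(preservation_threshold)),
            class = "removal_settings")
}

# Atom set a moiety takes with it on removal: ring + its exocyclic oxygens,
# or chain + its oxygens.
moiety_atoms <- function(x) {
  if (inherits(x, "sugar_ring_candidate")) c(x$ring_atoms, x$exo_oxygens)
  else c(x$chain_atoms, x$oxygen_atoms)
}

moiety_record <- function(x, m, terminal) {
  circ <- inherits(x, "sugar_ring_candidate")
  list(moiety_type = if (circ) "circular" else "linear",
       atoms = orig_atoms(m, moiety_atoms(x)),
       terminal = terminal,
       class = if (circ) x$ring_class else x$size_class,
       glycosidic_bond = if (circ) x$has_glycosidic_bond else NA,
       n_exo = if (circ) x$n_exo else NA_integer_,
       r_exo = if (circ) x$r_exo else NA_real_)
}

# Would excising `atoms` leave >= 2 fragments each at/above the threshold?
splits_remainder <- function(m, atoms, threshold) {
  rest <- setdiff(seq_along(m$atoms), atoms)
  if (!length(rest)) return(FALSE)
  sub <- subset_molecule(m, rest)
  comp <- mol_components(sub)
  sum(lengths(comp) >= threshold) >= 2L
}

#' Remove sugar moieties from a molecule
#'
#' Runs the iterative detection/removal loop and returns the aglycone with a
#' full account of every removed and retained moiety and every discarded
#' sub-threshold fragment. Atom indices in the records refer to the input
#' molecule, so heavy atoms are conserved exactly:
#' input = aglycone + removed moieties + discarded fragments.
#'
#' @param m a `molecule`
#' @param rs [removal_settings()]
#' @param cs [circular_settings()]
#' @param ls [linear_settings()]
#' @param detect one of `"both"`, `"circular"`, `"linear"`
#' @return a `deglyco_result`: list with `aglycone` (a `molecule`, or NULL if
#'   nothing remains), `removed` (list of moiety records, `terminal = TRUE`),
#'   `retained` (non-terminal moieties still present under terminal-only
#'   removal), `discarded_fragments` (list of original-index atom sets),
#'   `consists_only_of_sugars` (logical)
#' @export
remove_sugars <- function(m, rs = removal_settings(),
                          cs = circular_settings(), ls = linear_settings(),
                          detect = c("both", "circular", "linear")) {
  stopifnot(inherits(m, "molecule"))
  detect <- match.arg(detect)
  # Detection runs once, on the intact molecule; the iterative phase only
  # re-evaluates terminality of the detected set as atoms disappear. (Peeling
  # a sugar chain takes the bridging oxygen with the outer sugar, which can
  # drop the inner ring's exocyclic-oxygen count below the threshold; a
  # re-detection loop would then strand chains of ratio-marginal sugars such
  # as 2,6-dideoxy pyranoses.)
  circ <- if (detect != "linear") detect_circular_sugars(m, cs) else list()
  lin <- if (detect != "circular") detect_linear_sugars(m, ls, circ) else list()
  moieties <- c(circ, lin)
  moieties <- moieties[order(vapply(moieties, function(x) min(moiety_atoms(x)),
                                    integer(1)))]
  alive <- rep(TRUE, length(m$atoms))
  removed <- list(); discarded <- list()
  pending <- moieties
  while (length(pending)) {
    cur <- subset_molecule(m, which(alive))
    if (rs$remove_only_terminal) {
      term <- vapply(pending, function(x) {
        at <- intersect(moiety_atoms(x), which(alive))
        !splits_remainder(cur, match(at, which(alive)), rs$preservation_threshold)
      }, logical(1))
      if (!any(term)) break
      todo <- pending[term]; pending <- pending[!term]
    } else {
      todo <- pending; pending <- list()
    }
    for (x in todo) {
      at <- intersect(moiety_atoms(x), which(alive))
      rec <- moiety_record(x, m, terminal = rs$remove_only_terminal)
      rec$atoms <- orig_atoms(m, at)
      removed[[length(removed) + 1L]] <- rec
      alive[at] <- FALSE
    }
    if (!any(alive)) { pending <- list(); break }
    # discard sub-threshold fragments arising from this round
    aw <- which(alive)
    sub <- subset_molecule(m, aw)
    comp <- mol_components(sub)
    for (fr in comp[lengths(comp) < rs$preservation_threshold]) {
      discarded[[length(discarded) + 1L]] <- orig_atoms(sub, fr)
      alive[aw[fr]] <- FALSE
    }
    if (!any(alive)) { pending <- list(); break }
  }
  retained <- lapply(pending, function(x) {
    rec <- moiety_record(x, m, terminal = FALSE)
    rec$atoms <- orig_atoms(m, intersect(moiety_atoms(x), which(alive)))
    rec
  })
  cur <- if (any(alive)) subset_molecule(m, which(alive)) else NULL
  consists_only <- is.null(cur) && length(removed) > 0L
  structure(list(input = m,
                 aglycone = cur,
                 removed = removed,
                 retained = retained,
                 discarded_fragments = discarded,
                 consists_only_of_sugars = consists_only,
                 settings = list(removal = rs, circular = cs, linear = ls,
                                 detect = detect)),
            class = "deglyco_result")
}

#' @export
print.deglyco_result <- function(x, ...) {
  cat(sprintf("<deglyco_result %s: %d removed, %d retained, %s>\n",
              x$input$id, length(x$removed), length(x$retained),
              if (x$consists_only_of_sugars) "consists only of sugars"
              else if (is.null(x$aglycone)) "empty remainder"
              else sprintf("aglycone %d heavy atoms", length(x$aglycone$atoms))))
  invisible(x)
}

#' Classify every detectable moiety of a molecule as terminal or non-terminal
#'
#' Two passes: terminal-only removal labels everything it removes as
#' terminal; a subsequent remove-all pass on the remaining aglycone labels
#' the rest as non-terminal (cascading until no moiety is detectable).
#'
#' @inheritParams remove_sugars
#' @return list of moiety records (`moiety_type`, `atoms` in input indexing,
#'   `terminal`, `class`, `glycosidic_bond`, `n_exo`, `r_exo`)
#' @export
classify_terminality <- function(m, rs = removal_settings(),
                                 cs = circular_settings(), ls = linear_settings(),
                                 detect = "both") {
  pass1 <- remove_sugars(m, removal_settings(TRUE, rs$preservation_threshold),
                         cs, ls, detect)
  recs <- pass1$removed
  if (!is.null(pass1$aglycone)) {
    # map the aglycone back so its records carry input indices
    pass2 <- remove_sugars(pass1$aglycone,
                           removal_settings(FALSE, rs$preservation_threshold),
                           cs, ls, detect)
    for (r in pass2$removed) {
      r$terminal <- FALSE
      recs[[length(recs) + 1L]] <- r
    }
  }
  recs
}

#' Extract removed moieties as standalone structures
#'
#' Each removed moiety (ring plus its exocyclic oxygens, or chain plus its
#' oxygens) is exported as its own molecule; open valences are saturated
#' with implicit hydrogens when the structure is written as SMILES.
#'
#' @param result a `deglyco_result` from [remove_sugars()]
#' @return a `mol_collection` of extracted moieties (empty for sugar-free
#'   input)
#' @export
extract_moieties <- function(result) {
  stopifnot(inherits(result, "deglyco_result"))
  m <- result$input
  out <- list()
  for (k in seq_along(result$removed)) {
    rec <- result$removed[[k]]
    sub <- subset_molecule(m, rec$atoms, id = paste0(m$id, "_moiety", k))
    sub$smiles <- NA_character_
    out[[length(out) + 1L]] <- sub
  }
  structure(out, class = "mol_collection",
            rejects = data.frame(line = integer(), text = character(),
                                 reason = character(), stringsAsFactors = FALSE))
}
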