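#' glycoscan: sugar-moiety detection, removal and glycosylation statistics
#'
#' Detects circular (furanose/pyranose/heptose ring) and linear (open-chain)
#' sugar moieties in molecular structures, classifies them as terminal or
#' non-terminal, removes terminal sugars to expose aglycones, and aggregates
#' dataset-level glycosylation statistics. Includes stereoisomer grouping,
#' library substructure-frequency analysis, MaxMin diversity curation, and a
#' ground-truth synthetic glycoside generator.
#'
#' @keywords internal
"_PACKAGE"

#' Run the full glycosylation analysis of a collection
#'
#' Profiles every molecule (detection, terminality, removal), aggregates the
#' statistics taxonomy, and computes the moiety-count and exocyclic-ratio
#' histograms.
#'
#' @param mols a `mol_collection` from [read_collection()] or
#'   [parse_smiles()]
#' @param rs,cs,ls removal / circular / linear settings
#' @param progress log progress every 1000 molecules
#' @return a `glyco_analysis` object: list with `profiles`, `stats`,
#'   `moiety_histogram`, `ratio_histogram`, `settings`
#' @export
#' @examples
#' \donttest{
#' mols <- parse_smiles(c("OCC1OC(Oc2ccccc2)C(O)C(O)C1O", "Cc1ccccc1"),
#'                      c("phenyl-glucoside", "toluene"))
#' res <- glyco_analysis(mols)
#' print(res)
#' }
glyco_analysis <- function(mols, rs = removal_settings(),
                           cs = circular_settings(), ls = linear_settings(),
                           progress = FALSE) {
  profiles <- profile_collection(mols, rs, cs, ls, progress = progress)
  stats <- aggregate_stats(profiles)
  structure(list(profiles = profiles,
                 stats = stats,
                 moiety_histogram = moiety_count_histogram(profiles),
                 ratio_histogram = ratio_histogram(mols, cs),
                 settings = list(removal = rs, circular = cs, linear = ls)),
            class = "glyco_analysis")
}

#' @export
print.glyco_analysis <- function(x, ...) {
  print(x$stats)
  invisible(x)
}

#' @export
summary.glyco_analysis <- function(object, ...) {
  ms <- object$stats$molecule_stats
  get_cnt <- function(f) ms$count[ms$field == f]
  cat(sprintf("%d molecules, %d (%.2f%%) with sugar moieties\n",
              object$stats$n_molecules, get_cnt("has_sugars"),
              if (object$stats$n_molecules) 100 * get_cnt("has_sugars") / object$stats$n_molecules else 0))
  cat(sprintf("  circular: %d molecules, linear: %d, both: %d\n",
              get_cnt("has_circular"), get_cnt("has_linear"), get_cnt("has_both")))
  cat(sprintf("  consists only of sugars: %d\n", get_cnt("consists_only_of_sugars")))
  cat(sprintf("  total moieties: %d\n", object$stats$n_moieties))
  invisible(object)
}
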