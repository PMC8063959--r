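# Per-molecule glycosylation profiles and dataset-level aggregation.

profile_fields <- c(
  "has_sugars", "has_circular", "has_only_circular", "has_linear",
  "has_only_linear", "has_both", "consists_only_of_sugars",
  "is_sugar_monomer", "is_circular_monomer", "is_linear_monomer",
  "is_sugar_polymer",
  "has_terminal_circular", "has_only_terminal_circular",
  "has_nonterminal_circular", "has_only_nonterminal_circular",
  "has_both_terminal_kinds_circular",
  "has_terminal_linear", "has_only_terminal_linear",
  "has_nonterminal_linear", "has_only_nonterminal_linear",
  "has_both_terminal_kinds_linear")

#' Glycosylation profile of a single molecule
#'
#' Runs terminality classification (two removal passes) and derives the full
#' set of per-molecule booleans and counters: presence of circular/linear
#' sugars, sugar-only composition (monomer/polymer), and the terminal /
#' non-terminal breakdown per moiety type.
#'
#' @param m a `molecule`
#' @param rs,cs,ls removal / circular / linear settings
#' @return one-row data.frame (class `glyco_profile`) with the boolean
#'   fields, counters `n_circular`, `n_linear`, `n_total`, and `id`
#' @export
profile_molecule <- function(m, rs = removal_settings(),
                             cs = circular_settings(), ls = linear_settings()) {
  res <- remove_sugars(m, removal_settings(TRUE, rs$preservation_threshold), cs, ls)
  recs <- classify_terminality(m, rs, cs, ls)
  profile_from_records(m$id, recs, res$consists_only_of_sugars)
}

profile_from_records <- function(id, recs, consists_only) {
  type <- vapply(recs, function(r) r$moiety_type, character(1))
  term <- vapply(recs, function(r) r$terminal, logical(1))
  n_c <- sum(type == "circular"); n_l <- sum(type == "linear")
  ct <- sum(type == "circular" & term); cn <- sum(type == "circular" & !term)
  lt <- sum(type == "linear" & term); ln <- sum(type == "linear" & !term)
  n <- n_c + n_l
  p <- data.frame(
    id = id,
    has_sugars = n > 0L,
    has_circular = n_c > 0L,
    has_only_circular = n_c > 0L && n_l == 0L,
    has_linear = n_l > 0L,
    has_only_linear = n_l > 0L && n_c == 0L,
    has_both = n_c > 0L && n_l > 0L,
    consists_only_of_sugars = consists_only,
    is_sugar_monomer = consists_only && n == 1L,
    is_circular_monomer = consists_only && n == 1L && n_c == 1L,
    is_linear_monomer = consists_only && n == 1L && n_l == 1L,
    is_sugar_polymer = consists_only && n >= 2L,
    has_terminal_circular = ct > 0L,
    has_only_terminal_circular = ct > 0L && cn == 0L,
    has_nonterminal_circular = cn > 0L,
    has_only_nonterminal_circular = cn > 0L && ct == 0L,
    has_both_terminal_kinds_circular = ct > 0L && cn > 0L,
    has_terminal_linear = lt > 0L,
    has_only_terminal_linear = lt > 0L && ln == 0L,
    has_nonterminal_linear = ln > 0L,
    has_only_nonterminal_linear = ln > 0L && lt == 0L,
    has_both_terminal_kinds_linear = lt > 0L && ln > 0L,
    n_circular = n_c, n_linear = n_l, n_total = n,
    stringsAsFactors = FALSE)
  class(p) <- c("glyco_profile", "data.frame")
  p
}

#' Profile every molecule of a collection
#'
#' @param mols a `mol_collection`
#' @inheritParams profile_molecule
#' @param progress print progress every 1000 molecules
#' @return data.frame (class `glyco_profiles`), one row per molecule, plus an
#'   attribute `moieties`: the full list of moiety records across molecules
#'   (with a `mol_id` element each)
#' @export
profile_collection <- function(mols, rs = removal_settings(),
                               cs = circular_settings(), ls = linear_settings(),
                               progress = FALSE) {
  rows <- vector("list", length(mols))
  moieties <- list()
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    res <- remove_sugars(m, removal_settings(TRUE, rs$preservation_threshold), cs, ls)
    recs <- classify_terminality(m, rs, cs, ls)
    rows[[k]] <- profile_from_records(m$id, recs, res$consists_only_of_sugars)
    for (r in recs) { r$mol_id <- m$id; moieties[[length(moieties) + 1L]] <- r }
    if (progress && k %% 1000L == 0L)
      message(sprintf("profiled %d/%d molecules", k, length(mols)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("glyco_profiles", "data.frame")
  attr(out, "moieties") <- moieties
  attr(out, "settings") <- list(removal = rs, circular = cs, linear = ls)
  out
}

#' Aggregate dataset-level glycosylation statistics
#'
#' Computes the molecule-level and moiety-level statistics taxonomy: counts
#' and percentages for every profile field (percentages against the dataset
#' size), the moiety-type breakdown (circular/linear, terminal/non-terminal,
#' ring classes, chain sizes; percentages against total moieties), and the
#' moiety-count histogram. All partition identities hold exactly by
#' construction and are re-checked here.
#'
#' @param profiles a `glyco_profiles` data.frame from [profile_collection()]
#' @param moieties optional moiety record list (defaults to the attribute
#'   carried by `profiles`)
#' @return a `glyco_stats` object: list with `molecule_stats` and
#'   `moiety_stats` data.frames (count, percent), `n_molecules`, `n_moieties`
#' @export
aggregate_stats <- function(profiles, moieties = attr(profiles, "moieties")) {
  stopifnot(is.data.frame(profiles))
  n <- nrow(profiles)
  cnt <- vapply(profile_fields, function(f) sum(profiles[[f]]), integer(1))
  mol_stats <- data.frame(field = profile_fields, count = unname(cnt),
                          percent = if (n) round(100 * unname(cnt) / n, 2) else 0,
                          stringsAsFactors = FALSE)
  # partition identities
  stopifnot(
    cnt["has_only_circular"] + cnt["has_only_linear"] + cnt["has_both"] == cnt["has_sugars"],
    cnt["has_only_terminal_circular"] + cnt["has_only_nonterminal_circular"] +
      cnt["has_both_terminal_kinds_circular"] == cnt["has_circular"],
    cnt["has_only_terminal_linear"] + cnt["has_only_nonterminal_linear"] +
      cnt["has_both_terminal_kinds_linear"] == cnt["has_linear"],
    cnt["is_sugar_monomer"] + cnt["is_sugar_polymer"] == cnt["consists_only_of_sugars"])

  type <- vapply(moieties, function(r) r$moiety_type, character(1))
  term <- vapply(moieties, function(r) r$terminal, logical(1))
  cls <- vapply(moieties, function(r) r$class, character(1))
  glyc <- vapply(moieties, function(r) isTRUE(r$glycosidic_bond), logical(1))
  nm <- length(moieties)
  moiety_rows <- list(
    total = nm,
    circular = sum(type == "circular"),
    circular_terminal = sum(type == "circular" & term),
    circular_terminal_glycosidic = sum(type == "circular" & term & glyc),
    linear = sum(type == "linear"),
    linear_terminal = sum(type == "linear" & term),
    terminal = sum(term),
    nonterminal = sum(!term),
    circular_furanose = sum(cls == "furanose"),
    circular_pyranose = sum(cls == "pyranose"),
    circular_heptose = sum(type == "circular" & cls == "heptose"),
    linear_tetrose = sum(cls == "tetrose"),
    linear_pentose = sum(cls == "pentose"),
    linear_hexose = sum(cls == "hexose"),
    linear_heptose = sum(type == "linear" & cls == "heptose"))
  moiety_stats <- data.frame(field = names(moiety_rows),
                             count = unname(unlist(moiety_rows)),
                             percent = if (nm) round(100 * unname(unlist(moiety_rows)) / nm, 2) else 0,
                             stringsAsFactors = FALSE)
  structure(list(molecule_stats = mol_stats, moiety_stats = moiety_stats,
                 n_molecules = n, n_moieties = nm),
            class = "glyco_stats")
}

#' @export
print.glyco_stats <- function(x, ...) {
  cat(sprintf("Glycosylation statistics: %d molecules, %d sugar moieties\n",
              x$n_molecules, x$n_moieties))
  cat("\nMolecule level:\n")
  print(x$molecule_stats, row.names = FALSE)
  cat("\nMoiety level:\n")
  print(x$moiety_stats, row.names = FALSE)
  invisible(x)
}

#' Histogram of sugar-moiety counts per molecule
#'
#' @param profiles a `glyco_profiles` data.frame
#' @return data.frame with `n_total` (number of moieties in a molecule) and
#'   counts of molecules, overall and split into circular-only and
#'   linear-only counters; only sugar-containing molecules contribute
#' @export
moiety_count_histogram <- function(profiles) {
  p <- profiles[profiles$has_sugars, , drop = FALSE]
  if (!nrow(p)) return(data.frame(n_total = integer(), molecules = integer(),
                                  circular = integer(), linear = integer()))
  ns <- sort(unique(p$n_total))
  data.frame(n_total = ns,
             molecules = vapply(ns, function(k) sum(p$n_total == k), integer(1)),
             circular = vapply(ns, function(k) sum(p$n_circular == k & p$n_circular > 0), integer(1)),
             linear = vapply(ns, function(k) sum(p$n_linear == k & p$n_linear > 0), integer(1)))
}

#' Histogram of exocyclic oxygen ratios over candidate rings
#'
#' Enumerates all candidate rings (threshold-free) of a collection and bins
#' their ratios into half-open width-0.1 bins `[x, x+0.1)` from 0 to 2 (the
#' ratio is provably below 2: each ring carbon bears at most two oxygens),
#' split into candidates passing and failing the configured threshold.
#' Option filters (spiro/keto/isolated) are applied before binning so the
#' pass counts sum to the accepted circular-moiety count.
#'
#' @param mols a `mol_collection`
#' @param settings [circular_settings()] providing the threshold and option
#'   filters
#' @return data.frame with `lower`, `upper`, `pass`, `fail` counts
#' @export
ratio_histogram <- function(mols, settings = circular_settings()) {
  lower <- round(seq(0, 1.9, by = 0.1), 1)
  pass <- fail <- integer(length(lower))
  open_settings <- settings; open_settings$ratio_threshold <- 0
  for (m in mols) {
    acc <- detect_circular_sugars(m, open_settings)
    for (cand in acc) {
      # r_exo is rational; nudge before flooring so exact tenths bin correctly
      bin <- min(floor(cand$r_exo * 10 + 1e-9) + 1L, length(lower))
      if (cand$r_exo >= settings$ratio_threshold) pass[bin] <- pass[bin] + 1L
      else fail[bin] <- fail[bin] + 1L
    }
  }
  data.frame(lower = lower, upper = lower + 0.1, pass = pass, fail = fail)
}
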