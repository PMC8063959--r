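# Collection curation: diversity-preserving MaxMin subsetting,
# stereo-insensitive cross-set exclusion, stereoisomer grouping statistics.

# Atom-pair descriptors for the whole collection (ChemmineR), used as the
# default similarity backend for MaxMin.
collection_apset <- function(mols) {
  smi <- vapply(mols, function(m) if (!is.na(m$smiles)) m$smiles else mol_to_smiles(m),
                character(1))
  sdf_text <- ob_convert(paste0(smi, " gsidx", seq_along(mols), "\n", collapse = ""),
                         "SMI", "SDF")
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdf_text, tf)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(tf, skipErrors = TRUE))
  if (length(sdfs) != length(mols))
    stop("fingerprint generation lost molecules")
  suppressWarnings(ChemmineR::sdf2ap(sdfs))
}

#' Diversity-preserving MaxMin subset selection
#'
#' Greedy max-min picking: a seeded random start, then repeatedly the
#' molecule whose minimum distance to the already-selected set is largest.
#' Distance is 1 minus the atom-pair Tanimoto similarity unless a custom
#' `dist_fun(i, j)` over collection indices is supplied. Ties are broken by
#' the lexicographically smallest stereo-erased canonical SMILES, making the
#' pick deterministic for a given seed.
#'
#' @param mols a `mol_collection`
#' @param k target subset size
#' @param seed RNG seed for the starting pick
#' @param dist_fun optional distance function `(i, j) -> numeric`
#' @return integer vector of selected indices (length `k`, in pick order)
#' @export
maxmin_subset <- function(mols, k, seed = 1L, dist_fun = NULL) {
  n <- length(mols)
  if (k > n) stop("k exceeds collection size")
  if (k < 1L) stop("k must be positive")
  if (is.null(dist_fun)) {
    ap <- collection_apset(mols)
    dist_fun <- function(i, j)
      1 - ChemmineR::cmp.similarity(ap[i], ap[j])
  }
  keys <- collection_keys(mols)$without_stereo
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  sel <- sample.int(n, 1L)
  if (k == 1L) return(sel)
  mind <- vapply(seq_len(n), function(j) if (j == sel) 0 else dist_fun(sel, j),
                 numeric(1))
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    best <- max(mind[cand])
    tied <- cand[mind[cand] == best]
    nxt <- tied[order(keys[tied])][1]
    sel <- c(sel, nxt)
    for (j in cand) {
      d <- if (j == nxt) 0 else dist_fun(nxt, j)
      if (d < mind[j]) mind[j] <- d
    }
  }
  sel
}

#' Remove molecules matching any reference set, ignoring stereochemistry
#'
#' Matching is keyed on the stereo-erased canonical SMILES, so stereoisomers
#' of reference structures are removed even when not annotated as such.
#'
#' @param mols a `mol_collection`
#' @param references a `mol_collection` or list of them
#' @return the filtered `mol_collection`, with attribute `excluded` giving
#'   the removed indices
#' @export
exclude_matches <- function(mols, references) {
  if (inherits(references, "mol_collection")) references <- list(references)
  ref_keys <- unique(unlist(lapply(references, function(r)
    collection_keys(r)$without_stereo), use.names = FALSE))
  keys <- collection_keys(mols)$without_stereo
  drop <- which(keys %in% ref_keys)
  out <- structure(unclass(mols)[setdiff(seq_along(mols), drop)],
                   class = "mol_collection", rejects = attr(mols, "rejects"))
  attr(out, "excluded") <- drop
  out
}

#' Stereoisomer-grouping statistics, split by glycosylation
#'
#' Groups a collection by stereo-erased canonical SMILES and reports the
#' average number of stereoisomers per normalized structure, separately for
#' sugar-containing and sugar-free representatives.
#'
#' @param mols a `mol_collection` (pre-grouping records)
#' @param has_sugars logical vector along the grouped representatives, or
#'   `NULL` to compute it with default detection settings
#' @param cs,ls detection settings used when `has_sugars` is `NULL`
#' @return list with `n_records`, `n_groups`,
#'   `stereoisomers_per_structure_sugary`,
#'   `stereoisomers_per_structure_sugarfree`, and the grouped collection
#'   (`grouped`)
#' @export
stereo_group_stats <- function(mols, has_sugars = NULL,
                               cs = circular_settings(), ls = linear_settings()) {
  grouped <- group_stereoisomers(mols)
  sizes <- attr(grouped, "groups")$size
  if (is.null(has_sugars)) {
    has_sugars <- vapply(grouped, function(m) {
      circ <- detect_circular_sugars(m, cs)
      length(circ) > 0L || length(detect_linear_sugars(m, ls, circ)) > 0L
    }, logical(1))
  }
  stopifnot(length(has_sugars) == length(grouped))
  avg <- function(sel) if (any(sel)) sum(sizes[sel]) / sum(sel) else NA_real_
  list(n_records = length(mols),
       n_groups = length(grouped),
       stereoisomers_per_structure_sugary = avg(has_sugars),
       stereoisomers_per_structure_sugarfree = avg(!has_sugars),
       grouped = grouped)
}

#' Full curation workflow
#'
#' MaxMin diversity pick, stereo-insensitive exclusion against reference
#' sets, stereoisomer grouping — with a count report of every stage.
#'
#' @param mols input `mol_collection`
#' @param references reference sets for exclusion (may be empty list)
#' @param pick MaxMin target size (`NULL` skips the pick)
#' @param seed seed for the MaxMin start
#' @return list with `collection` (curated) and `report` (a `curation_report`
#'   with the stage counts and stereoisomer averages)
#' @export
curate_collection <- function(mols, references = list(), pick = NULL, seed = 1L) {
  input_size <- length(mols)
  cur <- mols
  if (!is.null(pick)) cur <- cur[maxmin_subset(cur, pick, seed = seed)]
  after_pick <- length(cur)
  if (length(references)) cur <- exclude_matches(cur, references)
  after_excl <- length(cur)
  st <- stereo_group_stats(cur)
  report <- structure(list(
    input_size = input_size,
    after_diversity_pick = after_pick,
    after_exclusion = after_excl,
    after_stereo_grouping = st$n_groups,
    stereoisomers_per_structure_sugary = st$stereoisomers_per_structure_sugary,
    stereoisomers_per_structure_sugarfree = st$stereoisomers_per_structure_sugarfree),
    class = "curation_report")
  list(collection = st$grouped, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report\n")
  cat(sprintf("  input:                 %d\n", x$input_size))
  cat(sprintf("  after diversity pick:  %d\n", x$after_diversity_pick))
  cat(sprintf("  after exclusion:       %d\n", x$after_exclusion))
  cat(sprintf("  after stereo grouping: %d\n", x$after_stereo_grouping))
  cat(sprintf("  stereoisomers/structure (sugar-containing): %s\n",
              format(x$stereoisomers_per_structure_sugary, digits = 4)))
  cat(sprintf("  stereoisomers/structure (sugar-free):       %s\n",
              format(x$stereoisomers_per_structure_sugarfree, digits = 4)))
  invisible(x)
}
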