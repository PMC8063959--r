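# Synthetic glycoside generator: aglycone scaffolds decorated with sugar
# units whose detection outcome is known by construction, plus decoy
# moieties that should only be detected under their matching non-default
# option. Used throughout the test suite as ground truth.

# Scaffold roots: sugar-free cores with two attachment hooks (%s). An empty
# hook leaves a benzylic/alcoholic OH or plain H behind. Validated sugar-free
# by the test suite.
gs_scaffold_roots <- c(
  "Cc1ccc(CO%s)c(CO%s)c1",
  "CC(CCO%s)CCCC(C)CCO%s",
  "c1ccc2c(c1)CC(CO%s)CC2O%s",
  "CC12CCC(O%s)CC1CCC1C2CCC2(C)C(O%s)CCC12"
)

# Substituent scaffolds: first atom bonds to the bridging oxygen of a sugar
# hook, turning that sugar into a bridge between two aglycones.
# Plain alkyl decorations drawn for unused hooks so generated molecules are
# structurally diverse (no two sugar-free molecules need be identical); all
# are sugar-free ether caps.
gs_plain_subs <- c("", "C", "CC", "CCC", "C(C)C", "CCCC", "CC(C)C", "CCCCC")

# (ring labels 8/9: roots hold labels 1/2 open at the hook positions)
gs_scaffold_subs <- c(
  "c8ccc(C)cc8",
  "C8CCC(C)CC8",
  "c8ccc9ccccc9c8",
  "C8CCCCC8"
)

# Sugar unit templates, anomeric position first (bonds to the incoming
# bridging oxygen), %s = chain-extension hook (next unit or substituent
# scaffold; empty leaves a free CH2OH). {R} is replaced by a per-unit SMILES
# ring-closure label so nested units never reuse an open ring number.
gs_circular_units <- list(
  pyranose = "C{R}OC(CO%s)C(O)C(O)C{R}O",
  furanose = "C{R}OC(CO%s)C(O)C{R}O",
  heptose  = "C{R}OC(CO%s)C(O)C(O)C(O)C{R}O"
)
# anomer pair for stereo duplication (same constitution as pyranose template)
gs_pyranose_anomers <- c(
  "[C@@H]{R}O[C@H](CO%s)[C@@H](O)[C@H](O)[C@H]{R}O",
  "[C@H]{R}O[C@H](CO%s)[C@@H](O)[C@H](O)[C@H]{R}O"
)

gs_linear_units <- list(
  tetrose = "CC(O)C(O)CO%s",
  pentose = "CC(O)C(O)C(O)CO%s",
  hexose  = "CC(O)C(O)C(O)C(O)CO%s",
  heptose = "CC(O)C(O)C(O)C(O)C(O)CO%s"
)

# Decoys: structures near the sugar definition that default settings must
# reject; each is detected only under its matching non-default option. Ring
# labels 8/9 cannot clash with the scaffold roots (which use 1/2).
gs_decoy_units <- list(
  pseudosugar     = "C8CC(O)C(O)C(O)C8O",   # carbocycle, no ring oxygen
  keto_ring       = "C8OC(CO)C(=O)C(O)C8O", # ring keto group
  spiro_ring      = "C8OC(CO)C(O)C(O)C89CCCC9", # shares one atom with carbocycle
  acidic_chain    = "CC(O)C(O)C(O)C(=O)O",  # open chain ending in carboxyl
  low_oxygen_ring = "C8OCCCC8O"             # pyranose with 2 exocyclic oxygens
)

#' Specification for the synthetic glycoside generator
#'
#' Defaults emulate the glycosylation structure reported for large natural
#' product collections: about 12 percent of molecules glycosylated, moiety
#' counts following a halving distribution (about half of the glycosides
#' carry a single sugar, the vast majority five or fewer), circular sugars
#' dominating linear ones 96:4, about 20 percent of glycosides carrying their
#' sugar as a bridge between two aglycone parts, and ring classes heavily
#' favouring pyranoses.
#'
#' @param n_molecules number of molecules to generate
#' @param fraction_glycosylated fraction carrying at least one sugar
#' @param sugar_count_distribution probability weights for 1..14 sugars per
#'   glycoside (normalized internally)
#' @param circular_fraction probability that a planted sugar is circular
#' @param bridging_fraction probability that a glycoside's first sugar
#'   bridges two aglycone scaffolds (non-terminal by construction)
#' @param ring_class_weights weights for pyranose/furanose/heptose
#' @param chain_class_weights weights for tetrose/pentose/hexose/heptose
#' @param decoy_rates named rates (applied to sugar-free molecules) for
#'   `pseudosugar`, `keto_ring`, `spiro_ring`, `acidic_chain`,
#'   `low_oxygen_ring`; must sum to at most 1
#' @param stereo_duplication_rate probability that a glycoside is emitted
#'   together with a stereo-flipped duplicate (anomer pair)
#' @param seed RNG seed; identical spec implies identical output
#' @return a `generator_spec`
#' @export
generator_spec <- function(n_molecules = 100L,
                           fraction_glycosylated = 0.12,
                           sugar_count_distribution = 0.5^(1:14),
                           circular_fraction = 0.96,
                           bridging_fraction = 0.2,
                           ring_class_weights = c(pyranose = 0.95, furanose = 0.045, heptose = 0.005),
                           chain_class_weights = c(tetrose = 0.39, pentose = 0.18, hexose = 0.41, heptose = 0.02),
                           decoy_rates = c(pseudosugar = 0, keto_ring = 0, spiro_ring = 0,
                                           acidic_chain = 0, low_oxygen_ring = 0),
                           stereo_duplication_rate = 0,
                           seed = 1L) {
  stopifnot(n_molecules >= 1L,
            fraction_glycosylated >= 0, fraction_glycosylated <= 1,
            length(sugar_count_distribution) == 14L,
            all(sugar_count_distribution >= 0),
            circular_fraction >= 0, circular_fraction <= 1,
            bridging_fraction >= 0, bridging_fraction <= 1,
            all(decoy_rates >= 0), sum(decoy_rates) <= 1,
            stereo_duplication_rate >= 0, stereo_duplication_rate <= 1)
  dr <- c(pseudosugar = 0, keto_ring = 0, spiro_ring = 0,
          acidic_chain = 0, low_oxygen_ring = 0)
  dr[names(decoy_rates)] <- decoy_rates
  structure(list(n_molecules = as.integer(n_molecules),
                 fraction_glycosylated = fraction_glycosylated,
                 sugar_count_distribution = sugar_count_distribution / sum(sugar_count_distribution),
                 circular_fraction = circular_fraction,
                 bridging_fraction = bridging_fraction,
                 ring_class_weights = ring_class_weights / sum(ring_class_weights),
                 chain_class_weights = chain_class_weights / sum(chain_class_weights),
                 decoy_rates = dr,
                 stereo_duplication_rate = stereo_duplication_rate,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

# Build a chain of sugar units (innermost first in the returned SMILES
# nesting); `classes` is a character vector, each either a circular ring
# class or a linear size class; `types` marks circular/linear; `tail` is
# spliced into the outermost unit's hook.
gs_build_chain <- function(types, classes, tail = "", stereo_variant = 0L) {
  s <- tail
  for (k in rev(seq_along(types))) {
    tmpl <- if (types[k] == "circular") {
      if (stereo_variant > 0L && k == 1L && classes[k] == "pyranose")
        gs_pyranose_anomers[stereo_variant]
      else gs_circular_units[[classes[k]]]
    } else gs_linear_units[[classes[k]]]
    tmpl <- gsub("{R}", sprintf("%%%d", 10L + k), tmpl, fixed = TRUE)
    s <- sub("%s", s, tmpl, fixed = TRUE)
  }
  s
}

#' Generate a synthetic glycoside collection with ground truth
#'
#' Sugar-free aglycone scaffolds are decorated with O-linked sugar units:
#' terminal chains (outermost removable first), bridging units connecting two
#' scaffolds (non-terminal by construction), and optional decoys that are
#' undetectable under default settings. Identical specs yield identical
#' output.
#'
#' @param spec a [generator_spec()]
#' @return list with `collection` (a `mol_collection`) and `truth`, a
#'   data.frame with one row per molecule: planted counts per moiety type and
#'   terminality, ring/chain classes (comma-separated), decoy class, and the
#'   expected profile booleans
#' @export
generate_glycosides <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  smiles <- character(); ids <- character()
  rows <- list()
  for (i in seq_len(spec$n_molecules)) {
    id <- sprintf("syn%04d", i)
    root <- sample(gs_scaffold_roots, 1L)
    glyco <- stats::runif(1) < spec$fraction_glycosylated
    decoy <- NA_character_
    n_circ_t <- n_circ_b <- n_lin_t <- n_lin_b <- 0L
    ring_classes <- character(); size_classes <- character()
    stereo_dup <- FALSE
    if (glyco) {
      n_sugars <- sample.int(14L, 1L, prob = spec$sugar_count_distribution)
      types <- ifelse(stats::runif(n_sugars) < spec$circular_fraction,
                      "circular", "linear")
      classes <- vapply(types, function(tp) {
        if (tp == "circular")
          sample(names(spec$ring_class_weights), 1L, prob = spec$ring_class_weights)
        else
          sample(names(spec$chain_class_weights), 1L, prob = spec$chain_class_weights)
      }, character(1))
      bridging <- stats::runif(1) < spec$bridging_fraction
      stereo_dup <- spec$stereo_duplication_rate > 0 &&
        stats::runif(1) < spec$stereo_duplication_rate &&
        types[1] == "circular" && classes[1] == "pyranose" && !bridging
      if (bridging) {
        sub <- sample(gs_scaffold_subs, 1L)
        hook1 <- gs_build_chain(types[1], classes[1], tail = sub)
        hook2 <- if (n_sugars > 1L)
          gs_build_chain(types[-1], classes[-1]) else sample(gs_plain_subs, 1L)
        if (types[1] == "circular") n_circ_b <- 1L else n_lin_b <- 1L
        if (n_sugars > 1L) {
          n_circ_t <- sum(types[-1] == "circular")
          n_lin_t <- sum(types[-1] == "linear")
        }
      } else {
        hook1 <- gs_build_chain(types, classes,
                                stereo_variant = if (stereo_dup) 1L else 0L)
        hook2 <- sample(gs_plain_subs, 1L)
        n_circ_t <- sum(types == "circular")
        n_lin_t <- sum(types == "linear")
      }
      ring_classes <- classes[types == "circular"]
      size_classes <- classes[types == "linear"]
      smi <- sub("%s", hook2, sub("%s", hook1, root, fixed = TRUE), fixed = TRUE)
    } else {
      total_decoy <- sum(spec$decoy_rates)
      hook1 <- sample(gs_plain_subs, 1L)
      if (total_decoy > 0 && stats::runif(1) < total_decoy) {
        decoy <- sample(names(spec$decoy_rates), 1L, prob = spec$decoy_rates)
        hook1 <- gs_decoy_units[[decoy]]
      }
      smi <- sub("%s", sample(gs_plain_subs, 1L),
                 sub("%s", hook1, root, fixed = TRUE), fixed = TRUE)
    }
    n_c <- n_circ_t + n_circ_b; n_l <- n_lin_t + n_lin_b
    rows[[length(rows) + 1L]] <- data.frame(
      id = id, glycosylated = glyco, decoy_class = decoy,
      n_circular = n_c, n_linear = n_l, n_total = n_c + n_l,
      n_terminal = n_circ_t + n_lin_t, n_bridging = n_circ_b + n_lin_b,
      ring_classes = paste(ring_classes, collapse = ","),
      size_classes = paste(size_classes, collapse = ","),
      has_sugars = n_c + n_l > 0L,
      has_circular = n_c > 0L, has_linear = n_l > 0L,
      has_only_circular = n_c > 0L && n_l == 0L,
      has_only_linear = n_l > 0L && n_c == 0L,
      has_both = n_c > 0L && n_l > 0L,
      consists_only_of_sugars = FALSE,
      has_terminal_circular = n_circ_t > 0L,
      has_nonterminal_circular = n_circ_b > 0L,
      has_only_terminal_circular = n_circ_t > 0L && n_circ_b == 0L,
      has_only_nonterminal_circular = n_circ_b > 0L && n_circ_t == 0L,
      has_terminal_linear = n_lin_t > 0L,
      has_nonterminal_linear = n_lin_b > 0L,
      has_only_terminal_linear = n_lin_t > 0L && n_lin_b == 0L,
      has_only_nonterminal_linear = n_lin_b > 0L && n_lin_t == 0L,
      stereo_parent = id,
      stringsAsFactors = FALSE)
    smiles <- c(smiles, smi); ids <- c(ids, id)
    if (stereo_dup) {
      # anomer duplicate: same constitution, one tetrahedral centre flipped
      dup_id <- paste0(id, "b")
      hook1b <- gs_build_chain(types, classes, stereo_variant = 2L)
      dup <- rows[[length(rows)]]
      dup$id <- dup_id; dup$stereo_parent <- id
      rows[[length(rows) + 1L]] <- dup
      smiles <- c(smiles,
                  sub("%s", hook2, sub("%s", hook1b, root, fixed = TRUE), fixed = TRUE))
      ids <- c(ids, dup_id)
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  collection <- parse_smiles(smiles, ids)
  if (length(collection) != length(smiles))
    stop("internal error: generated structure failed to parse")
  list(collection = collection, truth = truth)
}

#' Compare pipeline profiles against generator ground truth
#'
#' @param truth the `truth` data.frame from [generate_glycosides()]
#' @param profiles a `glyco_profiles` data.frame from [profile_collection()]
#'   computed on the generated collection
#' @return list with `field_agreement` (per-field fraction of molecules where
#'   pipeline output equals planted truth), `n_molecules`, and
#'   `all_exact` (TRUE when every compared field agrees everywhere)
#' @export
recovery_check <- function(truth, profiles) {
  stopifnot(all(truth$id %in% profiles$id))
  p <- profiles[match(truth$id, profiles$id), ]
  fields <- c("has_sugars", "has_circular", "has_linear", "has_only_circular",
              "has_only_linear", "has_both", "consists_only_of_sugars",
              "n_circular", "n_linear", "n_total",
              "has_terminal_circular", "has_nonterminal_circular",
              "has_only_terminal_circular", "has_only_nonterminal_circular",
              "has_terminal_linear", "has_nonterminal_linear",
              "has_only_terminal_linear", "has_only_nonterminal_linear")
  agr <- vapply(fields, function(f) mean(p[[f]] == truth[[f]]), numeric(1))
  list(field_agreement = agr, n_molecules = nrow(truth),
       all_exact = all(agr == 1))
}
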