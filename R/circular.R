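# Circular sugar detection: furanose/pyranose/heptose rings filtered on the
# exocyclic oxygen ratio r_exo = n_exo / n_inc.

#' Settings for circular sugar detection
#'
#' Defaults reproduce the conventional detection configuration: ring
#' candidates are 5-7-membered isolated saturated rings with exactly one ring
#' oxygen, accepted when the ratio of exocyclic oxygen atoms to ring heavy
#' atoms reaches 0.5; spiro rings and rings carrying keto groups are excluded
#' and no glycosidic bond is required.
#'
#' @param ratio_threshold minimum exocyclic oxygen ratio, in `[0, 2]`
#' @param require_glycosidic_bond require a C-O-X bridge off the ring
#' @param allow_spiro accept rings sharing exactly one atom with another ring
#' @param allow_keto accept rings with an exocyclic double-bonded oxygen on a
#'   ring carbon
#' @param require_isolated_cycle reject rings sharing a bond with another ring
#'   (and, unless `allow_spiro`, rings sharing one atom)
#' @return a `circular_settings` object
#' @export
circular_settings <- function(ratio_threshold = 0.5,
                              require_glycosidic_bond = FALSE,
                              allow_spiro = FALSE,
                              allow_keto = FALSE,
                              require_isolated_cycle = TRUE) {
  stopifnot(is.numeric(ratio_threshold), length(ratio_threshold) == 1L,
            ratio_threshold >= 0, ratio_threshold <= 2)
  structure(list(ratio_threshold = ratio_threshold,
                 require_glycosidic_bond = isTRUE(require_glycosidic_bond),
                 allow_spiro = isTRUE(allow_spiro),
                 allow_keto = isTRUE(allow_keto),
                 require_isolated_cycle = isTRUE(require_isolated_cycle)),
            class = "circular_settings")
}

ring_class_of <- function(n_inc) {
  c(`5` = "furanose", `6` = "pyranose", `7` = "heptose")[as.character(n_inc)]
}

#' Enumerate candidate sugar rings (pre-filter)
#'
#' Finds every ring of size 5-7 with exactly one ring oxygen, all other ring
#' atoms carbon, and no ring-internal bond of order above one (a cyclic double
#' bond disqualifies the ring, which is why ascorbic acid yields no
#' candidate). All flags and the exocyclic oxygen statistics are populated;
#' no threshold or option filtering is applied here.
#'
#' @param m a `molecule`
#' @param rings optional precomputed ring list (internal use)
#' @return list of `sugar_ring_candidate` objects, each a list with
#'   `ring_atoms`, `n_inc`, `ring_class`, `n_exo`, `r_exo`, `exo_oxygens` and
#'   logical flags `is_isolated_cycle`, `is_spiro`, `is_fused`,
#'   `has_keto_group`, `has_glycosidic_bond`
#' @export
find_candidate_rings <- function(m, rings = NULL) {
  stopifnot(inherits(m, "molecule"))
  if (is.null(rings)) rings <- perceive_rings(m)
  if (!length(rings)) return(list())
  bo <- bond_order_map(m)
  nb <- neighbor_list(m)
  out <- list()
  for (ri in seq_along(rings)) {
    ring <- rings[[ri]]
    n_inc <- length(ring)
    if (n_inc < 5L || n_inc > 7L) next
    elems <- m$atoms[ring]
    if (sum(elems == "O") != 1L || sum(elems == "C") != n_inc - 1L) next
    # ring-internal unsaturation disqualifies
    unsat <- FALSE
    for (k in seq_len(n_inc)) {
      a <- ring[k]; b <- ring[if (k == n_inc) 1L else k + 1L]
      if (get_bond_order(bo, a, b) > 1L) { unsat <- TRUE; break }
    }
    if (unsat) next
    # overlap with other rings
    other <- setdiff(seq_along(rings), ri)
    max_shared <- 0L
    for (oi in other) {
      sh <- length(intersect(ring, rings[[oi]]))
      if (sh > max_shared) max_shared <- sh
    }
    exo <- exocyclic_oxygens(m, ring, nb)
    keto <- FALSE
    for (a in ring[elems == "C"]) {
      for (x in nb[[a]]) {
        if (!(x %in% ring) && m$atoms[x] == "O" && get_bond_order(bo, a, x) == 2L) {
          keto <- TRUE; break
        }
      }
      if (keto) break
    }
    cand <- structure(list(
      ring_atoms = ring,
      n_inc = n_inc,
      ring_class = unname(ring_class_of(n_inc)),
      exo_oxygens = exo,
      n_exo = length(exo),
      r_exo = length(exo) / n_inc,
      is_isolated_cycle = max_shared == 0L,
      is_spiro = max_shared == 1L,
      is_fused = max_shared >= 2L,
      has_keto_group = keto,
      has_glycosidic_bond = FALSE,
      passes_ratio_threshold = NA), class = "sugar_ring_candidate")
    cand$has_glycosidic_bond <- has_glycosidic_bond(cand, m, nb)
    out[[length(out) + 1L]] <- cand
  }
  out
}

# Oxygen atoms directly bonded to ring atoms, excluding ring members; each
# oxygen atom is counted once even if multiply bonded or bonded to two ring
# atoms.
exocyclic_oxygens <- function(m, ring, nb = neighbor_list(m)) {
  exo <- integer()
  for (a in ring) {
    for (x in nb[[a]]) {
      if (!(x %in% ring) && m$atoms[x] == "O") exo <- c(exo, x)
    }
  }
  sort(unique(exo))
}

#' Exocyclic oxygen ratio of a candidate ring
#'
#' The number of oxygen atoms bonded directly to ring atoms (`n_exo`, the
#' ring oxygen itself never counted, each oxygen counted once) divided by the
#' ring heavy-atom count (`n_inc`).
#'
#' @param ring a `sugar_ring_candidate` from [find_candidate_rings()]
#' @return the exact rational value `n_exo / n_inc`
#' @export
compute_exocyclic_oxygen_ratio <- function(ring) {
  stopifnot(inherits(ring, "sugar_ring_candidate"))
  ring$n_exo / ring$n_inc
}

#' Test for an O-glycosidic bond on a candidate ring
#'
#' TRUE iff some ring carbon is bonded to an exocyclic oxygen that is itself
#' bonded to a heavy atom outside the ring (a C-O-X bridge).
#'
#' @param ring a `sugar_ring_candidate`
#' @param m the parent `molecule`
#' @param nb optional precomputed neighbor list
#' @return logical
#' @export
has_glycosidic_bond <- function(ring, m, nb = neighbor_list(m)) {
  ra <- ring$ring_atoms
  for (a in ra) {
    if (m$atoms[a] != "C") next
    for (x in nb[[a]]) {
      if (x %in% ra || m$atoms[x] != "O") next
      for (y in nb[[x]]) {
        if (!(y %in% ra) && y != a) return(TRUE)
      }
    }
  }
  FALSE
}

#' Detect circular sugar moieties
#'
#' Applies the configured filters to the candidate rings of
#' [find_candidate_rings()]: isolated-cycle/spiro handling, the keto
#' exclusion, the exocyclic-oxygen-ratio threshold (inclusive, `r_exo >=`
#' threshold) and optionally the glycosidic-bond requirement. Accepted rings
#' are mutually atom-disjoint; on overlap the candidate with the higher ratio
#' (ties: lowest atom index) wins.
#'
#' @param m a `molecule`
#' @param settings a [circular_settings()] object
#' @param candidates optional precomputed candidate list
#' @return list of accepted `sugar_ring_candidate`s with
#'   `passes_ratio_threshold` set
#' @export
detect_circular_sugars <- function(m, settings = circular_settings(),
                                   candidates = NULL) {
  stopifnot(inherits(settings, "circular_settings"))
  if (is.null(candidates)) candidates <- find_candidate_rings(m)
  acc <- list()
  for (cand in candidates) {
    cand$passes_ratio_threshold <- cand$r_exo >= settings$ratio_threshold
    if (settings$require_isolated_cycle) {
      if (cand$is_fused) next
      if (cand$is_spiro && !settings$allow_spiro) next
    }
    if (cand$has_keto_group && !settings$allow_keto) next
    if (!cand$passes_ratio_threshold) next
    if (settings$require_glycosidic_bond && !cand$has_glycosidic_bond) next
    acc[[length(acc) + 1L]] <- cand
  }
  if (length(acc) <= 1L) return(acc)
  # enforce atom-disjointness deterministically
  ord <- order(-vapply(acc, function(x) x$r_exo, numeric(1)),
               vapply(acc, function(x) min(x$ring_atoms), integer(1)))
  taken <- integer(); keep <- list()
  for (i in ord) {
    if (!length(intersect(acc[[i]]$ring_atoms, taken))) {
      keep[[length(keep) + 1L]] <- acc[[i]]
      taken <- c(taken, acc[[i]]$ring_atoms)
    }
  }
  keep[order(vapply(keep, function(x) min(x$ring_atoms), integer(1)))]
}
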