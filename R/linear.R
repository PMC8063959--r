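# Linear (open-chain) sugar detection: oxygenated acyclic carbon chains of
# 4-7 carbons, non-acidic by default, never overlapping accepted circular
# sugars.

#' Settings for linear sugar detection
#'
#' Defaults detect non-acidic open chains of 4 to 7 carbons outside of rings.
#'
#' @param min_carbons minimum chain length (default 4)
#' @param max_carbons maximum chain length (default 7)
#' @param allow_acidic accept chains containing or directly attached to a
#'   carboxyl carbon
#' @param allow_in_rings allow chain atoms to be ring members (detection of
#'   sugar-like stretches inside rings, e.g. pseudosugars and macrolide
#'   polyol stretches)
#' @return a `linear_settings` object
#' @export
linear_settings <- function(min_carbons = 4L, max_carbons = 7L,
                            allow_acidic = FALSE, allow_in_rings = FALSE) {
  stopifnot(min_carbons >= 1L, max_carbons >= min_carbons)
  structure(list(min_carbons = as.integer(min_carbons),
                 max_carbons = as.integer(max_carbons),
                 allow_acidic = isTRUE(allow_acidic),
                 allow_in_rings = isTRUE(allow_in_rings)),
            class = "linear_settings")
}

size_class_of <- function(n) {
  cls <- c(`4` = "tetrose", `5` = "pentose", `6` = "hexose", `7` = "heptose")
  unname(cls[as.character(n)])
}

# Carboxyl carbon: C with a double-bonded O and a further single-bonded
# terminal O (hydroxyl or carboxylate). Connectivity-based, so protonation
# state is irrelevant.
carboxyl_carbons <- function(m, nb = neighbor_list(m), bo = bond_order_map(m)) {
  out <- integer()
  for (a in seq_along(m$atoms)) {
    if (m$atoms[a] != "C") next
    has_dbl_o <- FALSE; has_term_o <- FALSE
    for (x in nb[[a]]) {
      if (m$atoms[x] != "O") next
      ord <- get_bond_order(bo, a, x)
      if (ord == 2L) has_dbl_o <- TRUE
      else if (ord == 1L && length(nb[[x]]) == 1L) has_term_o <- TRUE
    }
    if (has_dbl_o && has_term_o) out <- c(out, a)
  }
  out
}

#' Detect linear sugar moieties
#'
#' A linear sugar candidate is a simple path of eligible carbons (no triple
#' bonds, no carbon-carbon double bonds, outside rings unless
#' `allow_in_rings`) of length `min_carbons..max_carbons` in which at least
#' `length - 2` carbons bear at least one oxygen substituent (hydroxyl,
#' carbonyl, or ester/glycosidic oxygen); up to two deoxygenated positions
#' are tolerated. Chains containing, or directly bonded to, a carboxyl carbon
#' are rejected unless `allow_acidic`. Chains overlapping an accepted
#' circular sugar are discarded. Maximal chains are preferred: contained
#' candidates are absorbed and overlaps resolved keeping the longest chain
#' (ties by lowest atom index), so accepted candidates are mutually
#' atom-disjoint.
#'
#' @param m a `molecule`
#' @param settings a [linear_settings()] object
#' @param circular list of accepted circular candidates from
#'   [detect_circular_sugars()] run with matching settings (atoms excluded
#'   from chains)
#' @return list of `linear_sugar_candidate` objects: `chain_atoms` (the
#'   carbon path), `oxygen_atoms` (attached oxygens), `carbon_count`,
#'   `size_class`, flags `is_in_ring`, `is_acidic`
#' @export
detect_linear_sugars <- function(m, settings = linear_settings(),
                                 circular = list()) {
  stopifnot(inherits(settings, "linear_settings"))
  nb <- neighbor_list(m)
  bo <- bond_order_map(m)
  ring_atoms <- ring_atom_set(m)
  circ_atoms <- unique(unlist(lapply(circular, function(x)
    c(x$ring_atoms, x$exo_oxygens)), use.names = FALSE))
  acid_c <- carboxyl_carbons(m, nb, bo)

  eligible <- logical(length(m$atoms))
  for (a in seq_along(m$atoms)) {
    if (m$atoms[a] != "C") next
    if (a %in% circ_atoms) next
    if (!settings$allow_in_rings && (a %in% ring_atoms)) next
    bad <- FALSE
    for (x in nb[[a]]) {
      ord <- get_bond_order(bo, a, x)
      if (ord >= 3L) bad <- TRUE
      if (ord == 2L && m$atoms[x] != "O") bad <- TRUE  # C=C / C=N carbons are not sugar-like
    }
    if (!bad) eligible[a] <- TRUE
  }

  # Acidity: the whole connected carbon stretch carrying a carboxyl carbon is
  # skipped (an acidic chain is not a sugar, nor are its sub-chains).
  if (!settings$allow_acidic && length(acid_c)) {
    reach <- acid_c[eligible[acid_c]]
    queue <- reach
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (x in nb[[a]]) {
        if (eligible[x] && m$atoms[x] == "C" && !(x %in% reach)) {
          reach <- c(reach, x); queue <- c(queue, x)
        }
      }
    }
    eligible[reach] <- FALSE
  }

  oxygenated <- vapply(seq_along(m$atoms), function(a)
    any(m$atoms[nb[[a]]] == "O"), logical(1))

  # enumerate simple paths of eligible carbons, lengths min..max
  cands <- list()
  seen <- new.env(parent = emptyenv())
  lo <- settings$min_carbons; hi <- settings$max_carbons
  elig_idx <- which(eligible)
  cnb <- lapply(seq_along(m$atoms), function(a)
    nb[[a]][eligible[nb[[a]]] & m$atoms[nb[[a]]] == "C" &
              vapply(nb[[a]], function(x) get_bond_order(bo, a, x), integer(1)) >= 1L])
  walk <- function(path) {
    len <- length(path)
    if (len >= lo && len <= hi) {
      key <- paste(sort(path), collapse = ",")
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        cands[[length(cands) + 1L]] <<- path
      }
    }
    if (len == hi) return()
    for (x in cnb[[path[len]]]) {
      if (!(x %in% path)) walk(c(path, x))
    }
  }
  for (a in elig_idx) walk(a)

  ok <- list()
  for (path in cands) {
    len <- length(path)
    n_oxy <- sum(oxygenated[path])
    if (n_oxy < len - 2L || n_oxy < 1L) next
    acidic <- any(path %in% acid_c) ||
      any(vapply(path, function(a) any(nb[[a]] %in% acid_c), logical(1)))
    if (acidic && !settings$allow_acidic) next
    oxy <- integer()
    for (a in path) for (x in nb[[a]]) {
      if (m$atoms[x] == "O" && !(x %in% circ_atoms)) oxy <- c(oxy, x)
    }
    oxy <- sort(unique(oxy))
    ok[[length(ok) + 1L]] <- structure(list(
      chain_atoms = path,
      oxygen_atoms = oxy,
      carbon_count = len,
      size_class = size_class_of(len),
      is_in_ring = any(path %in% ring_atoms),
      is_acidic = acidic), class = "linear_sugar_candidate")
  }
  if (!length(ok)) return(ok)

  # keep maximal, mutually disjoint chains: longest first, ties by lowest
  # starting atom index in canonical order
  ord <- order(-vapply(ok, function(x) x$carbon_count, integer(1)),
               vapply(ok, function(x) min(x$chain_atoms), integer(1)),
               vapply(ok, function(x) paste(sort(x$chain_atoms), collapse = ","),
                      character(1)))
  taken <- integer(); keep <- list()
  for (i in ord) {
    if (!length(intersect(ok[[i]]$chain_atoms, taken))) {
      keep[[length(keep) + 1L]] <- ok[[i]]
      taken <- c(taken, ok[[i]]$chain_atoms)
    }
  }
  keep[order(vapply(keep, function(x) min(x$chain_atoms), integer(1)))]
}
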