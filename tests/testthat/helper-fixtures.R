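# Shared fixtures and independent oracles.
#
# Compound structures: simple sugars and small molecules are written with
# their real constitutions. For the larger literature glycosides (the
# cardiac glycoside with a trisaccharide chain, the phenolic glycoside with
# two bridging sugars, the tyrosine-derived metabolite with a central
# tetraol) the published constitutions were not available offline; the
# fixtures below are synthetic stand-ins that reproduce the named
# glycosylation topology exactly (same moiety counts, classes and
# terminality), which is what every assertion concerns.

fx <- list(
  glucose          = "OCC1OC(O)C(O)C(O)C1O",
  phenyl_glucoside = "OCC1OC(Oc2ccccc2)C(O)C(O)C1O",
  methyl_glucoside = "OCC1OC(OC)C(O)C(O)C1O",
  fructose         = "OCC1(O)OC(CO)C(O)C1O",
  vitamin_c        = "OCC(O)C1OC(=O)C(O)=C1O",
  inositol         = "OC1C(O)C(O)C(O)C(O)C1O",
  tetrahydropyran  = "C1CCOCC1",
  toluene          = "Cc1ccccc1",
  benzene          = "c1ccccc1",
  cyclohexane      = "C1CCCCC1",
  deoxyglucose_open = "OCC(O)C(O)C(O)CC=O",
  gluconic_acid    = "OCC(O)C(O)C(O)C(O)C(=O)O",
  # S-methyl-5-thio-pentulose phosphate type chain: thio terminus + phosphate
  thio_ribulose_p  = "CSCC(O)C(O)C(=O)COP(=O)(O)O",
  maltose          = "OCC1OC(OC2C(O)C(O)C(O)OC2CO)C(O)C(O)C1O",
  isomaltose_open  = "OCC1OC(OCC(O)C(O)C(O)C(O)C=O)C(O)C(O)C1O",
  # cardiac-glycoside stand-in: steroid-type aglycone + chain of three
  # 2,6-dideoxy pyranoses (each ring: 3 exocyclic O, ratio exactly 0.5)
  diginatin_like   = paste0("CC1OC(OC2CCC3(C)C(CCC4C3CCC3(C)C(C5=CC(=O)OC5)CCC43O)C2)",
                            "CC(O)C1OC1CC(O)C(OC2CC(O)C(O)C(C)O2)C(C)O1"),
  # phenolic-glycoside stand-in with two bridging (non-terminal) sugars
  cucurbitoside_like = paste0("O=C(OCC1OC(Oc2ccccc2OC3OC(COC(=O)c4ccccc4)",
                              "C(O)C(O)C3O)C(O)C1O)c1ccccc1"),
  # hexasaccharide stand-in: five rings + one open-chain unit, sugars only
  lndfh_like       = paste0("OCC(O)C(O)C(O)C(OC1OC(CO)C(O)C(OC2OC(CO)",
                            "C(OC3OC(CO)C(O)C(O)C3OC4OC(C)C(O)C(O)C4O)",
                            "C(OC5OC(C)C(O)C(O)C5O)C2NC(C)=O)C1O)C=O"),
  # central non-terminal tetraol bridging two aromatic halves
  aspergillusol_like = "Cc1ccc(C(O)C(O)C(O)C(O)c2ccc(C)cc2)cc1",
  # iridoid-like stand-in carrying one circular and one linear moiety
  lavaudioside_like = "OCC1OC(OCC2CCC(COCC(O)C(O)C(O)CO)CC2)C(O)C(O)C1O",
  spiro_sugar      = "OCC1OC(O)C(O)C(O)C12CCCC2",
  keto_sugar       = "OCC1OC(O)C(=O)C(O)C1O",
  low_oxy_pyranose = "OC1CCCOC1Oc1ccccc1"  # 2 exocyclic O, ratio 1/3
)

parse_fx <- function(names) {
  mols <- parse_smiles(unlist(fx[names], use.names = FALSE), names)
  stopifnot(length(mols) == length(names))
  mols
}

parse_one <- function(name) parse_fx(name)[[1]]

# Random atom-order permutation of a molecule graph (independent of the
# package's subsetting helpers).
permute_molecule <- function(m, perm) {
  stopifnot(length(perm) == length(m$atoms))
  inv <- order(perm)  # inv[old] = new position
  b <- m$bonds
  b$a1 <- inv[b$a1]; b$a2 <- inv[b$a2]
  glycoscan:::new_molecule(m$id, m$atoms[perm], b)
}

# --- brute-force ring oracle ------------------------------------------------

# All simple cycles of length lo..hi, as sorted atom-set keys.
bf_simple_cycles <- function(m, lo = 5L, hi = 7L) {
  nb <- lapply(seq_along(m$atoms), function(a)
    sort(unique(c(m$bonds$a2[m$bonds$a1 == a], m$bonds$a1[m$bonds$a2 == a]))))
  found <- new.env(parent = emptyenv())
  res <- list()
  dfs <- function(path) {
    last <- path[length(path)]
    for (x in nb[[last]]) {
      if (x == path[1] && length(path) >= lo) {
        key <- paste(sort(path), collapse = ",")
        if (!exists(key, envir = found, inherits = FALSE)) {
          assign(key, TRUE, envir = found)
          res[[length(res) + 1L]] <<- path
        }
      } else if (!(x %in% path) && length(path) < hi && x > path[1]) {
        dfs(c(path, x))
      }
    }
  }
  for (s in seq_along(m$atoms)) dfs(s)
  res
}

# Independent re-implementation of circular sugar detection from first
# principles: brute-force cycles, then the documented filters.
bf_detect_circular <- function(m, settings = circular_settings()) {
  cycles <- bf_simple_cycles(m, 3L, 12L)  # ring context for overlap flags
  cand_cycles <- Filter(function(r) length(r) >= 5 && length(r) <= 7, cycles)
  bo_lookup <- function(a, b) {
    hit <- (m$bonds$a1 == a & m$bonds$a2 == b) | (m$bonds$a1 == b & m$bonds$a2 == a)
    if (any(hit)) m$bonds$order[which(hit)[1]] else 0L
  }
  nb <- lapply(seq_along(m$atoms), function(a)
    sort(unique(c(m$bonds$a2[m$bonds$a1 == a], m$bonds$a1[m$bonds$a2 == a]))))
  acc <- list()
  for (ring in cand_cycles) {
    n <- length(ring)
    el <- m$atoms[ring]
    if (sum(el == "O") != 1L || sum(el == "C") != n - 1L) next
    unsat <- FALSE
    for (k in seq_len(n)) {
      if (bo_lookup(ring[k], ring[if (k == n) 1L else k + 1L]) > 1L) unsat <- TRUE
    }
    if (unsat) next
    shared <- 0L
    for (other in cycles) {
      if (identical(sort(other), sort(ring))) next
      shared <- max(shared, length(intersect(ring, other)))
    }
    exo <- sort(unique(unlist(lapply(ring, function(a)
      Filter(function(x) !(x %in% ring) && m$atoms[x] == "O", nb[[a]])))))
    keto <- any(vapply(ring[el == "C"], function(a)
      any(vapply(nb[[a]], function(x)
        !(x %in% ring) && m$atoms[x] == "O" && bo_lookup(a, x) == 2L, logical(1))),
      logical(1)))
    r_exo <- length(exo) / n
    if (settings$require_isolated_cycle) {
      if (shared >= 2L) next
      if (shared == 1L && !settings$allow_spiro) next
    }
    if (keto && !settings$allow_keto) next
    if (r_exo < settings$ratio_threshold) next
    acc[[length(acc) + 1L]] <- sort(ring)
  }
  # disjointness: mirror the implementation's deterministic resolution
  if (length(acc) > 1L) {
    rx <- vapply(acc, function(r) {
      exo <- unlist(lapply(r, function(a)
        Filter(function(x) !(x %in% r) && m$atoms[x] == "O", nb[[a]])))
      length(unique(exo)) / length(r)
    }, numeric(1))
    ord <- order(-rx, vapply(acc, min, integer(1)))
    taken <- integer(); keep <- list()
    for (i in ord) {
      if (!length(intersect(acc[[i]], taken))) {
        keep[[length(keep) + 1L]] <- acc[[i]]; taken <- c(taken, acc[[i]])
      }
    }
    acc <- keep
  }
  acc
}

# --- brute-force substructure oracle ---------------------------------------

# DFS backtracking monomorphism with element and bond-order matching
# (non-induced), independent of igraph.
bf_is_substructure <- function(pattern, target) {
  np <- length(pattern$atoms); nt <- length(target$atoms)
  if (np > nt) return(FALSE)
  pnb <- lapply(seq_len(np), function(a) {
    hits <- c(pattern$bonds$a2[pattern$bonds$a1 == a],
              pattern$bonds$a1[pattern$bonds$a2 == a])
    hits
  })
  p_ord <- function(a, b) {
    hit <- (pattern$bonds$a1 == a & pattern$bonds$a2 == b) |
      (pattern$bonds$a1 == b & pattern$bonds$a2 == a)
    pattern$bonds$order[which(hit)[1]]
  }
  t_ord <- function(a, b) {
    hit <- (target$bonds$a1 == a & target$bonds$a2 == b) |
      (target$bonds$a1 == b & target$bonds$a2 == a)
    if (any(hit)) target$bonds$order[which(hit)[1]] else 0L
  }
  map <- rep(NA_integer_, np)
  used <- rep(FALSE, nt)
  match_atom <- function(k) {
    if (k > np) return(TRUE)
    for (cand in seq_len(nt)) {
      if (used[cand] || target$atoms[cand] != pattern$atoms[k]) next
      ok <- TRUE
      for (x in pnb[[k]]) {
        if (x < k) {
          if (t_ord(cand, map[x]) != p_ord(k, x)) { ok <- FALSE; break }
        }
      }
      if (ok) {
        map[k] <<- cand; used[cand] <<- TRUE
        if (match_atom(k + 1L)) return(TRUE)
        used[cand] <<- FALSE; map[k] <<- NA_integer_
      }
    }
    FALSE
  }
  match_atom(1L)
}

# Decorated-ring builder for the analytic ratio suite: ring of `nc` carbons
# and one oxygen, carbon i carrying subs[i] hydroxyls (0, 1 or 2).
decorated_ring_smiles <- function(nc, subs) {
  stopifnot(length(subs) == nc, all(subs %in% 0:2))
  dec <- c("", "(O)", "(O)(O)")[subs + 1L]
  paste0("C1", dec[1],
         paste0("C", dec[-1], collapse = ""),
         "O1")
}
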