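# Molecular-graph helpers built on igraph.

#' @importFrom igraph graph_from_data_frame components bridges distances
#'   shortest_paths delete_edges V E make_empty_graph vcount
NULL

mol_igraph <- function(m) {
  n <- length(m$atoms)
  if (!nrow(m$bonds)) return(igraph::make_empty_graph(n, directed = FALSE))
  igraph::graph_from_data_frame(
    data.frame(from = m$bonds$a1, to = m$bonds$a2),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
}

# Connected components as a list of atom-index vectors.
mol_components <- function(m) {
  g <- mol_igraph(m)
  comp <- igraph::components(g)
  split(seq_along(comp$membership), comp$membership)
}

n_fragments <- function(m) {
  if (!length(m$atoms)) return(0L)
  igraph::components(mol_igraph(m))$no
}

# Neighbor list: integer vectors per atom.
neighbor_list <- function(m) {
  n <- length(m$atoms)
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer()
  if (nrow(m$bonds)) {
    for (k in seq_len(nrow(m$bonds))) {
      a <- m$bonds$a1[k]; b <- m$bonds$a2[k]
      nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
    }
  }
  nb
}

# Bond-order lookup matrix-free: keyed "a-b" with a<b.
bond_order_map <- function(m) {
  if (!nrow(m$bonds)) return(new.env(parent = emptyenv()))
  env <- new.env(parent = emptyenv(), size = nrow(m$bonds) * 2L)
  for (k in seq_len(nrow(m$bonds))) {
    a <- m$bonds$a1[k]; b <- m$bonds$a2[k]
    key <- paste0(min(a, b), "-", max(a, b))
    assign(key, m$bonds$order[k], envir = env)
  }
  env
}

get_bond_order <- function(bo, a, b) {
  key <- paste0(min(a, b), "-", max(a, b))
  if (exists(key, envir = bo, inherits = FALSE)) get(key, envir = bo) else 0L
}

# Relevant smallest rings: for every edge that lies on a cycle, the smallest
# cycle through that edge (shortest path between its endpoints in the graph
# with the edge removed, closed by the edge). Deduplicated by atom set.
# Sugar rings are chordless, so this recovers them exactly; fused and spiro
# neighbours are recovered too, which is all the ring context the candidate
# flags need.
perceive_rings <- function(m) {
  g <- mol_igraph(m)
  if (igraph::vcount(g) == 0L || nrow(m$bonds) == 0L) return(list())
  br <- igraph::bridges(g)
  cyc_edges <- setdiff(seq_len(nrow(m$bonds)), as.integer(br))
  rings <- list(); seen <- character()
  for (ei in cyc_edges) {
    a <- m$bonds$a1[ei]; b <- m$bonds$a2[ei]
    g2 <- igraph::delete_edges(g, ei)
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = a, to = b, output = "vpath"))
    vp <- sp$vpath[[1]]
    if (!length(vp)) next
    ring <- as.integer(igraph::V(g)$name[as.integer(vp)])
    key <- paste(sort(ring), collapse = ",")
    if (!(key %in% seen)) { seen <- c(seen, key); rings[[length(rings) + 1L]] <- ring }
  }
  rings
}

# Atoms that are members of at least one ring.
ring_atom_set <- function(m) {
  unique(unlist(perceive_rings(m), use.names = FALSE))
}
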