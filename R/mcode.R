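#' MCODE parameters
#'
#' Tunables of the molecular complex detection algorithm. Defaults match
#' the common Cytoscape settings: degree cutoff 2, node score cutoff
#' 0.2, haircut on, fluff off, k-core filter 2, unlimited practical
#' depth.
#'
#' @param degree_cutoff vertices with degree below this are not scored.
#' @param node_score_cutoff fraction of the seed weight below which
#'   neighbors are not recruited, in `[0, 1]`.
#' @param k_core discard clusters not containing a k-core of this order.
#' @param haircut remove singly-connected vertices from each cluster
#'   (the cluster's 2-core).
#' @param fluff add boundary neighbors whose neighborhood density
#'   exceeds `fluff_density`.
#' @param fluff_density density threshold for fluffing.
#' @param max_depth maximum expansion depth from the seed.
#' @return an `mcode_params` list.
#' @export
mcode_params <- function(degree_cutoff = 2, node_score_cutoff = 0.2,
                         k_core = 2, haircut = TRUE, fluff = FALSE,
                         fluff_density = 0.2, max_depth = 100) {
  if (degree_cutoff < 1) abort("degree_cutoff must be >= 1")
  if (node_score_cutoff < 0 || node_score_cutoff > 1) {
    abort("node_score_cutoff must lie in [0, 1]")
  }
  list(degree_cutoff = degree_cutoff, node_score_cutoff = node_score_cutoff,
       k_core = k_core, haircut = haircut, fluff = fluff,
       fluff_density = fluff_density, max_depth = max_depth)
}

graph_density_noloops <- function(n_vertices, n_edges) {
  if (n_vertices < 2) return(0)
  2 * n_edges / (n_vertices * (n_vertices - 1))
}

# stage 1: core-clustering-coefficient weight of every vertex:
# (order of the highest k-core of the closed neighborhood) x (density of
# that core, self-loops excluded)
mcode_vertex_weights <- function(g, degree_cutoff) {
  n <- igraph::vcount(g)
  w <- numeric(n)
  deg <- igraph::degree(g)
  adj <- igraph::adjacent_vertices(g, seq_len(n))
  for (v in seq_len(n)) {
    if (deg[v] < degree_cutoff) next
    nb <- c(v, as.integer(adj[[v]]))
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0) next
    members <- which(core == kmax)
    sub2 <- igraph::induced_subgraph(sub, members)
    w[v] <- kmax * graph_density_noloops(igraph::vcount(sub2),
                                         igraph::ecount(sub2))
  }
  w
}

#' Molecular complex detection (MCODE)
#'
#' Seeded graph clustering for dense modules in interaction networks.
#' Stage 1 weights every vertex by the order times density of the
#' highest k-core of its closed neighborhood; stage 2 grows a complex
#' from each yet-unseen vertex in decreasing weight order, recruiting
#' neighbors whose weight is at least `seed weight * (1 -
#' node_score_cutoff)` up to `max_depth`; stage 3 optionally removes
#' singly-connected members (haircut) and adds dense boundary neighbors
#' (fluff), then discards complexes lacking a k-core of order `k_core`.
#' Complexes are scored `density * size` and sorted by decreasing score,
#' ties broken by size and then by seed name, so output is independent
#' of node input order.
#'
#' @param g an undirected graph ([load_ppi()] output or any
#'   [igraph::graph]).
#' @param params an [mcode_params()] list.
#' @return list of clusters, each a list with `members` (sorted symbol
#'   vector), `seed`, `score`, `density`, `size`.
#' @export
mcode <- function(g, params = mcode_params()) {
  if (igraph::vcount(g) == 0) abort("graph has no vertices")
  p <- params
  names_v <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  w <- mcode_vertex_weights(g, p$degree_cutoff)
  adj <- igraph::adjacent_vertices(g, seq_len(igraph::vcount(g)))
  # deterministic seed order: weight desc, then vertex name
  order_idx <- order(-w, names_v, method = "radix")
  seen <- rep(FALSE, igraph::vcount(g))
  clusters <- list()
  for (seed in order_idx) {
    if (seen[seed] || w[seed] <= 0) next
    thresh <- w[seed] * (1 - p$node_score_cutoff)
    members <- seed
    seen[seed] <- TRUE
    frontier <- seed
    depth <- 0
    while (length(frontier) && depth < p$max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in as.integer(adj[[v]])) {
          if (!seen[u] && w[u] >= thresh) {
            seen[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1
    }
    cl <- postprocess_cluster(g, members, seed, p, w)
    if (!is.null(cl)) clusters[[length(clusters) + 1]] <- cl
  }
  # order clusters: score desc, size desc, seed name
  if (length(clusters)) {
    key <- order(-vapply(clusters, `[[`, 0, "score"),
                 -vapply(clusters, `[[`, 0L, "size"),
                 vapply(clusters, `[[`, "", "seed"),
                 method = "radix")
    clusters <- clusters[key]
  }
  clusters
}

postprocess_cluster <- function(g, members, seed, p, w) {
  names_v <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  sub <- igraph::induced_subgraph(g, members)
  core <- igraph::coreness(sub)
  if (max(core) < p$k_core) return(NULL)
  if (p$haircut) {
    keep <- members[core >= 2]
    # keep the seed's connected component after the haircut
    if (!seed %in% keep) keep <- unique(c(seed, keep))
    members <- keep
  }
  if (p$fluff) {
    boundary <- setdiff(unique(unlist(
      igraph::adjacent_vertices(g, members))), members)
    for (u in as.integer(boundary)) {
      nb <- c(u, as.integer(igraph::adjacent_vertices(g, u)[[1]]))
      subn <- igraph::induced_subgraph(g, nb)
      if (graph_density_noloops(igraph::vcount(subn),
                                igraph::ecount(subn)) > p$fluff_density) {
        members <- c(members, u)
      }
    }
    members <- unique(members)
  }
  sub <- igraph::induced_subgraph(g, members)
  # restrict to the component containing the seed so members stay connected
  comp <- igraph::components(sub)$membership
  seed_pos <- match(seed, members)
  members <- members[comp == comp[seed_pos]]
  if (length(members) < 2) return(NULL)
  sub <- igraph::induced_subgraph(g, members)
  dens <- graph_density_noloops(igraph::vcount(sub), igraph::ecount(sub))
  list(
    members = sort(names_v[members]),
    seed = names_v[seed],
    score = dens * length(members),
    density = dens,
    size = length(members)
  )
}
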