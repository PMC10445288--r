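# Brute-force oracles and small random fixtures, independent of the
# package's Dijkstra-based machinery: everything here is exhaustive DFS
# over simple paths, feasible for graphs of up to ~8 nodes.

# random small interactome plus nonempty disjoint source/target sets
rand_small_graph <- function(n_nodes = 6, n_edges = 10, seed = 1,
                             p_undirected = 0.3) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- expand.grid(tail = nodes, head = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$tail != pairs$head, ]
  idx <- sample.int(nrow(pairs), min(n_edges, nrow(pairs)))
  g <- interactome(tail = pairs$tail[idx], head = pairs$head[idx],
                   weight = runif(length(idx), 0.05, 0.95),
                   directed = runif(length(idx)) > p_undirected,
                   nodes = nodes)
  ends <- sample(nodes, 4)
  list(g = g, sources = ends[1:2], targets = ends[3:4])
}

# min cost over simple paths from one node to one node (0 when identical)
bf_min_cost <- function(edges, from, to) {
  if (from == to) return(0)
  adj <- split(seq_len(nrow(edges)), edges$tail)
  best <- Inf
  rec <- function(node, visited, acc) {
    for (i in adj[[node]]) {
      h <- edges$head[i]
      if (h %in% visited) next
      c2 <- acc + edges$cost[i]
      if (c2 >= best) next
      if (h == to) best <<- c2 else rec(h, c(visited, h), c2)
    }
  }
  rec(from, from, 0)
  best
}

# cheapest source-to-target WALK through directed edge (u, v): cheapest
# simple segment from any source to u, plus the edge, plus the cheapest
# simple segment from v to any target (segments may share nodes; with
# nonnegative costs the cheapest walk decomposes exactly this way)
bf_walk_through_edge <- function(g, sources, targets, u, v, cost_uv) {
  e <- g$edges
  pre <- min(vapply(sources, function(s) bf_min_cost(e, s, u), 0))
  suf <- min(vapply(targets, function(t) bf_min_cost(e, v, t), 0))
  pre + cost_uv + suf
}

# all simple source-to-target paths (list of node vectors)
bf_all_paths <- function(edges, sources, targets) {
  adj <- split(seq_len(nrow(edges)), edges$tail)
  out <- list()
  rec <- function(node, visited, acc) {
    if (node %in% targets)
      out[[length(out) + 1L]] <<- list(path = visited, cost = acc)
    for (i in adj[[node]]) {
      h <- edges$head[i]
      if (h %in% visited) next
      rec(h, c(visited, h), acc + edges$cost[i])
    }
  }
  for (s in sources) rec(s, s, 0)
  out
}

# min cost over SIMPLE source-to-target paths that use edge (u, v)
bf_simple_through_edge <- function(g, sources, targets, u, v) {
  paths <- bf_all_paths(g$edges, sources, targets)
  best <- Inf
  for (p in paths) {
    nd <- p$path
    if (length(nd) >= 2 && any(nd[-length(nd)] == u & nd[-1] == v))
      best <- min(best, p$cost)
  }
  best
}

# per-edge EdgeLinker candidates (cost + path) for comparison
el_per_edge <- function(g, sources, targets) {
  ag <- augment_with_super_nodes(g, sources, targets)
  ds <- shortest_distances_from_source(ag)
  dt <- shortest_distances_to_target(ag)
  cand <- per_edge_best_paths(ag, ds, dt)
  list(ag = ag, cand = cand, edge_path = attr(cand, "edge_path"))
}

# standard small profile set for pipeline tests, mapped onto a generated
# synthetic interactome
synthetic_profiles <- function(gen, n_chemicals = 2) {
  lapply(seq_len(n_chemicals), function(i) {
    list(chemical = sprintf("chem%02d", i),
         sources = gen$sources, targets = gen$targets)
  })
}
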