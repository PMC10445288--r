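#' Augment an interactome with super source and super target
#'
#' Adds a super source node s with a directed weight-1 (cost-0) edge to
#' every source receptor, and a super target t with a weight-1 edge from
#' every target TF, so that a single pair of Dijkstra runs covers all
#' source/target endpoints.
#'
#' @param g an [interactome].
#' @param sources,targets nonempty character vectors of node IDs (the
#'   responsive receptors S_x and TFs T_x); must be subsets of the
#'   interactome's nodes.
#' @return An object of class `augmented_graph`: parallel vectors `tail`,
#'   `head`, `cost`, `weight`, `orientation` over all edges (original edges
#'   first, then super edges), the node vector `nodes`, the super node IDs
#'   `super_source`/`super_target`, and `n_original`, the number of
#'   original (non-super) edges.
#' @export
augment_with_super_nodes <- function(g, sources, targets) {
  stopifnot(inherits(g, "interactome"))
  sources <- unique(as.character(sources))
  targets <- unique(as.character(targets))
  if (length(sources) == 0L || length(targets) == 0L)
    stop("sources and targets must be nonempty")
  missing <- setdiff(c(sources, targets), g$nodes)
  if (length(missing))
    stop("not in the interactome: ", paste(missing, collapse = ", "))
  ss <- ".s."; tt <- ".t."
  while (ss %in% g$nodes) ss <- paste0(ss, ".")
  while (tt %in% g$nodes) tt <- paste0(tt, ".")
  e <- g$edges
  structure(list(
    tail = c(e$tail, rep(ss, length(sources)), targets),
    head = c(e$head, sources, rep(tt, length(targets))),
    cost = c(e$cost, numeric(length(sources) + length(targets))),
    weight = c(e$weight, rep(1, length(sources) + length(targets))),
    orientation = c(e$orientation,
                    rep("super", length(sources) + length(targets))),
    nodes = c(g$nodes, ss, tt),
    sources = sources, targets = targets,
    super_source = ss, super_target = tt,
    n_original = nrow(e)), class = "augmented_graph")
}

.ag_igraph <- function(ag) {
  igraph::make_graph(as.vector(rbind(match(ag$tail, ag$nodes),
                                     match(ag$head, ag$nodes))),
                     n = length(ag$nodes), directed = TRUE)
}

# one igraph build, both Dijkstra sweeps and both deterministic trees
.el_run <- function(ag) {
  ig <- .ag_igraph(ag)
  si <- match(ag$super_source, ag$nodes)
  ti <- match(ag$super_target, ag$nodes)
  ds <- stats::setNames(as.vector(
    igraph::distances(ig, v = si, mode = "out", weights = ag$cost,
                      algorithm = "dijkstra")), ag$nodes)
  dt <- stats::setNames(as.vector(
    igraph::distances(ig, v = ti, mode = "in", weights = ag$cost,
                      algorithm = "dijkstra")), ag$nodes)
  list(ds = list(dist = ds, pred = .tight_parent(ag$tail, ag$head, ag$cost, ds)),
       dt = list(dist = dt, succ = .tight_parent(ag$head, ag$tail, ag$cost, dt)))
}

# deterministic tight-edge parent selection: for each head node the
# lexicographically smallest tail u with d[u] + cost(u, head) == d[head]
.tight_parent <- function(tails, heads, costs, d, tol = 1e-9) {
  ok <- is.finite(d[tails]) &
    abs(d[tails] + costs - d[heads]) <= tol * (1 + abs(d[heads]))
  res <- stats::setNames(rep(NA_character_, length(d)), names(d))
  if (!any(ok)) return(res)
  ht <- heads[ok]; tl <- tails[ok]
  o <- order(ht, tl)
  keep <- !duplicated(ht[o])
  res[ht[o][keep]] <- tl[o][keep]
  res
}

#' Shortest distances from the super source
#'
#' Runs Dijkstra's algorithm on the augmented graph from the super source
#' s to every node. The second node of every finite-distance path is a
#' source receptor (reached through a cost-0 super edge). Predecessor ties
#' are broken by the smallest node ID so reconstructed optimal paths are
#' deterministic.
#'
#' @param ag an `augmented_graph` from [augment_with_super_nodes()].
#' @return A list with `dist` (named numeric; `Inf` for unreachable nodes)
#'   and `pred` (named character; the chosen predecessor on one optimal
#'   path from s, `NA` where undefined).
#' @export
shortest_distances_from_source <- function(ag) {
  if (any(ag$cost < 0)) stop("negative edge costs violate Dijkstra's precondition")
  ig <- .ag_igraph(ag)
  d <- stats::setNames(as.vector(
    igraph::distances(ig, v = match(ag$super_source, ag$nodes), mode = "out",
                      weights = ag$cost, algorithm = "dijkstra")), ag$nodes)
  list(dist = d, pred = .tight_parent(ag$tail, ag$head, ag$cost, d))
}

#' Shortest distances to the super target
#'
#' Computes, for every node v, the cost of the cheapest path from v to the
#' super target t in the original edge orientation (equivalently, Dijkstra
#' from t on the edge-reversed graph, with every resulting path reversed
#' back). The penultimate node of every finite path is a target TF.
#'
#' @inheritParams shortest_distances_from_source
#' @return A list with `dist` (named numeric) and `succ` (named character;
#'   the chosen successor towards t on one optimal path).
#' @export
shortest_distances_to_target <- function(ag) {
  if (any(ag$cost < 0)) stop("negative edge costs violate Dijkstra's precondition")
  ig <- .ag_igraph(ag)
  d <- stats::setNames(as.vector(
    igraph::distances(ig, v = match(ag$super_target, ag$nodes), mode = "in",
                      weights = ag$cost, algorithm = "dijkstra")), ag$nodes)
  # successor on a v -> t optimal path = tight parent in the reversed graph
  list(dist = d, succ = .tight_parent(ag$head, ag$tail, ag$cost, d))
}

.walk_chain <- function(start, step, stop_at, max_steps) {
  out <- character(max_steps)
  cur <- start; i <- 0L
  while (!identical(cur, stop_at)) {
    i <- i + 1L
    if (i > max_steps)
      stop("path reconstruction exceeded the node count; ",
           "zero-cost cycles (weight-1 edges) are not supported")
    out[i] <- cur
    cur <- step[[cur]]
    if (is.na(cur)) stop("broken shortest-path chain at ", out[i])
  }
  out[seq_len(i)]
}

#' Best source-to-target path through every edge
#'
#' For each original edge (u, v) with finite d_s(u) and d_t(v),
#' concatenates the cheapest s-to-u path, the edge (u, v) and the cheapest
#' v-to-t path, giving the cheapest s-to-t path using that edge, of cost
#' d_s(u) + cost(u, v) + d_t(v). Different edges may share a cheapest path;
#' duplicates are kept once (the candidate list has at most |E| entries).
#' Super nodes s and t are stripped from every path.
#'
#' @param ag an `augmented_graph`.
#' @param d_s result of [shortest_distances_from_source()].
#' @param d_t result of [shortest_distances_to_target()].
#' @param max_cost only construct candidates of cost at most `max_cost`
#'   (plus a small tolerance); `Inf` keeps all.
#' @return A data.frame with columns `path` (node IDs joined by `|`) and
#'   `cost`, one row per distinct candidate path, unsorted. The attribute
#'   `edge_path` maps each original edge index to the path string it
#'   generated (`NA` where no candidate exists).
#' @export
per_edge_best_paths <- function(ag, d_s, d_t, max_cost = Inf) {
  n <- ag$n_original
  idx <- seq_len(n)
  tot <- d_s$dist[ag$tail[idx]] + ag$cost[idx] + d_t$dist[ag$head[idx]]
  keep <- is.finite(tot) & tot <= max_cost + 1e-9 * (1 + abs(max_cost))
  edge_path <- rep(NA_character_, n)
  which_keep <- which(keep)
  if (length(which_keep)) {
    nv <- length(ag$nodes)
    paths <- vapply(which_keep, function(i) {
      pre <- rev(.walk_chain(ag$tail[i], d_s$pred, ag$super_source, nv))
      suf <- .walk_chain(ag$head[i], d_t$succ, ag$super_target, nv)
      paste(c(pre, suf), collapse = "|")
    }, "")
    edge_path[which_keep] <- paths
    first <- !duplicated(paths)
    out <- data.frame(path = paths[first], cost = as.numeric(tot[which_keep][first]),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(path = character(0), cost = numeric(0),
                      stringsAsFactors = FALSE)
  }
  attr(out, "edge_path") <- edge_path
  rownames(out) <- NULL
  out
}

#' Rank candidate paths and build the signaling network
#'
#' Sorts candidate paths by increasing cost (equivalently decreasing
#' score), breaking ties lexicographically on the node-ID sequence, and
#' forms the toxicant signaling network as the union of the top `k` paths.
#' Every edge of the network is annotated with the rank of the first path
#' in which it appears.
#'
#' @param candidates data.frame from [per_edge_best_paths()] (or any
#'   data.frame with `path` and `cost` columns).
#' @param k number of top-ranked paths to retain (k >= 1).
#' @param ag optional `augmented_graph`, used to annotate network edges
#'   with their orientation.
#' @param chemical optional chemical/toxicant identifier.
#' @param include_degenerate keep single-node degenerate paths (a protein
#'   that is both source and target); dropped by default.
#' @return An object of class `signaling_network`: list with `chemical`,
#'   `k`, `candidates` (all ranked paths: `rank`, `score`, `cost`, `path`),
#'   `paths` (the top-k subset), `nodes`, `edges` (data.frame `tail`,
#'   `head`, `first_path_rank`, and `orientation` when `ag` is given) and
#'   `disconnected` (TRUE when no source-to-target path exists, in which
#'   case the network is empty and a warning is emitted).
#' @export
rank_and_truncate <- function(candidates, k, ag = NULL, chemical = NULL,
                              include_degenerate = FALSE) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  cand <- candidates
  if (!include_degenerate && nrow(cand))
    cand <- cand[grepl("|", cand$path, fixed = TRUE) , , drop = FALSE]
  if (nrow(cand) == 0L) {
    warning("no source-to-target path exists: disconnected result")
    net <- list(chemical = chemical, k = k,
                candidates = data.frame(rank = integer(0), score = numeric(0),
                                        cost = numeric(0), path = character(0)),
                paths = NULL, nodes = character(0),
                edges = data.frame(tail = character(0), head = character(0),
                                   first_path_rank = integer(0)),
                disconnected = TRUE)
    net$paths <- net$candidates
    return(structure(net, class = "signaling_network"))
  }
  o <- order(round(cand$cost, 9), cand$path)
  cand <- cand[o, , drop = FALSE]
  ranked <- data.frame(rank = seq_len(nrow(cand)),
                       score = exp(-cand$cost),
                       cost = cand$cost, path = cand$path,
                       stringsAsFactors = FALSE)
  rownames(ranked) <- NULL
  top <- ranked[seq_len(min(k, nrow(ranked))), , drop = FALSE]
  net_edges <- .paths_edge_ranks(top$path)
  if (!is.null(ag) && nrow(net_edges)) {
    okey <- paste(ag$tail, ag$head, sep = "\r")
    net_edges$orientation <- ag$orientation[
      match(paste(net_edges$tail, net_edges$head, sep = "\r"), okey)]
  }
  structure(list(chemical = chemical, k = k, candidates = ranked,
                 paths = top,
                 nodes = sort(unique(unlist(strsplit(top$path, "|", fixed = TRUE)))),
                 edges = net_edges, disconnected = FALSE),
            class = "signaling_network")
}

.paths_edge_ranks <- function(paths) {
  tails <- character(0); heads <- character(0); ranks <- integer(0)
  for (r in seq_along(paths)) {
    nd <- strsplit(paths[[r]], "|", fixed = TRUE)[[1L]]
    if (length(nd) < 2L) next
    tails <- c(tails, nd[-length(nd)])
    heads <- c(heads, nd[-1L])
    ranks <- c(ranks, rep(r, length(nd) - 1L))
  }
  key <- paste(tails, heads, sep = "\r")
  keep <- !duplicated(key)
  out <- data.frame(tail = tails[keep], head = heads[keep],
                    first_path_rank = ranks[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.signaling_network <- function(x, ...) {
  cat("signaling network",
      if (!is.null(x$chemical)) paste0("for ", x$chemical), "\n")
  if (x$disconnected) {
    cat("  DISCONNECTED: no source-to-target path\n")
  } else {
    cat("  ", nrow(x$paths), "of", nrow(x$candidates),
        "candidate paths retained (k =", x$k, ")\n",
        "  ", length(x$nodes), "proteins,", nrow(x$edges), "edges\n")
  }
  invisible(x)
}

#' Reconstruct toxicant signaling networks with EdgeLinker
#'
#' For every edge (u, v) of the interactome, EdgeLinker finds the cheapest
#' (highest-scoring) path from any responsive receptor in `sources` to any
#' responsive TF in `targets` that uses that edge, then returns the `k`
#' highest-scoring of these per-edge paths as the toxicant signaling
#' network. Because each retained path is the best path for at least one
#' edge, increasing `k` always grows the network by at least one edge while
#' another candidate path exists (with continuous weights).
#'
#' Sources/targets not present in the interactome are dropped with a
#' warning (the responsive proteins must be members of V).
#'
#' @param g an [interactome].
#' @param sources,targets character vectors: responsive receptors S_x and
#'   responsive TFs T_x.
#' @param k number of paths to retain (default 150). All candidate paths
#'   are kept, ranked, in the result so any other cutoff can be re-applied.
#' @param chemical optional chemical identifier carried into the result.
#' @param include_degenerate see [rank_and_truncate()].
#' @return A `signaling_network`; see [rank_and_truncate()].
#' @examples
#' g <- interactome(tail = c("R", "M", "M"), head = c("M", "F", "G"),
#'                  weight = c(0.9, 0.8, 0.4))
#' edgelinker(g, sources = "R", targets = c("F", "G"), k = 1)$paths
#' @export
edgelinker <- function(g, sources, targets, k = 150, chemical = NULL,
                       include_degenerate = FALSE) {
  stopifnot(inherits(g, "interactome"))
  sources <- unique(as.character(sources))
  targets <- unique(as.character(targets))
  drop_s <- setdiff(sources, g$nodes)
  drop_t <- setdiff(targets, g$nodes)
  if (length(drop_s) || length(drop_t))
    warning("dropping sources/targets absent from the interactome: ",
            paste(c(drop_s, drop_t), collapse = ", "))
  sources <- intersect(sources, g$nodes)
  targets <- intersect(targets, g$nodes)
  if (length(sources) == 0L || length(targets) == 0L)
    stop("no sources or no targets remain in the interactome; ",
         "the signaling network is undefined")
  ag <- augment_with_super_nodes(g, sources, targets)
  run <- .el_run(ag)
  cand <- per_edge_best_paths(ag, run$ds, run$dt)
  if (include_degenerate) {
    both <- intersect(sources, targets)
    if (length(both))
      cand <- rbind(cand, data.frame(path = both, cost = 0,
                                     stringsAsFactors = FALSE))
  }
  suppressWarnings(
    net <- rank_and_truncate(cand, k, ag = ag, chemical = chemical,
                             include_degenerate = include_degenerate))
  if (net$disconnected)
    warning("sources are disconnected from targets",
            if (!is.null(chemical)) paste0(" for ", chemical))
  net
}

# count distinct candidate paths with score >= s_min (cost <= -log(s_min));
# cheap because only qualifying edges are reconstructed/deduplicated
.count_paths_at_score <- function(g, sources, targets, s_min) {
  sources <- intersect(unique(sources), g$nodes)
  targets <- intersect(unique(targets), g$nodes)
  if (length(sources) == 0L || length(targets) == 0L) return(0L)
  ag <- augment_with_super_nodes(g, sources, targets)
  run <- .el_run(ag)
  nrow(per_edge_best_paths(ag, run$ds, run$dt, max_cost = -log(s_min)))
}

#' Up-weight edges incident to strongly perturbed proteins
#'
#' Optional path-prioritization hook: the weight of every edge incident to
#' a responsive protein with a z-score is multiplied by a bonus factor
#' `1 + scale * max(z, 0)` (the larger of the two endpoint factors), then
#' re-capped below 1, so paths through strongly perturbed proteins rank
#' higher. With `scale = 0` the interactome is returned unchanged. The
#' topology is never altered; only the ranking can change.
#'
#' @param g an [interactome].
#' @param profile a [toxicant_profile()] supplying responsive proteins and
#'   z-scores (proteins without z-scores receive no bonus).
#' @param scale nonnegative bonus strength per z-score unit (default 0.1).
#' @param cap re-cap for boosted weights (default 0.99).
#' @return The re-weighted interactome.
#' @export
apply_responsive_bonus <- function(g, profile, scale = 0.1, cap = 0.99) {
  stopifnot(inherits(g, "interactome"), scale >= 0)
  if (scale == 0) return(g)
  z <- profile$zscores
  z <- z[names(z) %in% profile$responsive & !is.na(z)]
  if (length(z) == 0L) return(g)
  f <- stats::setNames(1 + scale * pmax(z, 0), names(z))
  fac <- function(p) ifelse(p %in% names(f), f[p], 1)
  bonus <- pmax(fac(g$edges$tail), fac(g$edges$head))
  g$edges$weight <- pmin(g$edges$weight * bonus, cap)
  g$edges$cost <- -log(g$edges$weight)
  g
}

#' Write ranked paths and ranked edges to TSV files
#'
#' Writes the candidate paths (`rank`, `score`, `cost`, `path` with nodes
#' joined by `|`) and the network edges ranked by the first path in which
#' they appear (`tail`, `head`, `first_path_rank`).
#'
#' @param net a `signaling_network`.
#' @param paths_file,edges_file output paths (either may be `NULL` to
#'   skip).
#' @param all_candidates write every ranked candidate path (default TRUE,
#'   so any k cutoff can be re-applied later) rather than only the top k.
#' @return Invisibly, the written file names.
#' @export
write_network <- function(net, paths_file = NULL, edges_file = NULL,
                          all_candidates = TRUE) {
  stopifnot(inherits(net, "signaling_network"))
  if (!is.null(paths_file)) {
    tab <- if (all_candidates) net$candidates else net$paths
    utils::write.table(tab, paths_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(edges_file))
    utils::write.table(net$edges, edges_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(c(paths_file, edges_file))
}
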