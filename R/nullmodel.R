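#' Degree-preserving randomization of an interactome
#'
#' Repeatedly selects two edges (a, b) and (c, d) at random and replaces
#' them with the swapped edges (a, d) and (c, b), rejecting any proposal
#' that would create a duplicate edge or a self-loop. The in- and
#' out-degree of every node (directed pool) and the degree of every node
#' (undirected pool) are preserved exactly, while interaction partners are
#' shuffled. Directed and undirected edges are swapped in separate pools.
#'
#' Edge weights travel with the tail's outgoing slot: the swap of
#' a->b (w1) and c->d (w2) yields a->d with w1 and c->b with w2, so the
#' weight multiset per pool is preserved.
#'
#' @param g an [interactome].
#' @param n_swaps accepted swaps per pool; `NULL` (default) uses 10 times
#'   the pool size. `0` returns the graph unchanged.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return A randomized [interactome] with identical degree sequences.
#' @export
swap_randomize <- function(g, n_swaps = NULL, seed = NULL) {
  stopifnot(inherits(g, "interactome"))
  if (!is.null(seed)) set.seed(seed)
  e <- g$edges
  dir <- e[e$orientation == "directed", , drop = FALSE]
  und2 <- e[e$orientation == "undirected", , drop = FALSE]
  # undirected pool: one record per unordered pair (tail < head)
  und <- und2[und2$tail < und2$head, , drop = FALSE]

  # proposals also rejected when they would duplicate an edge of the
  # OTHER pool, so the no-duplicate-directed-edge invariant holds for the
  # recombined graph
  nodes <- g$nodes
  if (length(nodes) <= 3000L) {
    # dense integer-indexed fast path
    adj_of <- function(t, h, sym = TRUE) {
      m <- matrix(FALSE, length(nodes), length(nodes))
      if (length(t)) {
        m[cbind(match(t, nodes), match(h, nodes))] <- TRUE
        if (sym) m[cbind(match(h, nodes), match(t, nodes))] <- TRUE
      }
      m
    }
    dir_sw <- .swap_pool_dense(match(dir$tail, nodes), match(dir$head, nodes),
                               length(nodes), n_swaps, undirected = FALSE,
                               pool = "directed",
                               forb = adj_of(und2$tail, und2$head, sym = FALSE))
    dir_sw <- list(tail = nodes[dir_sw$tail], head = nodes[dir_sw$head])
    und_sw <- .swap_pool_dense(match(und$tail, nodes), match(und$head, nodes),
                               length(nodes), n_swaps, undirected = TRUE,
                               pool = "undirected",
                               forb = adj_of(dir_sw$tail, dir_sw$head))
    und_sw <- list(tail = nodes[und_sw$tail], head = nodes[und_sw$head])
  } else {
    forb_dir <- .key_env(und2$tail, und2$head)
    dir_sw <- .swap_pool(dir$tail, dir$head, n_swaps, undirected = FALSE,
                         pool = "directed", forbidden = forb_dir)
    forb_und <- .key_env(dir_sw$tail, dir_sw$head)
    und_sw <- .swap_pool(und$tail, und$head, n_swaps, undirected = TRUE,
                         pool = "undirected", forbidden = forb_und)
  }
  dir$tail <- dir_sw$tail; dir$head <- dir_sw$head
  und$tail <- und_sw$tail; und$head <- und_sw$head
  und_rev <- und
  und_rev$tail <- und$head; und_rev$head <- und$tail
  new_interactome(rbind(dir, und, und_rev), nodes = g$nodes,
                  penalty_applied = g$penalty_applied)
}

# integer-indexed swap with a dense logical adjacency for membership; the
# forb matrix holds the other pool's edges (symmetric for the undirected
# pool so either derived direction blocks)
.swap_pool_dense <- function(ti, hi, nv, n_swaps, undirected, pool,
                             forb = NULL) {
  m <- length(ti)
  if (m < 2L) {
    if (m == 1L && (is.null(n_swaps) || n_swaps > 0L))
      warning("pool '", pool, "' has fewer than 2 edges; left unchanged")
    return(list(tail = ti, head = hi))
  }
  target <- if (is.null(n_swaps)) 10L * m else as.integer(n_swaps)
  if (target == 0L) return(list(tail = ti, head = hi))
  adj <- matrix(FALSE, nv, nv)
  adj[cbind(ti, hi)] <- TRUE
  if (undirected) adj[cbind(hi, ti)] <- TRUE
  accepted <- 0L; attempts <- 0L
  max_attempts <- 60L * target
  while (accepted < target && attempts < max_attempts) {
    blk <- min(512L, max_attempts - attempts)
    i1 <- sample.int(m, blk, replace = TRUE)
    i2 <- sample.int(m, blk, replace = TRUE)
    for (b in seq_len(blk)) {
      attempts <- attempts + 1L
      i <- i1[b]; j <- i2[b]
      if (i == j) next
      a <- ti[i]; bb <- hi[i]; cc <- ti[j]; d <- hi[j]
      if (a == d || cc == bb) next                       # self-loop
      if ((a == cc && d == bb) ||
          (undirected && a == bb && d == cc)) next       # identical new edges
      if (adj[a, d] || adj[cc, bb]) next                 # duplicate in pool
      if (!is.null(forb) && (forb[a, d] || forb[cc, bb])) next
      adj[a, bb] <- FALSE; adj[cc, d] <- FALSE
      adj[a, d] <- TRUE; adj[cc, bb] <- TRUE
      if (undirected) {
        adj[bb, a] <- FALSE; adj[d, cc] <- FALSE
        adj[d, a] <- TRUE; adj[bb, cc] <- TRUE
      }
      hi[i] <- d; hi[j] <- bb
      accepted <- accepted + 1L
      if (accepted >= target) break
    }
  }
  if (accepted < target)
    warning("pool '", pool, "': only ", accepted, " of ", target,
            " swaps accepted within the attempt budget")
  list(tail = ti, head = hi)
}

.key_env <- function(tails, heads) {
  e <- new.env(hash = TRUE, size = max(2L * length(tails), 16L))
  for (k in paste(tails, heads, sep = "\r")) assign(k, TRUE, envir = e)
  e
}

.swap_pool <- function(tails, heads, n_swaps, undirected, pool,
                       forbidden = NULL) {
  m <- length(tails)
  if (m < 2L) {
    if (m == 1L && (is.null(n_swaps) || n_swaps > 0L))
      warning("pool '", pool, "' has fewer than 2 edges; left unchanged")
    return(list(tail = tails, head = heads))
  }
  target <- if (is.null(n_swaps)) 10L * m else as.integer(n_swaps)
  if (target == 0L) return(list(tail = tails, head = heads))
  key <- function(t, h) {
    if (undirected) paste(pmin(t, h), pmax(t, h), sep = "\r")
    else paste(t, h, sep = "\r")
  }
  seen <- new.env(hash = TRUE, size = 2L * m)
  for (k in key(tails, heads)) assign(k, TRUE, envir = seen)
  accepted <- 0L
  attempts <- 0L
  max_attempts <- 60L * target
  while (accepted < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    ij <- sample.int(m, 2L)
    i <- ij[1L]; j <- ij[2L]
    a <- tails[i]; b <- heads[i]; c <- tails[j]; d <- heads[j]
    if (a == d || c == b) next                       # self-loop
    k1 <- key(a, d); k2 <- key(c, b)
    if (k1 == k2 || exists(k1, envir = seen) || exists(k2, envir = seen))
      next                                           # duplicate
    if (!is.null(forbidden) && (
      exists(paste(a, d, sep = "\r"), envir = forbidden) ||
      exists(paste(c, b, sep = "\r"), envir = forbidden) ||
      (undirected && (exists(paste(d, a, sep = "\r"), envir = forbidden) ||
                      exists(paste(b, c, sep = "\r"), envir = forbidden)))))
      next                                           # collides with other pool
    rm(list = c(key(a, b), key(c, d)), envir = seen)
    assign(k1, TRUE, envir = seen)
    assign(k2, TRUE, envir = seen)
    heads[i] <- d; heads[j] <- b
    accepted <- accepted + 1L
  }
  if (accepted < target)
    warning("pool '", pool, "': only ", accepted, " of ", target,
            " swaps accepted within the attempt budget")
  list(tail = tails, head = heads)
}

#' Score threshold and tie-aware path count of a signaling network
#'
#' Computes s_k, the score of the k-th ranked path, and c0, the number of
#' candidate paths with score >= s_k (c0 can exceed k only through ties).
#' When the network has fewer than k candidates, the last (lowest-scoring)
#' candidate defines s_k.
#'
#' @param net a `signaling_network` from [edgelinker()].
#' @param k path-rank cutoff; defaults to the network's own k.
#' @return A list with `s_k` and `c0`.
#' @export
path_score_threshold <- function(net, k = net$k) {
  stopifnot(inherits(net, "signaling_network"))
  cand <- net$candidates
  if (nrow(cand) == 0L) stop("disconnected network has no path scores")
  kk <- min(k, nrow(cand))
  s_k <- cand$score[kk]
  cost_k <- cand$cost[kk]
  list(s_k = s_k,
       c0 = sum(cand$cost <= cost_k + 1e-9 * (1 + cost_k)))
}

#' Null distribution of path counts over randomized interactomes
#'
#' Generates `N` degree-preserving randomized interactomes and, for each,
#' counts the number of candidate source-to-target paths with score at
#' least `s_k` (over the full per-edge candidate list, not truncated at
#' k), using the same sources and targets as the original analysis. A
#' randomized network with no source-to-target connectivity contributes 0.
#'
#' @param g the original [interactome].
#' @param sources,targets responsive receptors and TFs of the chemical.
#' @param s_k score threshold from the original network (see
#'   [path_score_threshold()]).
#' @param N ensemble size (the reference analysis uses 10,000; tests use
#'   100-500).
#' @param seed integer seed for the whole ensemble.
#' @param n_swaps passed to [swap_randomize()].
#' @return Integer vector Y of length `N`.
#' @export
null_path_counts <- function(g, sources, targets, s_k, N, seed = NULL,
                             n_swaps = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(N), function(n) {
    r <- suppressWarnings(swap_randomize(g, n_swaps = n_swaps))
    .count_paths_at_score(r, sources, targets, s_k)
  }, 0L)
}

#' Permutation p-value with pseudocount
#'
#' `P_perm = (1 + sum(Y_n >= c0)) / N`, capped at 1. The pseudocount makes
#' the smallest attainable p-value exactly 1/N: had all permutations been
#' enumerable, at least one randomized network would be the original
#' interactome itself.
#'
#' @param c0 number of paths with score >= s_k in the original network.
#' @param Y integer vector of null path counts ([null_path_counts()]).
#' @return P_perm in \[1/N, 1\].
#' @export
permutation_pvalue <- function(c0, Y) {
  N <- length(Y)
  if (N < 1L) stop("Y must contain at least one null count")
  min((1 + sum(Y >= c0)) / N, 1)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; order-preserving and elementwise >= the input p-values.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values, same length and order as `p`.
#' @export
bh_qvalues <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Significance of signaling networks against the permutation null
#'
#' End-to-end significance pipeline: for each chemical profile, runs
#' EdgeLinker on the original interactome, computes s_k and c0, generates
#' the degree-preserving null ensemble, and reports the permutation
#' p-value, its GPD-refined version ([gpd_refined_pvalue()]) and BH
#' q-values across all chemicals.
#'
#' @param g an [interactome].
#' @param profiles a list of [toxicant_profile()] objects (or lists with
#'   `chemical`, `sources`, `targets`).
#' @param k EdgeLinker path cutoff (default 150).
#' @param N null ensemble size.
#' @param seed integer seed.
#' @param n_exceed_start starting tail size for the GPD fit; set to
#'   `Inf`/`NA` to skip refinement. Automatically skipped when `N` is
#'   smaller than `n_exceed_start`.
#' @param n_swaps passed to [swap_randomize()].
#' @return A data.frame with one row per chemical: `chemical`, `s_k`,
#'   `c0`, `P_perm`, `P_gpd`, `q`, `n_exceed`.
#' @export
significance <- function(g, profiles, k = 150, N = 1000, seed = NULL,
                         n_exceed_start = 250, n_swaps = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(profiles, function(pr) {
    net <- edgelinker(g, pr$sources, pr$targets, k = k,
                      chemical = pr$chemical)
    th <- path_score_threshold(net)
    Y <- null_path_counts(g, pr$sources, pr$targets, th$s_k, N,
                          n_swaps = n_swaps)
    p_perm <- permutation_pvalue(th$c0, Y)
    if (is.finite(n_exceed_start) && N >= n_exceed_start) {
      ref <- gpd_refined_pvalue(Y, th$c0, n_exceed_start = n_exceed_start)
      p_gpd <- ref$p; n_ex <- ref$n_exceed
    } else {
      p_gpd <- p_perm; n_ex <- NA_integer_
    }
    data.frame(chemical = pr$chemical, s_k = th$s_k, c0 = th$c0,
               P_perm = p_perm, P_gpd = p_gpd, n_exceed = n_ex,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_qvalues(out$P_gpd)
  rownames(out) <- NULL
  out[, c("chemical", "s_k", "c0", "P_perm", "P_gpd", "q", "n_exceed")]
}
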