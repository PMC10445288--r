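#' Weighted protein interactome
#'
#' An `interactome` is a directed, weighted graph G = (V, E, w) whose nodes
#' are proteins and whose edges are physical or regulatory interactions.
#' Each edge weight lies in (0, 1] and summarises the amount of evidence
#' supporting the interaction; the cost of an edge is the negative natural
#' logarithm of its weight, so that the lowest-cost path is also the
#' highest-scoring (largest product of weights) path.
#'
#' Undirected source interactions are stored *bidirected*: each undirected
#' record (u, v) yields the two directed edges u -> v and v -> u with equal
#' weight and orientation `"undirected"`. Directed records keep orientation
#' `"directed"`. Self-loops and duplicate directed edges are never present.
#'
#' @param tail,head character vectors of protein identifiers (equal length).
#' @param weight numeric edge weights in (0, 1].
#' @param directed logical; `FALSE` rows are treated as undirected
#'   interactions and bidirected into two directed edges.
#' @param evidence optional character vector of comma-separated evidence
#'   source names per input record.
#' @param nodes optional character vector of node identifiers to include
#'   even if isolated.
#' @return An object of class `interactome`: a list with elements `nodes`
#'   (sorted character vector), `edges` (data.frame with columns `tail`,
#'   `head`, `weight`, `cost`, `orientation`, `evidence`) and the logical
#'   flag `penalty_applied`.
#' @examples
#' g <- interactome(tail = c("A", "B"), head = c("B", "C"),
#'                  weight = c(0.8, 0.5), directed = c(TRUE, FALSE))
#' g$edges
#' @export
interactome <- function(tail, head, weight, directed = TRUE,
                        evidence = NULL, nodes = NULL) {
  n <- length(tail)
  stopifnot(length(head) == n, length(weight) == n)
  directed <- rep_len(as.logical(directed), n)
  if (is.null(evidence)) evidence <- rep("", n)
  evidence <- rep_len(as.character(evidence), n)
  tail <- as.character(tail)
  head <- as.character(head)
  if (any(!is.finite(weight)) || any(weight <= 0) || any(weight > 1))
    stop("edge weights must lie in (0, 1]")
  loop <- tail == head
  if (any(loop)) {
    warning(sum(loop), " self-loop record(s) dropped")
    tail <- tail[!loop]; head <- head[!loop]; weight <- weight[!loop]
    directed <- directed[!loop]; evidence <- evidence[!loop]
  }
  und <- !directed
  etail <- c(tail[directed], tail[und], head[und])
  ehead <- c(head[directed], head[und], tail[und])
  ew    <- c(weight[directed], weight[und], weight[und])
  eor   <- c(rep("directed", sum(directed)), rep("undirected", 2L * sum(und)))
  eev   <- c(evidence[directed], evidence[und], evidence[und])
  key <- paste(etail, ehead, sep = "\r")
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    # merge duplicates: max weight, union of evidence, "directed" wins
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      ew[idx[1L]] <- max(ew[idx])
      eor[idx[1L]] <- if (any(eor[idx] == "directed")) "directed" else "undirected"
      eev[idx[1L]] <- paste(unique(unlist(strsplit(eev[idx], ","))), collapse = ",")
    }
    etail <- etail[keep]; ehead <- ehead[keep]; ew <- ew[keep]
    eor <- eor[keep]; eev <- eev[keep]
  }
  all_nodes <- sort(unique(c(etail, ehead, nodes)))
  edges <- data.frame(tail = etail, head = ehead, weight = ew,
                      cost = -log(ew), orientation = eor, evidence = eev,
                      stringsAsFactors = FALSE)
  structure(list(nodes = all_nodes, edges = edges, penalty_applied = FALSE),
            class = "interactome")
}

new_interactome <- function(edges, nodes = NULL, penalty_applied = FALSE) {
  # fast internal constructor: `edges` already bidirected & validated
  edges$cost <- -log(edges$weight)
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$tail, edges$head, nodes))),
                 edges = edges, penalty_applied = penalty_applied),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  nd <- sum(x$edges$orientation == "directed")
  cat("interactome:", length(x$nodes), "proteins,", nrow(x$edges),
      "directed edges\n  (", nd, "regulatory,",
      nrow(x$edges) - nd, "bidirected-physical; undirected penalty",
      if (x$penalty_applied) "applied" else "not applied", ")\n")
  invisible(x)
}

#' Load an interactome from a tab-separated edge table
#'
#' The edge table has one interaction record per row with columns
#' `tail`, `head`, `directed` (1 = directed/regulatory, 0 = undirected/
#' physical) and `evidence_sources` (comma-separated evidence source
#' names). Records are merged per edge (union of evidence), self-loops
#' dropped with a warning, undirected records bidirected, and a weight in
#' (0, 1] computed from the supporting evidence via a noisy-OR over
#' per-source confidences ([combine_evidence_weights()]).
#'
#' When a directed record exists for a protein pair, any undirected record
#' for the same pair is treated as replaced by the predicted direction: its
#' evidence is merged into the directed edge(s) and no undirected-derived
#' edges are created for that pair.
#'
#' A file whose header is `tail  head  weight  cost  orientation` (the
#' weighted edge list written by [write_interactome()]) is recognised and
#' read back verbatim, with no evidence weighting.
#'
#' @param path path to the TSV edge table.
#' @param source_confidences named numeric vector or two-column data.frame
#'   (`source`, `confidence`) mapping evidence source names to confidences
#'   in (0, 1); `NULL` assigns `default_confidence` to every source.
#' @param default_confidence confidence used for all sources when
#'   `source_confidences` is `NULL`.
#' @param cap upper cap on combined edge weights, keeping costs strictly
#'   positive (default 0.99).
#' @return An [interactome] object.
#' @export
load_interactome <- function(path, source_confidences = NULL,
                             default_confidence = 0.6, cap = 0.99) {
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0L) stop("empty interactome file: ", path)
  first <- strsplit(raw[[1L]], "\t", fixed = TRUE)[[1L]]
  if (identical(tolower(first[1:3]), c("tail", "head", "weight"))) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (any(tab$weight <= 0 | tab$weight > 1))
      stop("weights in ", path, " must lie in (0, 1]")
    return(new_interactome(data.frame(
      tail = tab$tail, head = tab$head, weight = tab$weight,
      orientation = tab$orientation, evidence = "",
      stringsAsFactors = FALSE)))
  }
  has_header <- identical(tolower(first[1:2]), c("tail", "head"))
  body <- if (has_header) raw[-1L] else raw
  if (length(body) == 0L) stop("interactome file has a header but no records: ", path)
  rows <- strsplit(body, "\t", fixed = TRUE)
  offset <- if (has_header) 1L else 0L
  bad <- which(vapply(rows, length, 1L) < 4L)
  if (length(bad))
    stop("malformed interactome record at line ", bad[1L] + offset,
         " (expected 4 tab-separated fields)")
  tail <- vapply(rows, `[[`, "", 1L)
  head <- vapply(rows, `[[`, "", 2L)
  dflag <- vapply(rows, `[[`, "", 3L)
  ev <- vapply(rows, `[[`, "", 4L)
  if (any(!nzchar(tail) | !nzchar(head)))
    stop("malformed interactome record at line ",
         which(!nzchar(tail) | !nzchar(head))[1L] + offset, " (empty node ID)")
  if (!all(dflag %in% c("0", "1")))
    stop("malformed interactome record at line ",
         which(!dflag %in% c("0", "1"))[1L] + offset,
         " (directed flag must be 0 or 1)")
  if (any(!nzchar(ev)))
    stop("malformed interactome record at line ",
         which(!nzchar(ev))[1L] + offset, " (no evidence source)")
  directed <- dflag == "1"

  loop <- tail == head
  if (any(loop)) {
    warning(sum(loop), " self-loop record(s) dropped")
    tail <- tail[!loop]; head <- head[!loop]
    directed <- directed[!loop]; ev <- ev[!loop]
  }
  if (length(tail) == 0L) stop("no valid interactome records in ", path)

  # merge records per edge; canonicalize undirected pairs
  canon_t <- ifelse(directed, tail, pmin(tail, head))
  canon_h <- ifelse(directed, head, pmax(tail, head))
  key <- paste(canon_t, canon_h, directed, sep = "\r")
  agg_ev <- function(e) paste(sort(unique(unlist(strsplit(e, ",", fixed = TRUE)))),
                              collapse = ",")
  first_idx <- !duplicated(key)
  ev_merged <- vapply(split(ev, factor(key, levels = key[first_idx])), agg_ev, "")
  mt <- canon_t[first_idx]; mh <- canon_h[first_idx]; md <- directed[first_idx]

  # directed record wins over a parallel undirected record for the same
  # unordered pair: merge undirected evidence into the directed edge(s),
  # drop the undirected-derived edges (replacement semantics)
  pair <- paste(pmin(mt, mh), pmax(mt, mh), sep = "\r")
  dir_pairs <- unique(pair[md])
  drop_und <- !md & pair %in% dir_pairs
  if (any(drop_und)) {
    for (i in which(drop_und)) {
      tgt <- which(md & pair == pair[i])
      ev_merged[tgt] <- vapply(paste(ev_merged[tgt], ev_merged[i], sep = ","),
                               agg_ev, "")
    }
    mt <- mt[!drop_und]; mh <- mh[!drop_und]
    md <- md[!drop_und]; ev_merged <- ev_merged[!drop_und]
  }

  conf <- .resolve_confidences(source_confidences, ev_merged, default_confidence)
  w <- vapply(strsplit(ev_merged, ",", fixed = TRUE), function(s)
    combine_evidence_weights(s, conf, cap = cap), 0)
  interactome(tail = mt, head = mh, weight = w, directed = md,
              evidence = ev_merged)
}

.resolve_confidences <- function(source_confidences, evidence, default) {
  sources <- unique(unlist(strsplit(evidence, ",", fixed = TRUE)))
  if (is.null(source_confidences))
    return(stats::setNames(rep(default, length(sources)), sources))
  if (is.data.frame(source_confidences))
    source_confidences <- stats::setNames(
      as.numeric(source_confidences[[2L]]),
      as.character(source_confidences[[1L]]))
  source_confidences
}

#' Combine per-source evidence confidences into one edge weight
#'
#' Evidence integration is a noisy-OR over the distinct supporting sources:
#' `w = 1 - prod(1 - c_s)`, capped below 1 so that every edge cost
#' `-log(w)` stays strictly positive and longer paths are never free. The
#' weight is monotone nondecreasing in the number of supporting sources and
#' invariant to their order.
#'
#' @param sources character vector of evidence source names (duplicates
#'   count once).
#' @param source_confidences named numeric vector mapping each source name
#'   to a confidence in (0, 1).
#' @param cap maximum combined weight (default 0.99).
#' @return A single weight in (0, cap].
#' @examples
#' combine_evidence_weights("y2h", c(y2h = 0.5))            # 0.5
#' combine_evidence_weights(c("a", "b"), c(a = .5, b = .5)) # 0.75
#' @export
combine_evidence_weights <- function(sources, source_confidences, cap = 0.99) {
  sources <- unique(sources)
  if (length(sources) == 0L) stop("at least one evidence source is required")
  unknown <- setdiff(sources, names(source_confidences))
  if (length(unknown))
    stop("unknown evidence source(s): ", paste(unknown, collapse = ", "),
         "; known sources: ", paste(names(source_confidences), collapse = ", "))
  cs <- source_confidences[sources]
  if (any(cs <= 0) || any(cs >= 1))
    stop("source confidences must lie in (0, 1)")
  min(1 - prod(1 - cs), cap)
}

#' Penalize undirected-derived edges
#'
#' Multiplies the weight of every undirected-derived edge by `penalty`,
#' prioritizing directed (regulatory) edges during path finding. Guarded:
#' applying the penalty twice is an error.
#'
#' @param g an [interactome].
#' @param penalty multiplicative factor in (0, 1); default 0.75.
#' @return The penalized interactome (`penalty_applied` set).
#' @export
apply_undirected_penalty <- function(g, penalty = 0.75) {
  stopifnot(inherits(g, "interactome"))
  if (!is.numeric(penalty) || length(penalty) != 1L ||
      penalty <= 0 || penalty >= 1)
    stop("penalty must be a single number in (0, 1)")
  if (isTRUE(g$penalty_applied))
    stop("undirected penalty has already been applied to this interactome")
  und <- g$edges$orientation == "undirected"
  g$edges$weight[und] <- g$edges$weight[und] * penalty
  g$edges$cost <- -log(g$edges$weight)
  g$penalty_applied <- TRUE
  g
}

#' Edge cost from edge weight
#'
#' The cost of an edge is the negative natural logarithm of its weight, so
#' path cost (sum of edge costs) and path score (product of edge weights)
#' induce the same ranking: score = exp(-cost).
#'
#' @param weight numeric vector of weights in (0, 1].
#' @return Nonnegative costs, same length as `weight`.
#' @export
edge_cost <- function(weight) {
  if (any(!is.finite(weight)) || any(weight <= 0) || any(weight > 1))
    stop("weights must lie in (0, 1]")
  -log(weight)
}

#' Write an interactome as a weighted edge list
#'
#' Writes a TSV with columns `tail`, `head`, `weight`, `cost`,
#' `orientation` (one row per directed edge, undirected pairs appearing
#' twice).
#'
#' @param g an [interactome].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(g, path) {
  stopifnot(inherits(g, "interactome"))
  utils::write.table(
    g$edges[, c("tail", "head", "weight", "cost", "orientation")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
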