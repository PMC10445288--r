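test_that("super-node augmentation wires sources and targets at cost zero", {
  g <- interactome(tail = c("A", "B", "C"), head = c("B", "C", "D"),
                   weight = c(0.5, 0.5, 0.5))
  ag <- augment_with_super_nodes(g, sources = c("A", "B"),
                                 targets = c("B", "C", "D"))
  sup <- ag$orientation == "super"
  expect_equal(sum(sup), 5L)                   # |S| + |T| new edges
  expect_true(all(ag$cost[sup] == 0))          # weight one => cost zero
  expect_true(all(ag$weight[sup] == 1))
  # a node in both S and T gets both an s->u and a u->t edge
  expect_true(any(ag$tail == ag$super_source & ag$head == "B"))
  expect_true(any(ag$tail == "B" & ag$head == ag$super_target))
  expect_error(augment_with_super_nodes(g, character(0), "D"), "nonempty")
  expect_error(augment_with_super_nodes(g, "A", "ZZ"), "not in the interactome")
})

test_that("distances from s and to t match hand sums on a chain", {
  # chain A -> B -> C with weights {1, 0.5}: d_s(C) = log 2, plus supers
  g <- interactome(tail = c("A", "B"), head = c("B", "C"),
                   weight = c(1, 0.5))
  ag <- augment_with_super_nodes(g, "A", "C")
  ds <- shortest_distances_from_source(ag)
  dt <- shortest_distances_to_target(ag)
  expect_equal(ds$dist[["A"]], 0)              # cost-0 super edge
  expect_equal(ds$dist[["B"]], 0)              # weight-1 edge A->B
  expect_equal(ds$dist[["C"]], log(2))
  expect_equal(dt$dist[["C"]], 0)
  expect_equal(dt$dist[["B"]], log(2))
  expect_equal(dt$dist[["A"]], log(2))
})

test_that("per-edge best paths match exhaustive oracles on small graphs", {
  for (seed in 1:30) {
    f <- rand_small_graph(n_nodes = sample(5:8, 1), n_edges = sample(8:14, 1),
                          seed = seed)
    res <- el_per_edge(f$g, f$sources, f$targets)
    e <- f$g$edges
    for (i in seq_len(nrow(e))) {
      oracle <- bf_walk_through_edge(f$g, f$sources, f$targets,
                                     e$tail[i], e$head[i], e$cost[i])
      ps <- res$edge_path[i]
      if (is.na(ps)) {
        expect_equal(oracle, Inf)
      } else {
        got <- res$cand$cost[match(ps, res$cand$path)]
        expect_equal(got, oracle, tolerance = 1e-9)
        nd <- strsplit(ps, "|", fixed = TRUE)[[1]]
        if (!anyDuplicated(nd)) {
          # node-simple candidates also equal the simple-path optimum
          expect_equal(got,
                       bf_simple_through_edge(f$g, f$sources, f$targets,
                                              e$tail[i], e$head[i]),
                       tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("duplicate per-edge paths collapse and degenerate edges vanish", {
  # single chain: every edge's best path is the same path
  g <- interactome(tail = c("A", "B"), head = c("B", "C"),
                   weight = c(0.5, 0.5))
  res <- el_per_edge(g, "A", "C")
  expect_equal(nrow(res$cand), 1L)
  expect_equal(res$cand$path, "A|B|C")
  # an edge whose head cannot reach any target produces no candidate
  g2 <- interactome(tail = c("A", "A"), head = c("B", "X"),
                    weight = c(0.5, 0.5), nodes = c("A", "B", "X"))
  res2 <- el_per_edge(g2, "A", "B")
  expect_equal(res2$cand$path, "A|B")
  expect_true(is.na(res2$edge_path[g2$edges$head == "X"]))
})

test_that("ranking truncates at k with deterministic lexicographic ties", {
  cand <- data.frame(path = c("B|C", "A|C", "A|B|C"),
                     cost = c(1, 1, 2))
  net <- rank_and_truncate(cand, k = 10)
  expect_equal(net$candidates$path, c("A|C", "B|C", "A|B|C"))
  expect_equal(nrow(net$paths), 3L)            # k beyond candidates: all kept
  net1 <- rank_and_truncate(cand, k = 1)
  expect_equal(net1$paths$path, "A|C")
  expect_equal(net1$edges$first_path_rank, 1L)
  # scores are exp(-cost)
  expect_equal(net$candidates$score, exp(-net$candidates$cost))
})

test_that("k = 1 returns the global cheapest path, sans super nodes", {
  for (seed in 31:40) {
    f <- rand_small_graph(seed = seed)
    paths <- bf_all_paths(f$g$edges, f$sources, f$targets)
    net <- tryCatch(
      suppressWarnings(edgelinker(f$g, f$sources, f$targets, k = 1)),
      error = function(e) NULL)
    if (length(paths) == 0) {
      expect_true(is.null(net) || net$disconnected)
    } else {
      best <- min(vapply(paths, `[[`, 0, "cost"))
      expect_equal(net$paths$cost[1], best, tolerance = 1e-9)
      nd <- strsplit(net$paths$path[1], "|", fixed = TRUE)[[1]]
      expect_true(nd[1] %in% f$sources)
      expect_true(nd[length(nd)] %in% f$targets)
    }
  }
})

test_that("each extra path adds at least one new edge (edge growth)", {
  n_checked <- 0
  for (seed in 41:55) {
    spec <- synthetic_spec(n_nodes = 25, n_directed = 40, n_undirected = 15,
                           n_planted = 2, seed = seed)
    gen <- generate_interactome(spec)
    net <- edgelinker(gen$interactome, gen$sources, gen$targets,
                      k = nrow(gen$interactome$edges))
    kmax <- nrow(net$candidates)
    edges_at <- function(k) {
      top <- net$candidates$path[seq_len(k)]
      unique(unlist(lapply(strsplit(top, "|", fixed = TRUE), function(nd)
        paste(nd[-length(nd)], nd[-1]))))
    }
    prev <- edges_at(1)
    for (k in seq_len(min(kmax, 25) - 1)) {
      cur <- edges_at(k + 1)
      expect_true(all(prev %in% cur) && length(cur) > length(prev))
      prev <- cur
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 50)
})

test_that("sources disconnected from targets give an explicit result", {
  g <- interactome(tail = c("A", "C"), head = c("B", "D"),
                   weight = c(0.5, 0.5))
  expect_warning(net <- edgelinker(g, "A", "D", k = 5), "disconnected")
  expect_true(net$disconnected)
  expect_equal(length(net$nodes), 0L)
  expect_error(path_score_threshold(net), "disconnected")
})

test_that("the z-score bonus reroutes ties and zero bonus is the identity", {
  # two equal-cost routes R -> {M1 | M2} -> T
  g <- interactome(tail = c("R", "R", "M1", "M2"),
                   head = c("M1", "M2", "T", "T"),
                   weight = c(0.5, 0.5, 0.5, 0.5))
  prof <- structure(list(chemical = "x", sources = "R", targets = "T",
                         responsive = c("R", "T", "M2"),
                         responsive_intermediates = "M2",
                         nonresponsive = character(0),
                         zscores = c(M2 = 4)), class = "toxicant_profile")
  expect_equal(apply_responsive_bonus(g, prof, scale = 0), g)
  gb <- apply_responsive_bonus(g, prof, scale = 0.2)
  net <- edgelinker(gb, "R", "T", k = 1)
  expect_equal(net$paths$path, "R|M2|T")
  # monotonicity: boosted edges never get more expensive
  expect_true(all(gb$edges$cost <= g$edges$cost + 1e-12))
})

test_that("identical inputs produce byte-identical output files", {
  gen <- generate_interactome(synthetic_spec(seed = 99))
  run <- function() {
    net <- edgelinker(gen$interactome, gen$sources, gen$targets, k = 10)
    pf <- tempfile(); ef <- tempfile()
    write_network(net, pf, ef)
    c(paths = paste(readLines(pf), collapse = "\n"),
      edges = paste(readLines(ef), collapse = "\n"))
  }
  expect_identical(run(), run())
})
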