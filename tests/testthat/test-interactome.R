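write_edge_table <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("tail\thead\tdirected\tevidence_sources", rows), path)
  path
}

test_that("loading merges duplicate records and bidirects undirected edges", {
  path <- write_edge_table(c("A\tB\t1\ty2h",
                             "B\tC\t0\tcoip",
                             "B\tC\t0\tmint"))
  g <- load_interactome(path, default_confidence = 0.5)
  expect_setequal(g$nodes, c("A", "B", "C"))
  # A->B directed; B-C merged to one undirected record, bidirected
  expect_equal(nrow(g$edges), 3L)
  expect_equal(sum(g$edges$orientation == "directed"), 1L)
  bc <- g$edges[g$edges$orientation == "undirected", ]
  expect_setequal(paste(bc$tail, bc$head), c("B C", "C B"))
  # merged evidence (coip + mint) -> noisy-OR of two 0.5 confidences
  expect_equal(unique(bc$weight), 0.75)
  expect_equal(unique(bc$evidence), "coip,mint")
})

test_that("self-loops are dropped with a warning and empty files error", {
  path <- write_edge_table(c("A\tA\t0\ty2h", "A\tB\t1\ty2h"))
  expect_warning(g <- load_interactome(path), "self-loop")
  expect_equal(nrow(g$edges), 1L)
  empty <- tempfile()
  writeLines(character(0), empty)
  expect_error(load_interactome(empty), "empty")
  path2 <- write_edge_table("A\tB\t1")  # missing evidence field
  expect_error(load_interactome(path2), "line 2")
  path3 <- write_edge_table("A\tB\t2\ty2h")
  expect_error(load_interactome(path3), "directed flag")
})

test_that("a directed record replaces a parallel undirected record", {
  path <- write_edge_table(c("A\tB\t1\tpredicted",
                             "B\tA\t0\tcoip"))
  g <- load_interactome(path, default_confidence = 0.5)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$orientation, "directed")
  expect_equal(g$edges$tail, "A")
  # the undirected evidence still contributes to the weight
  expect_equal(g$edges$evidence, "coip,predicted")
  expect_equal(g$edges$weight, 0.75)
})

test_that("a 10-edge synthetic table round-trips through write + load", {
  set.seed(11)
  nodes <- sprintf("Q%02d", 1:8)
  tails <- sample(nodes, 10, replace = TRUE)
  heads <- sample(nodes, 10, replace = TRUE)
  keep <- tails != heads & !duplicated(paste(tails, heads))
  rows <- paste(tails[keep], heads[keep],
                sample(0:1, sum(keep), replace = TRUE), "src1", sep = "\t")
  path <- write_edge_table(rows)
  g1 <- load_interactome(path, source_confidences = c(src1 = 0.7))
  # write the weighted edge list, reload it as data, and rebuild
  out <- tempfile(fileext = ".tsv")
  write_interactome(g1, out)
  tab <- read.delim(out)
  g2 <- interactome(tail = tab$tail, head = tab$head, weight = tab$weight,
                    directed = tab$orientation == "directed")
  expect_equal(g2$edges[order(g2$edges$tail, g2$edges$head),
                        c("tail", "head", "weight", "cost")],
               g1$edges[order(g1$edges$tail, g1$edges$head),
                        c("tail", "head", "weight", "cost")],
               ignore_attr = TRUE)
})

test_that("noisy-OR evidence combination matches its closed form", {
  conf <- c(a = 0.5, b = 0.5, c = 0.9, d = 0.9, e = 0.9)
  expect_equal(combine_evidence_weights("a", conf), 0.5)
  expect_equal(combine_evidence_weights(c("a", "b"), conf), 0.75)
  # 1 - 0.1^3 = 0.999, then the cap applies
  expect_equal(combine_evidence_weights(c("c", "d", "e"), conf), 0.99)
  expect_equal(combine_evidence_weights(c("c", "d", "e"), conf, cap = 0.999),
               0.999)
  expect_error(combine_evidence_weights("zz", conf), "unknown evidence source")
  # order invariance and monotonicity in the number of sources
  set.seed(3)
  cs <- setNames(runif(6, 0.1, 0.9), letters[1:6])
  for (r in 1:5) {
    pick <- sample(names(cs), sample(2:6, 1))
    expect_equal(combine_evidence_weights(pick, cs),
                 combine_evidence_weights(rev(pick), cs))
    expect_gte(combine_evidence_weights(pick, cs),
               max(combine_evidence_weights(pick[1], cs, cap = 1) - 1e-12, 0))
  }
})

test_that("undirected penalty multiplies only undirected edges, once", {
  g <- interactome(tail = c("A", "B"), head = c("B", "C"),
                   weight = c(0.6, 0.8), directed = c(TRUE, FALSE))
  gp <- apply_undirected_penalty(g, 0.5)
  expect_equal(gp$edges$weight[gp$edges$orientation == "directed"], 0.6)
  expect_equal(unique(gp$edges$weight[gp$edges$orientation == "undirected"]),
               0.4)
  expect_error(apply_undirected_penalty(gp, 0.5), "already been applied")
  expect_error(apply_undirected_penalty(g, 1.2), "penalty")
  g_dir <- interactome("A", "B", 0.6, directed = TRUE)
  expect_equal(apply_undirected_penalty(g_dir, 0.5)$edges$weight, 0.6)
})

test_that("edge cost is -log(weight) and score/cost rankings agree", {
  expect_equal(edge_cost(1), 0)
  expect_equal(edge_cost(0.5), log(2))
  expect_error(edge_cost(0), "weights")
  expect_error(edge_cost(1.1), "weights")
  set.seed(7)
  for (r in 1:20) {
    w <- runif(sample(2:6, 1), 0.01, 1)
    cost <- sum(edge_cost(w))
    expect_equal(prod(w), exp(-cost))
  }
  # ranking by summed cost equals ranking by product score on path sets
  set.seed(8)
  costs <- replicate(30, sum(edge_cost(runif(sample(1:5, 1), 0.05, 0.99))))
  expect_equal(order(costs), order(exp(-costs), decreasing = TRUE))
})

test_that("bidirection doubles undirected records, keeps directed count", {
  set.seed(21)
  n_dir <- 7; n_und <- 5
  tails <- sprintf("U%02d", 1:(n_dir + n_und))
  heads <- sprintf("U%02d", 2:(n_dir + n_und + 1))
  g <- interactome(tails, heads, runif(n_dir + n_und, 0.2, 0.9),
                   directed = rep(c(TRUE, FALSE), c(n_dir, n_und)))
  expect_equal(sum(g$edges$orientation == "directed"), n_dir)
  expect_equal(sum(g$edges$orientation == "undirected"), 2L * n_und)
  und <- g$edges[g$edges$orientation == "undirected", ]
  key <- paste(und$tail, und$head, sep = "|")
  rev_key <- paste(und$head, und$tail, sep = "|")
  expect_setequal(key, rev_key)  # every undirected edge has its reverse
  # equal weights across the two directions
  expect_equal(und$weight[match(key, rev_key)], und$weight)
})
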