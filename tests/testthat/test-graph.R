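corr_from_matrix <- function(r, m = 10) {
  ids <- if (!is.null(rownames(r))) rownames(r)
         else paste0("e", seq_len(nrow(r)))
  p <- matrix(corr_pvalue(as.vector(r), m), nrow(r), ncol(r))
  diag(p) <- 0
  dimnames(r) <- dimnames(p) <- list(ids, ids)
  structure(list(entity_ids = ids, r_matrix = r, p_matrix = p,
                 method = "pearson", m = m),
            class = "correlation_result")
}

test_that("network construction applies the joint r and p gate", {
  ones <- corr_from_matrix(matrix(1, 4, 4))
  g <- build_network(ones, r_min = 0.65, alpha = 0.001)
  expect_equal(nrow(g$edges), 6)          # complete graph on 4 nodes

  # strict inequality at the threshold: r_min = 1 leaves nothing
  expect_equal(nrow(build_network(ones, r_min = 1, alpha = 0.05)$edges), 0)
  expect_equal(nrow(build_network(ones, r_min = 1, alpha = 0.05)$nodes), 4)

  r <- diag(1, 4)
  r[1, 2] <- r[2, 1] <- 0.9
  r[3, 4] <- r[4, 3] <- 0.8
  r[1, 3] <- r[3, 1] <- 0.4
  g2 <- build_network(corr_from_matrix(r, m = 20), r_min = 0.65,
                      alpha = 0.05)
  expect_equal(nrow(g2$edges), 2)
  expect_setequal(paste(g2$edges$from, g2$edges$to),
                  c("e1 e2", "e3 e4"))
  expect_equal(sort(g2$edges$weight), c(0.8, 0.9))

  expect_error(build_network(ones, r_min = 1.2), "r_min")
  expect_error(build_network(ones, alpha = 0), "alpha")
})

test_that("the p gate can veto edges the r gate would admit", {
  r <- diag(1, 3)
  r[1, 2] <- r[2, 1] <- 0.7   # with m = 5, p ~ 0.19
  r[1, 3] <- r[3, 1] <- 0.99
  g <- build_network(corr_from_matrix(r, m = 5), r_min = 0.65, alpha = 0.05)
  expect_equal(paste(g$edges$from, g$edges$to), "e1 e3")
})

test_that("k-NN reduction keeps each node's top-k edges with ties", {
  # complete 4-node graph with distinct weights, k = 1: survivors are the
  # union over nodes of each node's single heaviest edge
  set.seed(21)
  g <- random_test_graph(4, p = 1)
  g$edges$weight <- sample(seq(0.1, 0.6, by = 0.1))   # distinct
  red <- knn_reduce(g, 1)
  expect_equal(red$edges, oracle_knn(g$edges, 1),
               ignore_attr = "row.names")
  expect_identical(red$nodes, g$nodes)

  # k at least the max degree is the identity
  expect_equal(knn_reduce(g, 3)$edges, g$edges)

  # star with equal weights, k = 1: every tied edge survives
  star <- network_graph(
    data.frame(id = c("c", "l1", "l2", "l3"), group = "g"),
    data.frame(from = "c", to = c("l1", "l2", "l3"), weight = 0.5))
  expect_equal(nrow(knn_reduce(star, 1)$edges), 3)
})

test_that("k-NN reduction is idempotent, monotone in k, and a subset", {
  set.seed(31)
  for (rep in 1:20) {
    g <- random_test_graph(sample(4:10, 1), p = 0.7)
    for (k in 1:3) {
      once <- knn_reduce(g, k)
      key <- function(h) paste(h$edges$from, h$edges$to)
      expect_setequal(key(knn_reduce(once, k)), key(once))
      expect_true(all(key(once) %in% key(g)))
      expect_true(all(key(once) %in% key(knn_reduce(g, k + 1))))
    }
  }
})

test_that("components match brute-force reachability", {
  lone <- network_graph(data.frame(id = c("a", "b", "c"), group = "g"))
  expect_equal(length(graph_components(lone)), 3)

  set.seed(41)
  full <- random_test_graph(5, p = 1)
  expect_equal(length(graph_components(full)), 1)

  tri2 <- network_graph(
    data.frame(id = letters[1:6], group = "g"),
    data.frame(from = c("a", "b", "c", "d", "e", "f"),
               to   = c("b", "c", "a", "e", "f", "d"),
               weight = 1))
  comps <- graph_components(tri2)
  expect_equal(sort(vapply(comps, length, 1L)), c(3L, 3L))
  expect_setequal(lapply(comps, sort),
                  oracle_components(letters[1:6], tri2$edges))
})

test_that("group mixing summarises between- and within-group edges", {
  g1 <- random_test_graph(5, p = 1, groups = rep("only", 5))
  expect_equal(group_mixing(g1)$between_fraction, 0)

  bip <- network_graph(
    data.frame(id = c("a1", "a2", "b1", "b2"),
               group = c("A", "A", "B", "B")),
    data.frame(from = c("a1", "a1", "a2", "a2"),
               to = c("b1", "b2", "b1", "b2"), weight = 1))
  expect_equal(group_mixing(bip)$between_fraction, 1)
  expect_equal(unname(group_mixing(bip)$within_density), c(0, 0))

  cliq <- network_graph(
    data.frame(id = c("a1", "a2", "a3", "b1", "b2", "b3"),
               group = rep(c("A", "B"), each = 3)),
    data.frame(from = c("a1", "a1", "a2", "b1", "b1", "b2"),
               to = c("a2", "a3", "a3", "b2", "b3", "b3"), weight = 1))
  mix <- group_mixing(cliq)
  expect_equal(mix$between_fraction, 0)
  expect_equal(unname(mix$within_density), c(1, 1))

  bad <- g1; bad$nodes$group[2] <- ""
  expect_error(group_mixing(bad), "group attribute")
})

test_that("the permutation null brackets the observed mixing correctly", {
  set.seed(51)
  g <- random_test_graph(10, p = 0.6, groups = rep(c("A", "B"), each = 5))
  res <- mixing_permutation_test(g, n_perm = 200)
  expect_length(res$null, 200)
  expect_gte(res$p_lower, 1 / 201)
  expect_lte(res$p_lower, 1)
  expect_equal(res$observed, group_mixing(g)$between_fraction)
})

test_that("GraphML and edge-list exports round-trip the network", {
  set.seed(61)
  g <- random_test_graph(6, p = 0.5, groups = rep(c("A", "B"), 3))
  g$edges$weight <- runif(nrow(g$edges))
  g$provenance <- list(r_min = 0.65, alpha = 0.05, k = 3,
                       method = "pearson")

  f <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, f, "graphml")
  back <- import_graph(f, "graphml")
  expect_setequal(back$nodes$id, g$nodes$id)
  expect_identical(
    back$nodes$group[match(g$nodes$id, back$nodes$id)], g$nodes$group)
  key <- function(h) paste(h$edges$from, h$edges$to)
  expect_setequal(key(back), key(g))
  expect_equal(back$edges$weight[match(key(g), key(back))],
               g$edges$weight, tolerance = 1e-10)
  expect_equal(back$provenance$r_min, 0.65)
  expect_equal(back$provenance$k, 3)

  # weights are serialised with at least 10 significant digits
  txt <- readLines(f)
  wline <- grep("e_weight\">", txt, value = TRUE)[1]
  digits <- nchar(gsub("[^0-9]", "", sub(".*\">0\\.", "", wline)))
  expect_gte(digits, 10)

  f2 <- withr::local_tempfile(fileext = ".csv")
  fn <- withr::local_tempfile(fileext = ".csv")
  export_graph(g, f2, "edgelist", nodes_path = fn)
  back2 <- import_graph(f2, "edgelist", nodes_path = fn)
  expect_setequal(key(back2), key(g))
  expect_identical(back2$edges$weight[match(key(g), key(back2))],
                   g$edges$weight)
  expect_setequal(back2$nodes$id, g$nodes$id)

  # an empty graph still exports a node-only document
  empty <- network_graph(data.frame(id = c("a", "b"), group = "g"))
  f3 <- withr::local_tempfile(fileext = ".graphml")
  export_graph(empty, f3, "graphml")
  back3 <- import_graph(f3, "graphml")
  expect_equal(nrow(back3$nodes), 2)
  expect_equal(nrow(back3$edges), 0)

  expect_error(export_graph(g, file.path(tempdir(), "no", "dir.graphml")),
               "no such directory")
})
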