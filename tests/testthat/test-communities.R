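test_that("edge betweenness matches hand-derived values on the worked example", {
  net <- build_network(fruit_dataset())
  eb <- edge_betweenness(net)
  val <- function(a, b) {
    eb$betweenness[eb$excerpt_a == min(a, b) & eb$excerpt_b == max(a, b)]
  }
  expect_equal(val("grapes", "seaweed"), 3)
  expect_equal(val("raspberry", "grapes"), 2)
  expect_equal(val("tomato", "grapes"), 2)
  expect_equal(val("raspberry", "tomato"), 1)

  # unweighted path a - b - c
  path <- similarity_network(c("a", "b", "c"),
                             data.frame(excerpt_a = c("a", "b"),
                                        excerpt_b = c("b", "c"),
                                        score = c(1, 1)), 1)
  eb2 <- edge_betweenness(path)
  expect_equal(eb2$betweenness, c(2, 2))

  expect_error(edge_betweenness(similarity_network("a", NULL, 1)),
               class = "themesort_format_error")
})

test_that("edge and node betweenness agree with the path-enumeration oracle", {
  for (seed in 1:25) {
    n <- sample(4:8, 1)
    net <- random_network(n, p_edge = 0.5, seed = seed * 17)
    if (nrow(net$edges) == 0) next
    oracle <- oracle_betweenness(net)
    eb <- edge_betweenness(net)
    expect_equal(eb$betweenness,
                 unname(oracle$edge[edge_key(eb$excerpt_a, eb$excerpt_b)]),
                 tolerance = 1e-9)
    nb <- node_betweenness(net)
    expect_equal(nb$betweenness, unname(oracle$node[nb$excerpt_id]),
                 tolerance = 1e-9)
  }
})

test_that("betweenness agrees with an independent graph library", {
  for (seed in 1:10) {
    net <- random_network(sample(6:12, 1), p_edge = 0.4, seed = seed * 31)
    if (nrow(net$edges) == 0) next
    g <- as_igraph(net)
    expect_equal(edge_betweenness(net)$betweenness,
                 igraph::edge_betweenness(g, directed = FALSE,
                                          weights = igraph::E(g)$distance),
                 tolerance = 1e-9)
    expect_equal(node_betweenness(net)$betweenness,
                 unname(igraph::betweenness(g, directed = FALSE,
                                            weights = igraph::E(g)$distance)),
                 tolerance = 1e-9)
  }
})

test_that("iterative removal fragments the network as expected", {
  # worked example: the grapes-seaweed tie goes first
  net <- build_network(fruit_dataset())
  den <- girvan_newman(net)
  expect_equal(den$removed_edges$excerpt_a[1], "grapes")
  expect_equal(den$removed_edges$excerpt_b[1], "seaweed")
  expect_equal(den$removed_edges$betweenness[1], 3)
  expect_equal(den$n_communities[1], 1)
  expect_equal(den$n_communities[length(den$n_communities)], 4)

  # two triangles joined by a bridge: the bridge goes first and level 1 is
  # the two triangles
  tri <- similarity_network(
    letters[1:6],
    data.frame(excerpt_a = c("a", "a", "b", "d", "d", "e", "c"),
               excerpt_b = c("b", "c", "c", "e", "f", "f", "d"),
               score = 1), 1)
  dtri <- girvan_newman(tri)
  expect_equal(sort(unlist(dtri$removed_edges[1, c("excerpt_a", "excerpt_b")],
                           use.names = FALSE)), c("c", "d"))
  lvl1 <- dtri$levels[[2]]
  expect_equal(unname(lvl1[c("a", "b", "c")]), rep(lvl1[["a"]], 3))
  expect_equal(unname(lvl1[c("d", "e", "f")]), rep(lvl1[["d"]], 3))
  expect_true(lvl1[["a"]] != lvl1[["d"]])

  # disjoint cliques are already separate at level 0
  cliq <- similarity_network(
    c("a", "b", "c", "x", "y", "z"),
    data.frame(excerpt_a = c("a", "a", "b", "x", "x", "y"),
               excerpt_b = c("b", "c", "c", "y", "z", "z"),
               score = 2), 2)
  expect_equal(max(girvan_newman(cliq)$levels[[1]]), 2)

  # edgeless network: a single level of isolated singletons
  iso <- similarity_network(c("a", "b"), NULL, 1)
  diso <- girvan_newman(iso)
  expect_length(diso$levels, 1)
  expect_equal(max(diso$levels[[1]]), 2)
})

test_that("dendrogram levels are nested refinements ending in singletons", {
  for (seed in 1:6) {
    net <- build_network(random_sort_dataset(sample(8:14, 1), 4,
                                             seed = seed * 13))
    den <- girvan_newman(net)
    n <- length(net$nodes)
    expect_equal(max(den$levels[[length(den$levels)]]), n)
    for (i in seq_along(den$levels)[-1]) {
      prev <- den$levels[[i - 1]]
      cur <- den$levels[[i]]
      # refinement: nodes together now were together before
      cross <- table(prev, cur)
      expect_true(all(colSums(cross > 0) == 1))
      expect_gt(max(cur), max(prev))
    }
  }
})

test_that("weighted modularity matches direct arithmetic and brute force", {
  net <- build_network(fruit_dataset())
  nodes <- net$nodes
  one <- stats::setNames(rep(1L, 4), nodes)
  expect_equal(partition_quality(net, one), 0)
  split3 <- stats::setNames(c(1L, 1L, 1L, 2L),
                            c("raspberry", "tomato", "grapes", "seaweed"))
  expect_equal(partition_quality(net, split3), -0.02)

  # edgeless network: Q defined as 0 for every partition
  iso <- similarity_network(c("a", "b"), NULL, 1)
  expect_equal(partition_quality(iso, stats::setNames(1:2, c("a", "b"))), 0)

  # agreement with an independent implementation on random networks
  for (seed in 1:8) {
    rnet <- random_network(sample(5:10, 1), 0.5, seed = seed * 7)
    memb <- sample.int(3, length(rnet$nodes), replace = TRUE)
    names(memb) <- rnet$nodes
    if (nrow(rnet$edges) == 0) next
    g <- as_igraph(rnet)
    expect_equal(partition_quality(rnet, memb),
                 igraph::modularity(g, memb[igraph::V(g)$name],
                                    weights = igraph::E(g)$score),
                 tolerance = 1e-12)
  }
})

test_that("the modularity cut picks cliques apart and keeps cohesive networks whole", {
  # worked example: a single community beats every finer level
  net <- build_network(fruit_dataset())
  sel <- select_partition(girvan_newman(net))
  expect_equal(max(sel), 1)

  # two disjoint cliques: the cliques themselves are the best level, and by
  # brute force over all set partitions no partition beats them
  cliq <- similarity_network(
    c("a", "b", "c", "x", "y", "z"),
    data.frame(excerpt_a = c("a", "a", "b", "x", "x", "y"),
               excerpt_b = c("b", "c", "c", "y", "z", "z"),
               score = 2), 2)
  sel2 <- select_partition(girvan_newman(cliq))
  expect_equal(max(sel2), 2)
  expect_equal(length(unique(sel2[c("a", "b", "c")])), 1)
  expect_equal(length(unique(sel2[c("x", "y", "z")])), 1)
  qs <- vapply(enum_partitions(cliq$nodes),
               function(p) partition_quality(cliq, parts_to_membership(p)),
               numeric(1))
  expect_equal(partition_quality(cliq, sel2), max(qs), tolerance = 1e-12)
})

test_that("fixed-k selection returns the first level with k communities", {
  net <- build_network(fruit_dataset())
  den <- girvan_newman(net)
  expect_equal(max(select_partition(den, k = 2)), 2)
  k2 <- select_partition(den, k = 2)
  expect_equal(length(unique(k2[c("raspberry", "tomato", "grapes")])), 1)
  expect_equal(max(select_partition(den, k = 4)), 4)  # all singletons
  expect_error(select_partition(den, k = 10),
               class = "themesort_selection_error")
})

test_that("finalizing a partition separates groups from unassigned excerpts", {
  memb <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 3L), LETTERS[1:6])
  cl <- finalize_clustering(memb)
  expect_length(cl$groups, 2)
  expect_equal(cl$unassigned, "F")
  # ids in decreasing size order
  expect_equal(sort(cl$groups[[1]]), c("A", "B", "C"))
  expect_equal(sort(cl$groups[[2]]), c("D", "E"))
  expect_equal(cl$assignment$group, c(1L, 1L, 1L, 2L, 2L, NA))

  # equal sizes: tie broken by smallest member label
  memb2 <- stats::setNames(c(2L, 2L, 1L, 1L), c("D", "C", "B", "A"))
  cl2 <- finalize_clustering(memb2)
  expect_equal(sort(cl2$groups[[1]]), c("A", "B"))

  all_single <- finalize_clustering(stats::setNames(1:4, letters[1:4]))
  expect_length(all_single$groups, 0)
  expect_length(all_single$unassigned, 4)

  f <- withr::local_tempfile(fileext = ".csv")
  write_clustering(cl, f)
  tab <- utils::read.table(f, header = TRUE, sep = ",",
                           colClasses = "character")
  expect_equal(tab$group[tab$excerpt_id == "F"], "UNASSIGNED")
})

test_that("community detection is deterministic", {
  ds <- random_sort_dataset(15, 5, seed = 99)
  net <- build_network(ds)
  d1 <- girvan_newman(net)
  d2 <- girvan_newman(net)
  expect_identical(d1, d2)
  expect_identical(detect_themes(net), detect_themes(net))
})

test_that("dendrograms serialize to JSON with quality per level", {
  net <- build_network(fruit_dataset())
  den <- girvan_newman(net)
  f <- withr::local_tempfile(fileext = ".json")
  write_dendrogram_json(den, f)
  parsed <- jsonlite::read_json(f)
  expect_length(parsed$levels, length(den$levels))
  expect_equal(parsed$levels[[1]]$quality, den$quality[1])
  expect_length(parsed$removed_edges, nrow(den$removed_edges))
})
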