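path3 <- tibble::tibble(modulator = c("n1", "n2"), dependent = c("n2", "n3"))
cycle3 <- tibble::tibble(modulator = c("n1", "n2", "n3"),
                         dependent = c("n2", "n3", "n1"))

test_that("bipartite_split maps arcs to out/in-copy edges", {
  bs <- bipartite_split(path3)
  expect_setequal(paste(bs$out_copy, bs$in_copy), c("n1+ n2-", "n2+ n3-"))

  empty <- tibble::tibble(modulator = character(0), dependent = character(0))
  expect_equal(nrow(bipartite_split(empty)), 0)

  set.seed(61)
  g <- rand_digraph(8, 0.3)
  expect_equal(nrow(bipartite_split(g)), nrow(g))   # arc count preserved
})

test_that("worked driver examples: path, star, disjoint edges, cycle", {
  res <- max_matching_drivers(path3)
  expect_equal(res$matching_size, 2)
  expect_equal(res$driver_nodes, "n1")

  star <- tibble::tibble(modulator = rep("c", 3),
                         dependent = paste0("l", 1:3))
  res_s <- max_matching_drivers(star)
  expect_equal(res_s$matching_size, 1)
  expect_equal(length(res_s$driver_nodes), 3)
  expect_true("c" %in% res_s$driver_nodes)   # centre has no in-edge

  two <- tibble::tibble(modulator = c("a", "c"), dependent = c("b", "d"))
  f2 <- sample_driver_sets(two, runs = 50, seed = 1)
  expect_equal(f2$count[match(c("a", "c"), f2$gene)], c(50L, 50L))
  expect_equal(f2$count[match(c("b", "d"), f2$gene)], c(0L, 0L))

  # 3-cycle: perfect matching, one driver per run, symmetric frequencies
  fc <- sample_driver_sets(cycle3, runs = 300, seed = 2)
  expect_equal(attr(fc, "matching_size"), 3L)
  expect_equal(sum(fc$count), 300L)            # exactly one driver per run
  expect_true(all(fc$count > 60))              # roughly runs/3 = 100 each
  expect_equal(select_candidates(fc), character(0))
})

test_that("path drivers are unique across any number of runs", {
  fp <- sample_driver_sets(path3, runs = 100, seed = 3)
  expect_equal(fp$count[fp$gene == "n1"], 100L)
  expect_equal(sum(fp$count[fp$gene != "n1"]), 0L)
  expect_equal(select_candidates(fp), "n1")
})

test_that("matching size equals the exhaustive oracle on random digraphs", {
  set.seed(62)
  for (i in 1:40) {
    n <- sample(2:8, 1)
    g <- rand_digraph(n, runif(1, 0.1, 0.6))
    nodes <- paste0("n", seq_len(n))
    res <- max_matching_drivers(g, nodes = nodes)
    expect_equal(res$matching_size, oracle_matching_size(g, nodes))
    expect_equal(length(res$driver_nodes),
                 max(n - res$matching_size, 1))
    # size is order-invariant
    for (j in 1:5) {
      ord <- sample(nodes)
      expect_equal(max_matching_drivers(g, node_order = ord,
                                        nodes = nodes)$matching_size,
                   res$matching_size)
    }
  }
})

test_that("matching size agrees with igraph's bipartite matcher", {
  skip_if_not_installed("igraph")
  set.seed(63)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    g <- rand_digraph(n, 0.3)
    if (nrow(g) == 0) next
    nodes <- paste0("n", seq_len(n))
    bg <- igraph::make_bipartite_graph(
      types = rep(c(FALSE, TRUE), each = n),
      edges = as.vector(rbind(match(g$modulator, nodes),
                              match(g$dependent, nodes) + n))
    )
    ig <- igraph::max_bipartite_match(bg)$matching_size
    expect_equal(max_matching_drivers(g, nodes = nodes)$matching_size, ig)
  }
})

test_that("driver bookkeeping respects matching structure", {
  set.seed(64)
  g <- rand_digraph(10, 0.25)
  nodes <- paste0("n", 1:10)
  res <- max_matching_drivers(g, nodes = nodes)
  # matched edges form a matching: each dependent (in-copy) used once, each
  # modulator (out-copy) used once
  expect_false(any(duplicated(res$matched_edges$dependent)))
  expect_false(any(duplicated(res$matched_edges$modulator)))
  expect_equal(nrow(res$matched_edges), res$matching_size)
  # drivers are exactly the nodes with unmatched in-copies
  expect_setequal(res$driver_nodes,
                  setdiff(nodes, res$matched_edges$dependent))

  # isolated nodes are their own drivers
  res_iso <- max_matching_drivers(path3, nodes = c("n1", "n2", "n3", "iso"))
  expect_true("iso" %in% res_iso$driver_nodes)

  # edgeless graph: every node a driver
  empty <- tibble::tibble(modulator = character(0), dependent = character(0))
  res_e <- max_matching_drivers(empty, nodes = c("a", "b"))
  expect_equal(res_e$matching_size, 0)
  expect_setequal(res_e$driver_nodes, c("a", "b"))
})

test_that("all-run candidates are a subset of every sampled driver set", {
  set.seed(65)
  g <- rand_digraph(12, 0.2)
  freq <- sample_driver_sets(g, runs = 40, seed = 6)
  cand <- select_candidates(freq)
  for (i in 1:40) {
    ord <- bonemet:::with_seed(bonemet:::derive_seed(6, i), sample(freq$gene))
    res <- max_matching_drivers(g, node_order = ord, nodes = freq$gene)
    expect_true(all(cand %in% res$driver_nodes))
  }
  expect_error(select_candidates(tibble::tibble(gene = "a", count = 1)),
               "sample_driver_sets")
})

test_that("perfect matchings still yield one driver, as ordered", {
  res <- max_matching_drivers(cycle3, node_order = c("n2", "n3", "n1"))
  expect_equal(res$matching_size, 3)
  expect_equal(res$driver_nodes, "n2")
})
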