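test_that("co-expression edges follow the Pearson formula and cutoffs", {
  m <- rbind(
    f1 = c(1, 2, 3, 4, 5),
    f2 = c(2, 4, 6, 8, 10),     # duplicate of f1 up to scale: r = 1
    f3 = c(-1, -2, -3, -4, -5), # negated: r = -1
    f4 = c(2, 4, 7, 8, 12),
    f5 = c(5, 5, 5, 5, 5)       # zero variance: excluded
  )
  colnames(m) <- paste0("s", 1:5)
  expect_warning(net <- coexp_network(m, paste0("s", 1:5), r_cut = 0.9),
                 "zero-variance")
  expect_false("f5" %in% net$nodes)
  e <- net$edges
  expect_equal(e$r[e$from == "f1" & e$to == "f2"], 1)
  expect_equal(e$r[e$from == "f1" & e$to == "f3"], -1)
  # hand-computed Pearson for x=(1,2,3), y=(2,4,7) on a 3-sample network
  m2 <- rbind(x = c(1, 2, 3), y = c(2, 4, 7))
  colnames(m2) <- paste0("s", 1:3)
  r_hand <- {
    x <- c(1, 2, 3); y <- c(2, 4, 7)
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  net2 <- coexp_network(m2, paste0("s", 1:3), r_cut = 0, p_cut = 1)
  expect_equal(net2$edges$r, r_hand)
  # fewer than 3 samples: significance undefined
  expect_error(coexp_network(m, paste0("s", 1:2)), ">= 3 samples")
  # raising r_cut never adds edges
  n_edges <- vapply(c(0, 0.5, 0.9, 0.99), function(rc) {
    nrow(suppressWarnings(coexp_network(m, paste0("s", 1:5), r_cut = rc,
                                        p_cut = 1))$edges)
  }, numeric(1))
  expect_true(all(diff(n_edges) <= 0))
})

test_that("degree centrality counts incident links", {
  star <- network_from_edges(
    tibble::tibble(from = "hub", to = paste0("leaf", 1:4))
  )
  deg <- degree_centrality(star)
  expect_equal(deg$degree[deg$node == "hub"], 4)
  expect_true(all(deg$degree[deg$node != "hub"] == 1))
  # handshake lemma
  expect_equal(sum(deg$degree), 2 * nrow(star$edges))
  # empty graph: all zero
  empty <- network_from_edges(tibble::tibble(from = character(),
                                             to = character()),
                              nodes = c("a", "b"))
  expect_true(all(degree_centrality(empty)$degree == 0))
})

test_that("W-core pruning matches its definition on canonical cases", {
  tri <- network_from_edges(tibble::tibble(from = c("a", "b", "a"),
                                           to = c("b", "c", "c")))
  expect_setequal(w_core(tri, 2)$nodes, c("a", "b", "c"))
  path <- network_from_edges(tibble::tibble(from = c("a", "b"),
                                            to = c("b", "c")))
  expect_equal(length(w_core(path, 2)$nodes), 0)  # pruning cascades
  g <- random_graph(8, 0.4, seed = 1)
  expect_setequal(w_core(g, 0)$nodes, g$nodes)
})

test_that("W-core matches brute-force subset search and igraph coreness", {
  for (seed in 1:10) {
    g <- random_graph(sample(5:9, 1), stats::runif(1, 0.2, 0.6), seed)
    for (W in 1:3) {
      core <- w_core(g, W)
      expect_identical(sort(core$nodes),
                       brute_w_core(g$nodes, g$edges, W),
                       info = sprintf("seed %d W %d", seed, W))
      # every node keeps >= W neighbours inside the core
      if (length(core$nodes) > 0) {
        deg <- degree_centrality(core)
        expect_true(all(deg$degree >= W))
      }
    }
    if (requireNamespace("igraph", quietly = TRUE)) {
      ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                          vertices = g$nodes)
      cn <- igraph::coreness(ig)
      for (W in 1:3) {
        expect_setequal(w_core(g, W)$nodes, names(cn)[cn >= W])
      }
    }
  }
})

test_that("core regulators rank by degree difference with stated ties", {
  net_a <- network_from_edges(
    tibble::tibble(from = "hub", to = paste0("x", 1:9)),
    nodes = c("hub", paste0("x", 1:9), "lone")
  )
  net_b <- network_from_edges(
    tibble::tibble(from = character(), to = character()),
    nodes = c("hub", paste0("x", 1:9), "lone")
  )
  regs <- core_regulators(net_a, net_b)
  expect_equal(regs$node[1], "hub")
  expect_equal(regs$degree_diff[1], 9)
  expect_equal(regs$degree_diff[regs$node == "lone"], 0)
  # identical networks: all differences zero
  same <- core_regulators(net_a, net_a)
  expect_true(all(same$degree_diff == 0))
  # tie on |diff| resolves to the larger maximum degree
  na <- network_from_edges(tibble::tibble(from = c("p", "p", "q"),
                                          to = c("u", "v", "u")))
  nb <- network_from_edges(tibble::tibble(from = "q", to = c("v")),
                           nodes = c("p", "q", "u", "v"))
  # p: 2 vs 0 (diff 2, max 2); u: 2 vs 0 (diff 2, max 2); q: 1 vs 1 (0)
  regs2 <- core_regulators(na, nb, top_k = 2)
  expect_setequal(regs2$node, c("p", "u"))
})
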