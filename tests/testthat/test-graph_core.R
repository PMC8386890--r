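test_that("from_edge_list builds simple graphs with first-appearance node order", {
  g <- from_edge_list(rbind(c("a", "b"), c("b", "c")))
  expect_equal(n_nodes(g), 3L)
  expect_equal(n_edges(g), 2L)
  expect_equal(g$nodes, c("a", "b", "c"))
  expect_equal(graph_volume(g), 4L)
  expect_equal(unname(node_degrees(g)), c(1L, 2L, 1L))

  g2 <- from_edge_list(rbind(c("z", "a"), c("a", "m")), isolated_nodes = "q")
  expect_equal(g2$nodes, c("z", "a", "m", "q"))
  expect_equal(unname(node_degrees(g2)["q"]), 0L)
  # canonical edge order: sorted within pair, lexicographic across pairs
  expect_equal(edge_labels_of(g2), c("a--m", "a--z"))
})

test_that("duplicate edges collapse with a warning; self-loops are rejected", {
  expect_warning(g <- from_edge_list(rbind(c("a", "b"), c("b", "a"))),
                 "duplicate")
  expect_equal(n_edges(g), 1L)
  expect_error(from_edge_list(rbind(c("a", "a"))), "self-loop.*a.*a")
})

test_that("line graph matches hand examples and the degree-sum edge count", {
  lp <- line_graph(path3())
  expect_equal(n_nodes(lp$graph), 2L)
  expect_equal(n_edges(lp$graph), 1L)

  lt <- line_graph(triangle())
  expect_equal(n_nodes(lt$graph), 3L)
  expect_equal(n_edges(lt$graph), 3L)  # K3 is self-line-graph

  lg <- line_graph(grid_graph(8, 8))
  expect_equal(n_nodes(lg$graph), 112L)
  expect_equal(n_edges(lg$graph), 292L)  # sum_v C(d_v,2) = 4*1 + 24*3 + 36*6

  expect_error(line_graph(from_edge_list(list(), isolated_nodes = "a")),
               "at least one edge")
})

test_that("line-graph map is a deterministic bijection onto the edges", {
  g <- from_edge_list(rbind(c("b", "d"), c("a", "b"), c("a", "d"), c("c", "d")))
  lg <- line_graph(g)
  expect_equal(length(lg$edge_to_index), n_edges(g))
  expect_equal(sort(unname(lg$edge_to_index)), seq_len(n_edges(g)))
  expect_equal(names(lg$edge_to_index), edge_labels_of(g))
  expect_equal(paste0(lg$index_to_edge[, 1], "--", lg$index_to_edge[, 2]),
               edge_labels_of(g))
  # identical input, identical map
  lg2 <- line_graph(from_edge_list(rbind(c("b", "d"), c("a", "b"),
                                         c("a", "d"), c("c", "d"))))
  expect_identical(lg, lg2)
})

test_that("line graph agrees with igraph on random graphs (counts and degrees)", {
  set.seed(42)
  for (rep in 1:20) {
    g <- random_connected_graph(sample(4:30, 1))
    lg <- line_graph(g)
    d <- node_degrees(g)
    expect_equal(n_nodes(lg$graph), n_edges(g))
    expect_equal(n_edges(lg$graph), sum(choose(d, 2)))
    ig_l <- igraph::make_line_graph(as_igraph(g))
    expect_equal(n_edges(lg$graph), igraph::ecount(ig_l))
    expect_equal(sort(unname(node_degrees(lg$graph))),
                 sort(as.integer(igraph::degree(ig_l))))
  }
})

test_that("grid graphs have the lattice counts and are triangle-free", {
  g <- grid_graph(8, 8)
  expect_equal(n_nodes(g), 64L)
  expect_equal(n_edges(g), 112L)
  expect_equal(global_clustering(g), 0)

  expect_equal(n_edges(grid_graph(1, 2)), 1L)
  g33 <- grid_graph(3, 3)
  expect_equal(n_nodes(g33), 9L)
  expect_equal(n_edges(g33), 12L)
  expect_error(grid_graph(0, 5), "positive")

  for (rc in list(c(2, 5), c(3, 4), c(6, 2))) {
    gg <- grid_graph(rc[1], rc[2])
    expect_equal(n_edges(gg), rc[1] * (rc[2] - 1) + rc[2] * (rc[1] - 1))
    expect_equal(global_clustering(gg), 0)
  }
})

test_that("planted partition: deterministic limits and exact seed replay", {
  pp <- planted_partition(2, 3, 1, 0, seed = 7)
  expect_equal(n_nodes(pp$graph), 6L)
  expect_equal(n_edges(pp$graph), 6L)  # two disjoint triangles
  expect_equal(length(pp$truth$communities), 2L)
  comp <- igraph::components(as_igraph(pp$graph))
  expect_equal(comp$no, 2L)

  empty <- planted_partition(2, 3, 0, 0, seed = 7)
  expect_equal(n_edges(empty$graph), 0L)

  a <- planted_partition(3, 5, 0.7, 0.2, seed = 123)
  b <- planted_partition(3, 5, 0.7, 0.2, seed = 123)
  expect_identical(a, b)
  c <- planted_partition(3, 5, 0.7, 0.2, seed = 124)
  expect_false(identical(a$graph$edges, c$graph$edges))

  expect_error(planted_partition(0, 3, 0.5, 0.1), "at least 1")
  expect_warning(planted_partition(2, 3, 0.2, 0.8, seed = 1), "p_out > p_in")
})

test_that("planted partition mean edge count matches the binomial expectation", {
  # PP(4, 8, 0.6, 0.1): E|E| = 4*C(8,2)*0.6 + C(4,2)*64*0.1 = 105.6
  counts <- vapply(1:500, function(s)
    n_edges(planted_partition(4, 8, 0.6, 0.1, seed = s)$graph), 1L)
  expectation <- 4 * choose(8, 2) * 0.6 + choose(4, 2) * 64 * 0.1
  varsum <- 4 * choose(8, 2) * 0.6 * 0.4 + choose(4, 2) * 64 * 0.1 * 0.9
  se <- sqrt(varsum / 500)
  expect_lt(abs(mean(counts) - expectation), 3 * se)
})

test_that("stochastic block model: validation, limits, expectation", {
  sb <- sbm_graph(c(3, 3), diag(2), seed = 1)
  expect_equal(n_edges(sb$graph), 6L)
  expect_equal(lengths(sb$truth$communities), c(3L, 3L))
  expect_equal(n_edges(sbm_graph(c(4, 4), matrix(0, 2, 2), seed = 1)$graph), 0L)

  expect_error(sbm_graph(c(3, 3), matrix(0.5, 3, 3)), "2 x 2")
  expect_error(sbm_graph(c(3, 3), matrix(2, 2, 2)), "\\[0, 1\\]")

  P <- matrix(c(0.8, 0.1, 0.1, 0.4), 2, 2)
  counts <- vapply(1:400, function(s)
    n_edges(sbm_graph(c(6, 9), P, seed = 1000 + s)$graph), 1L)
  expectation <- choose(6, 2) * 0.8 + choose(9, 2) * 0.4 + 54 * 0.1
  p_all <- c(rep(0.8, choose(6, 2)), rep(0.4, choose(9, 2)), rep(0.1, 54))
  se <- sqrt(sum(p_all * (1 - p_all)) / 400)
  expect_lt(abs(mean(counts) - expectation), 3 * se)
})
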