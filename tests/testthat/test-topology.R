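test_that("degrees satisfy the handshake lemma on toys and random graphs", {
  expect_equal(node_degree(triangle_graph())$degree, c(2, 2, 2))
  star <- star_graph("C0", paste0("L", 1:4))
  d <- node_degree(star)
  expect_equal(d$degree[d$id == "C0"], 4)
  expect_equal(sum(d$degree), 2 * n_edges(star))
  for (seed in 1:10) {
    g <- normalize_graph(random_edge_df(15, 0.2, seed))
    expect_equal(sum(node_degree(g)$degree), 2 * n_edges(g))
  }
})

test_that("degree distribution is a proper probability mass function", {
  expect_equal(degree_distribution(triangle_graph()),
               tibble::tibble(k = 2L, n_nodes = 3L, p_k = 1))
  k13 <- star_graph("C", paste0("L", 1:3))
  dd <- degree_distribution(k13)
  expect_equal(dd$p_k[dd$k == 1], 0.75)
  expect_equal(dd$p_k[dd$k == 3], 0.25)
  # direct-count oracle: 10 nodes, 4 of degree 1 (the leaves on A)
  g <- toy_graph(c("A", "B", "C", rep("A", 4)), c("B", "C", "A", paste0("L", 1:4)),
                 nodes = paste0("I", 1:3))
  dd <- degree_distribution(g)
  expect_equal(dd$p_k[dd$k == 1], 0.4)
  expect_equal(sum(dd$p_k), 1, tolerance = 1e-12)
  # isolated nodes appear at k = 0
  expect_equal(dd$p_k[dd$k == 0], 0.3)
  expect_error(degree_distribution(hetnet(pairs_df(character(), character()))),
               "empty graph")
})

test_that("local clustering matches the triangle-enumeration oracle", {
  expect_equal(local_clustering(triangle_graph(), "A")$clustering, 1)
  expect_equal(local_clustering(star_graph("C", paste0("L", 1:5)), "C")$clustering, 0)
  # square with one diagonal: a degree-3 vertex sees 2 of its 3 neighbour
  # pairs connected (the two far sides), so C = 2*2/(3*2) = 2/3
  sq <- toy_graph(c("A", "B", "C", "D", "A"), c("B", "C", "D", "A", "C"))
  expect_equal(local_clustering(sq, "A")$clustering, 2 / 3)
  expect_equal(local_clustering(sq, "B")$clustering,
               oracle_local_clustering(edge_table(sq), node_table(sq)$id)[["B"]])
  expect_error(local_clustering(sq, "Z"), "Unknown node")

  for (seed in 1:20) {
    edges <- random_edge_df(sample(5:30, 1), stats::runif(1, 0.1, 0.5), seed)
    g <- normalize_graph(edges)
    ids <- node_table(g)$id
    got <- local_clustering(g)
    expect_equal(setNames(got$clustering, got$id)[ids],
                 oracle_local_clustering(edge_table(g), ids))
  }
})

test_that("C(k) averages local clustering by degree; global is the node mean", {
  expect_equal(clustering_distribution(triangle_graph())$c_k, 1)
  expect_equal(global_clustering(triangle_graph()), 1)
  k13 <- star_graph("C", paste0("L", 1:3))
  expect_equal(clustering_distribution(k13)$c_k, c(0, 0))
  expect_equal(global_clustering(k13), 0)
  # kite: K4 plus a pendant on one vertex; global mean over all 5 nodes
  kite <- hetnet(rbind(pairs_df(t(combn(paste0("K", 1:4), 2))[, 1],
                                t(combn(paste0("K", 1:4), 2))[, 2]),
                       pairs_df("K1", "P")))
  percc <- oracle_local_clustering(edge_table(kite), node_table(kite)$id)
  expect_equal(global_clustering(kite), mean(percc))
})

test_that("density follows D = 2E / (N (N - 1))", {
  expect_equal(graph_density(complete_graph(LETTERS[1:5])), 1)
  expect_equal(graph_density(path_graph(c("A", "B", "C"))), 2 / 3)
  g <- gen_hetnet_like(seed = 1)
  expect_equal(graph_density(g), 2 * 260 / (156 * 155))
  expect_equal(round(graph_density(g), 2), 0.02)
  expect_error(graph_density(hetnet(pairs_df(character(), character()),
                                    nodes = data.frame(id = "A", family = "F1"))),
               "at least 2 nodes")
})

test_that("shortest paths agree with a Floyd-Warshall oracle", {
  p4 <- path_graph(c("A", "B", "C", "D"))
  expect_equal(path_length_histogram(p4),
               tibble::tibble(length = 1:3, n_pairs = c(3L, 2L, 1L)))
  expect_equal(mean_path_length(p4), 10 / 6)
  expect_equal(graph_diameter(p4), 3)
  k4 <- complete_graph(LETTERS[1:4])
  expect_equal(mean_path_length(k4), 1)
  expect_equal(graph_diameter(k4), 1)
  # disconnected pairs are excluded, not infinite
  two <- toy_graph(c("A", "C"), c("B", "D"))
  expect_equal(path_length_histogram(two),
               tibble::tibble(length = 1L, n_pairs = 2L))
  expect_error(mean_path_length(hetnet(pairs_df(character(), character()),
                                       nodes = data.frame(id = c("A", "B"), family = NA))),
               "no connected pairs")

  for (seed in 1:20) {
    g <- normalize_graph(random_edge_df(sample(5:30, 1), stats::runif(1, 0.05, 0.4), seed))
    ids <- node_table(g)$id
    ora <- oracle_distances(edge_table(g), ids)
    got <- shortest_path_lengths(g)
    expect_equal(nrow(got), sum(is.finite(ora[upper.tri(ora)])))
    for (r in sample(nrow(got), min(20, nrow(got)))) {
      expect_equal(got$distance[r], unname(ora[got$from[r], got$to[r]]))
    }
  }
})

test_that("edge edits move shortest paths the right way", {
  for (seed in 1:5) {
    g <- normalize_graph(random_edge_df(12, 0.3, seed))
    et <- edge_table(g)
    d0 <- oracle_distances(et, node_table(g)$id)
    drop <- et[-1, ]
    d1 <- oracle_distances(drop, node_table(g)$id)
    expect_true(all(d1 >= d0))  # removing an edge never shortens a path
  }
})

test_that("components and relative connectivity match a union-find oracle", {
  expect_equal(relative_connectivity(triangle_graph()), 1)
  g <- toy_graph(c(paste0("A", 1:9), "B1", "B2", "B3", "B4"),
                 c(paste0("A", 2:10), "B2", "B3", "B4", "B5"),
                 nodes = "LONE")
  expect_equal(relative_connectivity(g), 10 / 16)
  comp <- graph_components(g)
  memb <- oracle_components(edge_table(g), node_table(g)$id)
  expect_equal(length(unique(comp$component)), length(unique(memb)))
  single <- hetnet(pairs_df(character(), character()),
                   nodes = data.frame(id = "A", family = NA))
  expect_equal(relative_connectivity(single), 1)

  # f is invariant under node relabeling
  g1 <- normalize_graph(random_edge_df(20, 0.15, 4))
  et <- edge_table(g1)
  perm <- setNames(sprintf("Z%02d", sample(20)), sprintf("N%02d", 1:20))
  g2 <- normalize_graph(pairs_df(perm[et$protomer_a], perm[et$protomer_b]),
                        data.frame(id = unname(perm[node_table(g1)$id]), family = NA))
  expect_equal(relative_connectivity(g2), relative_connectivity(g1))
})

test_that("edge share counts incident edges once", {
  tri <- triangle_graph()
  expect_equal(edge_share(tri, c("A", "B", "C")), 1)
  expect_equal(edge_share(tri, "A"), 2 / 3)
  expect_equal(edge_share(tri, character()), 0)
  expect_error(edge_share(tri, "NOPE"), "Unknown node")
  # for an independent subset this equals the subset degree sum over E
  g <- gen_hetnet_like(seed = 2)
  top9 <- node_degree(g)$id[1:9]
  expect_equal(edge_share(g, top9), 110 / 260)
})

test_that("topology_profile collects consistent scalars and tables", {
  g <- gen_hetnet_like(seed = 5)
  prof <- topology_profile(g)
  sc <- glance(prof)
  expect_equal(sc$n_nodes, 156)
  expect_equal(sc$n_edges, 260)
  expect_equal(sc$average_degree, 2 * 260 / 156)
  expect_equal(sum(prof$degree_distribution$p_k), 1, tolerance = 1e-12)
  expect_equal(sc$diameter, max(prof$path_length_histogram$length))
  expect_true(all(prof$clustering_distribution$c_k >= 0 &
                    prof$clustering_distribution$c_k <= 1))
  expect_gt(sc$relative_connectivity, 0)
  expect_lte(sc$relative_connectivity, 1)
})
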