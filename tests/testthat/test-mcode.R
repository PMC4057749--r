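test_that("k-core matches the iterative-pruning oracle and is antitone in k", {
  expect_equal(k_core(triangle_graph(), 2)$id, c("A", "B", "C"))
  expect_equal(nrow(k_core(star_graph("C", paste0("L", 1:5)), 2)), 0)
  k4p <- hetnet(rbind(pairs_df(t(combn(paste0("K", 1:4), 2))[, 1],
                               t(combn(paste0("K", 1:4), 2))[, 2]),
                      pairs_df("K1", "P")))
  expect_equal(k_core(k4p, 2)$id, paste0("K", 1:4))
  for (seed in 1:10) {
    g <- normalize_graph(random_edge_df(sample(8:30, 1), stats::runif(1, 0.1, 0.4), seed))
    ids <- node_table(g)$id
    for (k in 0:4) {
      expect_equal(k_core(g, k)$id, oracle_kcore(edge_table(g), ids, k))
    }
    for (k in 0:3) {
      expect_true(all(k_core(g, k + 1)$id %in% k_core(g, k)$id))
    }
  }
})

test_that("vertex weights are the core-clustering coefficient times core k", {
  k4 <- complete_graph(paste0("K", 1:4))
  expect_equal(vertex_weights(k4)$weight, rep(3, 4))  # K4 core: k=3, density 1
  iso <- hetnet(pairs_df("A", "B"), nodes = data.frame(id = "Z", family = NA))
  w <- vertex_weights(iso)
  expect_equal(w$weight[w$id == "Z"], 0)            # isolated node
  expect_equal(w$weight[w$id == "A"], 0)            # degree 1 < cutoff 2
  w1 <- vertex_weights(iso, degree_cutoff = 1)
  expect_equal(w1$weight[w1$id == "A"], 1)          # pair is its own 1-core, density 1
})

test_that("complex prediction seeds symmetric components separately", {
  two_k4 <- hetnet(rbind(pairs_df(t(combn(paste0("A", 1:4), 2))[, 1],
                                  t(combn(paste0("A", 1:4), 2))[, 2]),
                         pairs_df(t(combn(paste0("B", 1:4), 2))[, 1],
                                  t(combn(paste0("B", 1:4), 2))[, 2])))
  cand <- predict_complexes(two_k4)
  expect_equal(nrow(cand), 2)
  expect_equal(cand$members[[1]], paste0("A", 1:4))
  expect_equal(cand$members[[2]], paste0("B", 1:4))
  edgeless <- hetnet(pairs_df(character(), character()),
                     nodes = data.frame(id = letters[1:4], family = NA))
  expect_equal(nrow(predict_complexes(edgeless)), 0)
  # K4 + pendant: the pendant's weight (0) fails the inclusion inequality
  k4p <- hetnet(rbind(pairs_df(t(combn(paste0("K", 1:4), 2))[, 1],
                               t(combn(paste0("K", 1:4), 2))[, 2]),
                      pairs_df("K1", "P")))
  cand <- predict_complexes(k4p)
  expect_equal(cand$members[[1]], paste0("K", 1:4))
})

test_that("post-processing applies core filter and haircut as specified", {
  g <- hetnet(rbind(pairs_df(t(combn(paste0("K", 1:4), 2))[, 1],
                             t(combn(paste0("K", 1:4), 2))[, 2]),
                    pairs_df("K1", "P")))
  cand <- tibble::tibble(seed = "K1", members = list(c(paste0("K", 1:4), "P")))
  out <- tidy(postprocess_complexes(g, cand))
  expect_equal(out$members[[1]], paste0("K", 1:4))  # haircut removes the pendant
  tri <- triangle_graph()
  out <- tidy(postprocess_complexes(tri, tibble::tibble(seed = "A",
                                                        members = list(c("A", "B", "C")))))
  expect_equal(nrow(out), 1)                        # a triangle is a 2-core
  p5 <- path_graph(paste0("P", 1:5))
  out <- postprocess_complexes(p5, tibble::tibble(seed = "P1",
                                                  members = list(paste0("P", 1:5))))
  expect_equal(nrow(tidy(out)), 0)                  # a path has no 2-core
})

test_that("mcode is deterministic, disjoint, and exact on canonical graphs", {
  # two K5s joined by a bridge: every vertex weighs 4 (the K5 core), so the
  # bridge endpoint passes the seed threshold 4 * 0.8 and expansion spans
  # both cliques -- one complex, hand-derived from the three stages
  k5a <- t(combn(paste0("A", 1:5), 2))
  k5b <- t(combn(paste0("B", 1:5), 2))
  g <- hetnet(rbind(pairs_df(k5a[, 1], k5a[, 2]), pairs_df(k5b[, 1], k5b[, 2]),
                    pairs_df("A1", "B1")))
  expect_equal(vertex_weights(g)$weight, rep(4, 10))
  cl <- tidy(mcode(g))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$members[[1]], c(paste0("A", 1:5), paste0("B", 1:5)))
  expect_equal(cl$score, 10 * 21 / choose(10, 2))
  # a stricter node-score cutoff keeps the cliques separate
  cl2 <- tidy(mcode(g, node_score_cutoff = 0))
  expect_equal(nrow(cl2), 1)  # weights tie at 4, so expansion still crosses
  # two *disconnected* K5s do split into two clusters
  g2 <- hetnet(rbind(pairs_df(k5a[, 1], k5a[, 2]), pairs_df(k5b[, 1], k5b[, 2])))
  expect_equal(nrow(tidy(mcode(g2))), 2)
  # complete graph: exactly one cluster of all n nodes, score n
  for (n in c(3, 5, 8)) {
    kn <- complete_graph(sprintf("V%02d", 1:n))
    cl <- tidy(mcode(kn))
    expect_equal(nrow(cl), 1)
    expect_equal(cl$size, n)
    expect_equal(cl$score, n)
  }
})

test_that("mcode clusters satisfy their invariants on sparse random graphs", {
  for (seed in 1:10) {
    g <- normalize_graph(random_edge_df(50, 0.03, seed))
    cl <- tidy(mcode(g))
    all_members <- unlist(cl$members)
    expect_equal(anyDuplicated(all_members), 0)  # node-disjoint
    for (m in cl$members) {
      sub <- igraph::induced_subgraph(igraph::as.igraph(g), m)
      # every cluster contains a 2-core (checked by the pruning oracle)
      sub_edges <- setNames(as.data.frame(igraph::as_edgelist(sub)),
                            c("protomer_a", "protomer_b"))
      expect_gt(length(oracle_kcore(sub_edges, m, 2)), 0)
      # haircut members keep >= 2 within-cluster neighbours
      expect_true(all(igraph::degree(sub) >= 2))
      # connected
      expect_equal(igraph::components(sub)$no, 1)
    }
  }
})

test_that("haircut is idempotent and mcode is label-invariant", {
  for (seed in 1:5) {
    g <- normalize_graph(random_edge_df(30, 0.12, seed))
    cl <- tidy(mcode(g))
    ig <- igraph::as.igraph(g)
    for (m in cl$members) {
      again <- hetnet:::haircut_members(ig, m)
      expect_equal(again, sort(m))
    }
  }
  # relabeling nodes relabels clusters but preserves their structure
  g1 <- normalize_graph(random_edge_df(25, 0.2, 3))
  et <- edge_table(g1)
  ids <- node_table(g1)$id
  perm <- setNames(sprintf("Q%02d", seq_along(ids)), sample(ids))
  g2 <- normalize_graph(pairs_df(perm[et$protomer_a], perm[et$protomer_b]))
  cl1 <- tidy(mcode(g1))
  cl2 <- tidy(mcode(g2))
  expect_equal(nrow(cl1), nrow(cl2))
  expect_equal(sort(cl1$score), sort(cl2$score))
  sets1 <- sort(vapply(cl1$members, function(m) paste(sort(unname(perm[m])), collapse = ","), ""))
  sets2 <- sort(vapply(cl2$members, function(m) paste(sort(m), collapse = ","), ""))
  expect_equal(sets1, sets2)
})
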