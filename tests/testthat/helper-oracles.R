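# Brute-force oracles, deliberately independent of igraph and of the
# package internals: everything works on a plain edge data frame (columns
# protomer_a / protomer_b) plus an id vector.

pairs_df <- function(a, b) data.frame(protomer_a = a, protomer_b = b)

toy_graph <- function(a, b, nodes = NULL) {
  hetnet(pairs_df(a, b),
         nodes = if (!is.null(nodes)) data.frame(id = nodes, family = NA) else NULL)
}

triangle_graph <- function() toy_graph(c("A", "B", "C"), c("B", "C", "A"))

complete_graph <- function(ids) {
  cmb <- t(combn(ids, 2))
  toy_graph(cmb[, 1], cmb[, 2])
}

path_graph <- function(ids) toy_graph(ids[-length(ids)], ids[-1])

star_graph <- function(center, leaves) toy_graph(rep(center, length(leaves)), leaves)

# seeded Erdos-Renyi edge frame built with base R only
random_edge_df <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n))
  cmb <- t(combn(ids, 2))
  keep <- stats::runif(nrow(cmb)) < p
  pairs_df(cmb[keep, 1], cmb[keep, 2])
}

oracle_adj <- function(edges, ids) {
  m <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(edges))) {
    a <- edges$protomer_a[i]; b <- edges$protomer_b[i]
    if (a != b) { m[a, b] <- TRUE; m[b, a] <- TRUE }
  }
  m
}

# triangle-enumeration clustering coefficient
oracle_local_clustering <- function(edges, ids) {
  adj <- oracle_adj(edges, ids)
  vapply(ids, function(v) {
    nb <- ids[adj[v, ]]
    k <- length(nb)
    if (k < 2) return(0)
    nl <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (adj[nb[i], nb[j]]) nl <- nl + 1
    }
    2 * nl / (k * (k - 1))
  }, numeric(1))
}

# Floyd-Warshall all-pairs shortest paths
oracle_distances <- function(edges, ids) {
  n <- length(ids)
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  adj <- oracle_adj(edges, ids)
  d[adj] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# union-find connected components; returns membership vector
oracle_components <- function(edges, ids) {
  parent <- setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$protomer_a[i]); rb <- find(edges$protomer_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(ids, find, character(1))
}

# iterative-pruning k-core
oracle_kcore <- function(edges, ids, k) {
  alive <- ids
  repeat {
    adj <- oracle_adj(edges[edges$protomer_a %in% alive &
                              edges$protomer_b %in% alive, , drop = FALSE], alive)
    deg <- rowSums(adj)
    drop <- alive[deg < k]
    if (length(drop) == 0) return(sort(alive))
    alive <- setdiff(alive, drop)
    if (length(alive) == 0) return(character())
  }
}

# relative-connectivity trajectory recomputed from scratch on every prefix
oracle_prefix_f <- function(edges, ordered_ids) {
  vapply(seq_along(ordered_ids), function(k) {
    sub_ids <- ordered_ids[seq_len(k)]
    sub_edges <- edges[edges$protomer_a %in% sub_ids &
                         edges$protomer_b %in% sub_ids, , drop = FALSE]
    memb <- oracle_components(sub_edges, sub_ids)
    max(table(memb)) / k
  }, numeric(1))
}
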