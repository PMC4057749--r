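#' Seeded synthetic network generators
#'
#' Generators for the three reference network models — Erdos-Renyi random
#' graphs, preferential-attachment (scale-free) graphs and Ravasz-style
#' hierarchical graphs — plus [gen_hetnet_like()], which realises graphs
#' matching the summary constraints of the curated GPCR heteroreceptor
#' network. All generators are deterministic: the same arguments and seed
#' produce an identical edge list. Every generated graph is already simple
#' and undirected, so [normalize_graph()] leaves it unchanged.
#'
#' Nodes are labelled `R001`, `R002`, ... and assigned GPCR families in the
#' proportions `family_props` (default 82% F1 / 10% F2 / 8% F3, the
#' composition observed in the curated network), with greedy label swaps
#' biasing edges towards intrafamily pairings (`family_assortativity`).
#'
#' @param n Number of nodes.
#' @param p Edge probability (Erdos-Renyi).
#' @param seed Integer seed; the RNG state of the session is not disturbed.
#' @param family_props Named numeric vector of F1/F2/F3 proportions.
#' @param family_assortativity In \[0, 1\]: 0 assigns families at random,
#'   larger values perform proportionally more intrafamily-favouring label
#'   swaps (node count x 10 x value attempts).
#' @return A `hetnet` object.
#' @examples
#' gen_random(50, 0.05, seed = 1)
#' @export
gen_random <- function(n, p, seed = NULL, family_props = c(F1 = 0.82, F2 = 0.10, F3 = 0.08),
                       family_assortativity = 0.9) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  with_gen_seed(seed, {
    g <- igraph::sample_gnp(n, p, directed = FALSE, loops = FALSE)
    finish_synthetic(g, family_props, family_assortativity)
  })
}

#' @param m Edges attached by each incoming node (preferential attachment).
#'   Growth starts from a complete graph on `m` nodes, so the edge count is
#'   `m * (n - m) + choose(m, 2)`.
#' @rdname gen_random
#' @export
gen_scale_free <- function(n, m, seed = NULL,
                           family_props = c(F1 = 0.82, F2 = 0.10, F3 = 0.08),
                           family_assortativity = 0.9) {
  stopifnot(n > m, m >= 1)
  with_gen_seed(seed, {
    start <- igraph::make_full_graph(m, directed = FALSE)
    g <- igraph::sample_pa(n, power = 1, m = m, start.graph = start,
                           directed = FALSE)
    g <- igraph::simplify(g)
    finish_synthetic(g, family_props, family_assortativity)
  })
}

#' @param levels Recursion depth of the hierarchical construction.
#' @param base_size Size of the base clique (>= 4). The graph has
#'   `base_size^levels` nodes: at each level the current block is
#'   replicated `base_size - 1` times and every peripheral node of the
#'   replicas is wired to the central root, producing the high, degree-
#'   dependent clustering (C(k) ~ 1/k) characteristic of hierarchical
#'   modular networks.
#' @rdname gen_random
#' @export
gen_hierarchical <- function(levels, base_size, seed = NULL,
                             family_props = c(F1 = 0.82, F2 = 0.10, F3 = 0.08),
                             family_assortativity = 0.9) {
  stopifnot(levels >= 1, base_size >= 4)
  b <- base_size
  # block: list(n, edges (2-col matrix), root, peripheral)
  block <- list(n = b,
                edges = t(utils::combn(b, 2)),
                root = 1L, peripheral = 2:b)
  lvl <- 1L
  while (lvl < levels) {
    n0 <- block$n
    copies <- purrr::map(seq_len(b - 1), function(i) {
      off <- i * n0
      list(edges = block$edges + off, peripheral = block$peripheral + off)
    })
    new_peripheral <- unlist(purrr::map(copies, "peripheral"))
    edges <- rbind(block$edges,
                   do.call(rbind, purrr::map(copies, "edges")),
                   cbind(block$root, new_peripheral))
    block <- list(n = n0 * b, edges = edges, root = block$root,
                  peripheral = new_peripheral)
    lvl <- lvl + 1L
  }
  g <- igraph::graph_from_edgelist(block$edges, directed = FALSE)
  g <- igraph::simplify(g)
  with_gen_seed(seed, finish_synthetic(g, family_props, family_assortativity))
}

#' Generate a graph matching GPCR-HetNet summary constraints
#'
#' Builds a degree sequence containing the given `top_degrees`,
#' `n_degree1` nodes of degree 1 and `n_isolated` isolated nodes, fills
#' the remaining nodes with degrees in `[2, min(top_degrees) - 1]` so the
#' sequence sums to `2 * e`, and realises it as a simple graph
#' (deterministic Havel-Hakimi realisation followed by seeded
#' degree-preserving rewiring). The defaults reproduce the printed summary
#' of the curated GPCR heteroreceptor network: 156 protomers, 260
#' heteromer pairs, 23 disconnected protomers, 57 degree-1 protomers and
#' top degrees 17, 17, 13, 12, 11, 10, 10, 10, 10.
#'
#' With `top_independent = TRUE` (default) any edges between two
#' top-degree nodes are removed by degree-preserving double-edge swaps, so
#' the top nodes' share of all edges equals their degree sum over `e` —
#' the convention under which the curated network's nine most-connected
#' protomers carry 42% of all links.
#'
#' @param n,e Node and edge counts.
#' @param n_isolated Number of degree-0 nodes.
#' @param n_degree1 Number of degree-1 nodes.
#' @param top_degrees Integer vector of the largest degrees, each >= 2.
#' @param top_independent Forbid edges between top-degree nodes.
#' @inheritParams gen_random
#' @return A `hetnet` object satisfying all constraints exactly.
#' @examples
#' g <- gen_hetnet_like(seed = 42)
#' glance(topology_profile(g))
#' @export
gen_hetnet_like <- function(n = 156, e = 260, n_isolated = 23, n_degree1 = 57,
                            top_degrees = c(17, 17, 13, 12, 11, 10, 10, 10, 10),
                            seed = NULL, top_independent = TRUE,
                            family_props = c(F1 = 0.82, F2 = 0.10, F3 = 0.08),
                            family_assortativity = 0.9) {
  top_degrees <- sort(as.integer(top_degrees), decreasing = TRUE)
  n_top <- length(top_degrees)
  n_fill <- n - n_isolated - n_degree1 - n_top
  if (n_fill < 0) {
    abort(paste0("Unsatisfiable: n_isolated + n_degree1 + length(top_degrees) = ",
                 n_isolated + n_degree1 + n_top, " exceeds n = ", n))
  }
  if (any(top_degrees < 2)) abort("top_degrees must all be >= 2.")
  s <- 2 * e - sum(top_degrees) - n_degree1
  if (n_fill == 0 && s != 0) {
    abort(paste0("Unsatisfiable: degree sum ", sum(top_degrees) + n_degree1,
                 " differs from 2e = ", 2 * e, " with no filler nodes."))
  }
  cap <- max(2L, min(top_degrees) - 1L)
  if (n_fill > 0 && (s < 2 * n_fill || s > cap * n_fill)) {
    abort(paste0("Unsatisfiable: ", n_fill, " filler nodes must absorb degree ",
                 s, ", outside the feasible range [", 2 * n_fill, ", ",
                 cap * n_fill, "] for degrees in [2, ", cap, "]."))
  }
  fill <- rep(2L, n_fill)
  r <- s - 2L * n_fill
  i <- 1L
  while (r > 0) {  # round-robin increments, capped
    if (fill[i] < cap) { fill[i] <- fill[i] + 1L; r <- r - 1L }
    i <- if (i == n_fill) 1L else i + 1L
  }
  degs <- c(top_degrees, fill, rep(1L, n_degree1), rep(0L, n_isolated))
  ids <- sprintf("R%03d", seq_len(n))
  top_ids <- ids[seq_len(n_top)]

  with_gen_seed(seed, {
    pos <- which(degs > 0)
    g0 <- igraph::realize_degseq(degs[pos])  # deterministic Havel-Hakimi
    g0 <- igraph::rewire(g0, igraph::keeping_degseq(loops = FALSE,
                                                    niter = 20 * e))
    el <- igraph::as_edgelist(g0, names = FALSE)
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    igraph::V(g)$name <- ids
    g <- igraph::add_edges(g, rbind(ids[pos[el[, 1]]], ids[pos[el[, 2]]]))
    if (top_independent) g <- untangle_top(g, top_ids)
    finish_synthetic(g, family_props, family_assortativity)
  })
}

# Degree-preserving removal of edges among `top_ids` via double-edge swaps:
# replace (u,v) + (x,y) by (u,x) + (v,y) with x, y outside the top set.
untangle_top <- function(g, top_ids) {
  repeat {
    ends <- igraph::as_edgelist(g, names = TRUE)
    bad <- which(ends[, 1] %in% top_ids & ends[, 2] %in% top_ids)
    if (length(bad) == 0) return(g)
    u <- ends[bad[1], 1]; v <- ends[bad[1], 2]
    others <- which(!(ends[, 1] %in% top_ids) & !(ends[, 2] %in% top_ids))
    others <- others[sample.int(length(others))]
    swapped <- FALSE
    for (j in others) {
      x <- ends[j, 1]; y <- ends[j, 2]
      for (ori in 1:2) {
        if (ori == 2) { tmp <- x; x <- y; y <- tmp }
        if (x != u && y != v &&
            !igraph::are_adjacent(g, u, x) && !igraph::are_adjacent(g, v, y)) {
          g <- igraph::delete_edges(g, igraph::get_edge_ids(
            g, c(u, v, x, y)))
          g <- igraph::add_edges(g, c(u, x, v, y))
          swapped <- TRUE
          break
        }
      }
      if (swapped) break
    }
    if (!swapped) {
      abort("Could not realise an independent top-degree set for this sequence.")
    }
  }
}

with_gen_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

finish_synthetic <- function(g, family_props, family_assortativity) {
  n <- igraph::vcount(g)
  if (is.null(igraph::V(g)$name)) igraph::V(g)$name <- sprintf("R%03d", seq_len(n))
  igraph::V(g)$family <- assign_families(g, family_props, family_assortativity)
  igraph::V(g)$display_name <- rep(NA_character_, n)
  if (igraph::ecount(g) > 0) {
    igraph::E(g)$methods <- rep("", igraph::ecount(g))
    igraph::E(g)$n_publications <- rep(0L, igraph::ecount(g))
    igraph::E(g)$controversial <- rep(FALSE, igraph::ecount(g))
  }
  new_hetnet(g)
}

assign_families <- function(g, props, assortativity) {
  n <- igraph::vcount(g)
  props <- props / sum(props)
  counts <- floor(n * props)
  while (sum(counts) < n) counts[which.max(n * props - counts)] <- counts[which.max(n * props - counts)] + 1
  fam <- sample(rep(names(props), counts))
  if (assortativity > 0 && igraph::ecount(g) > 0) {
    ends <- igraph::as_edgelist(g, names = FALSE)
    attempts <- ceiling(10 * n * assortativity)
    intra <- function(f) sum(f[ends[, 1]] == f[ends[, 2]])
    cur <- intra(fam)
    for (i in seq_len(attempts)) {
      ab <- sample.int(n, 2)
      if (fam[ab[1]] == fam[ab[2]]) next
      f2 <- fam
      f2[ab] <- fam[rev(ab)]
      new <- intra(f2)
      if (new >= cur) { fam <- f2; cur <- new }
    }
  }
  fam
}
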