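#' k-core of a graph
#'
#' The maximal induced subgraph in which every node has at least `k`
#' neighbours within the subgraph, computed by iteratively pruning nodes
#' of insufficient degree.
#'
#' @param x A `hetnet` object.
#' @param k Non-negative integer.
#' @return A tibble (`id`) of the member nodes, sorted; possibly empty.
#'   `k_core(x, k + 1)` is always a subset of `k_core(x, k)`.
#' @examples
#' k_core(gen_hetnet_like(seed = 1), 2)
#' @export
k_core <- function(x, k) {
  stopifnot(k >= 0)
  g <- as_graph(x)
  core <- igraph::coreness(g)
  tibble::tibble(id = sort(igraph::V(g)$name[core >= k]))
}

# vertex ids (igraph indices) of the maximal k-core of graph g
highest_core_vertices <- function(g) {
  core <- igraph::coreness(g)
  kmax <- max(core)
  list(k = kmax, vids = which(core == kmax))
}

simple_density <- function(n, e) {
  if (n < 2) return(0)
  2 * e / (n * (n - 1))
}

#' MCODE vertex weighting
#'
#' Scores each node by its core-clustering coefficient: the density of the
#' highest k-core of its closed neighbourhood, multiplied by that core's
#' k. Nodes with degree below `degree_cutoff` are not scored (weight 0).
#' This amplifies dense local regions while discounting spurious
#' low-degree periphery.
#'
#' @param x A `hetnet` object.
#' @param degree_cutoff Minimum degree for a node to be scored (default 2).
#' @return A tibble (`id`, `degree`, `weight`).
#' @export
vertex_weights <- function(x, degree_cutoff = 2) {
  stopifnot(degree_cutoff >= 1)
  g <- as_graph(x)
  deg <- igraph::degree(g)
  w <- vapply(seq_len(igraph::vcount(g)), function(v) {
    if (deg[v] < degree_cutoff) return(0)
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    hc <- highest_core_vertices(sub)
    core_sub <- igraph::induced_subgraph(sub, hc$vids)
    hc$k * simple_density(igraph::vcount(core_sub), igraph::ecount(core_sub))
  }, numeric(1))
  tibble::tibble(id = igraph::V(g)$name, degree = as.integer(deg), weight = w)
}

#' MCODE complex prediction
#'
#' Seeds candidate complexes from the highest-weight unvisited node and
#' grows them outward breadth-first, including neighbours whose weight is
#' at least `seed_weight * (1 - node_score_cutoff)`. Each node joins at
#' most one complex, so candidates are node-disjoint; ties are broken by
#' higher weight, then higher degree, then ascending id.
#'
#' @param x A `hetnet` object.
#' @param weights Optional precomputed [vertex_weights()] table.
#' @param node_score_cutoff Fractional weight tolerance for inclusion
#'   (default 0.2).
#' @inheritParams vertex_weights
#' @return A tibble (`seed`, `members`) where `members` is a list-column of
#'   character vectors.
#' @export
predict_complexes <- function(x, weights = NULL, node_score_cutoff = 0.2,
                              degree_cutoff = 2) {
  stopifnot(node_score_cutoff >= 0, node_score_cutoff <= 1)
  g <- as_graph(x)
  wt <- weights %||% vertex_weights(g, degree_cutoff)
  ids <- igraph::V(g)$name
  w <- setNames(wt$weight[match(ids, wt$id)], ids)
  deg <- igraph::degree(g)
  order_idx <- order(-w, -deg, ids)
  visited <- setNames(rep(FALSE, length(ids)), ids)
  nbr_cache <- igraph::adjacent_vertices(g, ids)
  names(nbr_cache) <- ids
  out_seed <- character()
  out_members <- list()
  for (i in order_idx) {
    seed <- ids[i]
    if (visited[[seed]] || w[[seed]] <= 0) next
    threshold <- w[[seed]] * (1 - node_score_cutoff)
    members <- seed
    visited[[seed]] <- TRUE
    queue <- seed
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nbrs <- ids[as.integer(nbr_cache[[v]])]
      for (nb in nbrs) {
        if (!visited[[nb]] && w[[nb]] >= threshold) {
          visited[[nb]] <- TRUE
          members <- c(members, nb)
          queue <- c(queue, nb)
        }
      }
    }
    out_seed <- c(out_seed, seed)
    out_members <- c(out_members, list(sort(members)))
  }
  tibble::tibble(seed = out_seed, members = out_members)
}

#' MCODE post-processing
#'
#' Filters and trims candidate complexes: candidates lacking a
#' `k_core_filter`-core are dropped; with `fluff`, boundary neighbours
#' whose closed-neighbourhood density exceeds `fluff_threshold` are added
#' (before the haircut, and never into two clusters); with `haircut`,
#' peripheral members with fewer than two within-cluster neighbours are
#' iteratively removed. Members are finally restricted to the connected
#' component containing the seed. Each cluster is scored density x size
#' and ranked by decreasing score, ties by larger size then ascending
#' seed id.
#'
#' @param x A `hetnet` object.
#' @param candidates A [predict_complexes()] table.
#' @param k_core_filter Required core (default 2).
#' @param haircut Remove <2-neighbour periphery (default `TRUE`).
#' @param fluff Add dense boundary neighbours (default `FALSE`).
#' @param fluff_threshold Closed-neighbourhood density required to fluff a
#'   boundary node in (default 0.5).
#' @return A `hetnet_clusters` object; `tidy()` gives the cluster table
#'   (`rank`, `seed`, `size`, `density`, `score`, `members`).
#' @export
postprocess_complexes <- function(x, candidates, k_core_filter = 2,
                                  haircut = TRUE, fluff = FALSE,
                                  fluff_threshold = 0.5) {
  stopifnot(k_core_filter >= 1)
  g <- as_graph(x)
  ids <- igraph::V(g)$name
  claimed <- unique(unlist(candidates$members))  # keeps clusters node-disjoint under fluff
  rows <- purrr::pmap(candidates, function(seed, members) {
    sub <- igraph::induced_subgraph(g, members)
    if (igraph::vcount(sub) == 0) return(NULL)
    if (max(igraph::coreness(sub)) < k_core_filter) return(NULL)
    if (fluff) {
      boundary <- setdiff(unique(unlist(purrr::map(
        members, function(m) ids[as.integer(igraph::neighbors(g, m))]
      ))), claimed)
      add <- boundary[vapply(boundary, function(b) {
        nb <- c(b, ids[as.integer(igraph::neighbors(g, b))])
        sb <- igraph::induced_subgraph(g, nb)
        simple_density(igraph::vcount(sb), igraph::ecount(sb)) > fluff_threshold
      }, logical(1))]
      members <- sort(c(members, add))
    }
    if (haircut) members <- haircut_members(g, members)
    if (length(members) == 0) return(NULL)
    members <- seed_component(g, members, seed)
    sub <- igraph::induced_subgraph(g, members)
    if (max(igraph::coreness(sub)) < k_core_filter) return(NULL)
    dens <- simple_density(igraph::vcount(sub), igraph::ecount(sub))
    claimed <<- c(claimed, members)
    tibble::tibble(seed = seed, size = length(members), density = dens,
                   score = dens * length(members), members = list(members))
  })
  tbl <- dplyr::bind_rows(rows)
  if (nrow(tbl) > 0) {
    tbl <- tbl |>
      dplyr::arrange(dplyr::desc(.data$score), dplyr::desc(.data$size), .data$seed) |>
      dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  } else {
    tbl <- tibble::tibble(rank = integer(), seed = character(), size = integer(),
                          density = numeric(), score = numeric(), members = list())
  }
  structure(list(clusters = tbl), class = "hetnet_clusters")
}

# iteratively drop members with < 2 neighbours inside the member set
# (equivalently: keep the 2-core of the induced subgraph)
haircut_members <- function(g, members) {
  sub <- igraph::induced_subgraph(g, members)
  core <- igraph::coreness(sub)
  sort(igraph::V(sub)$name[core >= 2])
}

seed_component <- function(g, members, seed) {
  sub <- igraph::induced_subgraph(g, members)
  comp <- igraph::components(sub)
  nm <- igraph::V(sub)$name
  keep_comp <- if (seed %in% nm) {
    comp$membership[[which(nm == seed)]]
  } else {
    # seed trimmed away: keep the largest component, ties by smallest id
    sizes <- comp$csize
    cand <- which(sizes == max(sizes))
    first_ids <- vapply(cand, function(i) min(nm[comp$membership == i]), character(1))
    cand[order(first_ids)][1]
  }
  sort(nm[comp$membership == keep_comp])
}

#' Molecular Complex Detection (MCODE-style clustering)
#'
#' Full dense-module detection pipeline: [vertex_weights()] →
#' [predict_complexes()] → [postprocess_complexes()]. Defaults follow the
#' standard parameterisation for receptor interaction networks: degree
#' cutoff 2, node score cutoff 0.2, 2-core filter, haircut on, fluff off.
#' Deterministic under the documented tie-breaks.
#'
#' @param x A `hetnet` object.
#' @inheritParams vertex_weights
#' @inheritParams predict_complexes
#' @inheritParams postprocess_complexes
#' @return A `hetnet_clusters` object.
#' @examples
#' mcode(gen_hetnet_like(seed = 1))
#' @export
mcode <- function(x, degree_cutoff = 2, node_score_cutoff = 0.2,
                  k_core_filter = 2, haircut = TRUE, fluff = FALSE,
                  fluff_threshold = 0.5) {
  g <- as_graph(x)
  wt <- vertex_weights(g, degree_cutoff)
  cand <- predict_complexes(g, wt, node_score_cutoff, degree_cutoff)
  postprocess_complexes(g, cand, k_core_filter = k_core_filter,
                        haircut = haircut, fluff = fluff,
                        fluff_threshold = fluff_threshold)
}

#' @export
print.hetnet_clusters <- function(x, ...) {
  cl <- x$clusters
  cat("<mcode clusters> ", nrow(cl), " cluster(s)\n", sep = "")
  if (nrow(cl) > 0) {
    show <- cl |>
      dplyr::mutate(members = purrr::map_chr(
        .data$members,
        ~ paste(head(.x, 6), collapse = ",") |>
          paste0(if (length(.x) > 6) ",..." else "")
      ))
    print(as.data.frame(show), row.names = FALSE)
  }
  invisible(x)
}

#' @export
tidy.hetnet_clusters <- function(x, ...) x$clusters

#' @export
glance.hetnet_clusters <- function(x, ...) {
  cl <- x$clusters
  tibble::tibble(
    n_clusters = nrow(cl),
    n_clustered_nodes = length(unique(unlist(cl$members))),
    top_score = if (nrow(cl) > 0) max(cl$score) else NA_real_
  )
}
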