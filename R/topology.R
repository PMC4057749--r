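#' Node degrees
#'
#' @param x A `hetnet` object (or igraph graph).
#' @return A tibble (`id`, `degree`) sorted by decreasing degree, ties by
#'   ascending id. The degree sum equals twice the edge count.
#' @export
node_degree <- function(x) {
  g <- as_graph(x)
  tibble::tibble(id = igraph::V(g)$name,
                 degree = as.integer(igraph::degree(g, loops = FALSE))) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$id)
}

#' Degree distribution P(k)
#'
#' P(k) is the fraction of nodes with exactly `k` connections. Isolated
#' nodes contribute to `k = 0`; all nodes, connected or not, are in the
#' denominator.
#'
#' @param x A `hetnet` object.
#' @return A tibble (`k`, `n_nodes`, `p_k`) over the observed support;
#'   `sum(p_k) == 1`.
#' @export
degree_distribution <- function(x) {
  g <- as_graph(x)
  if (igraph::vcount(g) == 0) abort("empty graph", class = "hetnet_empty_error")
  node_degree(g) |>
    dplyr::count(k = .data$degree, name = "n_nodes") |>
    dplyr::arrange(.data$k) |>
    dplyr::mutate(p_k = .data$n_nodes / igraph::vcount(g))
}

#' Local clustering coefficient C(n)
#'
#' C(n) = 2 n_l / (k (k - 1)), where n_l is the number of edges among the
#' neighbours of `n` and k its degree. Nodes with degree < 2 get C(n) = 0
#' (the formula is undefined there); they are nonetheless included in the
#' network-wide mean, following the convention of the standard network
#' analysis platforms for this kind of data.
#'
#' @param x A `hetnet` object.
#' @param node Optional single node id; if omitted, all nodes.
#' @return A tibble (`id`, `degree`, `clustering`).
#' @export
local_clustering <- function(x, node = NULL) {
  g <- as_graph(x)
  cc <- unname(igraph::transitivity(g, type = "local", isolates = "zero"))
  out <- tibble::tibble(id = igraph::V(g)$name,
                        degree = as.integer(igraph::degree(g)),
                        clustering = cc)
  out$clustering[out$degree < 2] <- 0
  if (!is.null(node)) {
    if (!node %in% out$id) {
      abort(paste0("Unknown node '", node, "'"), class = "hetnet_lookup_error")
    }
    out <- out[out$id == node, ]
  }
  out
}

#' Clustering-coefficient distribution C(k) and global coefficient
#'
#' C(k) is the mean local clustering coefficient over nodes of degree `k`;
#' the global coefficient is the mean of C(n) over all nodes in the
#' network (isolated and degree-1 nodes enter as zeros).
#'
#' @param x A `hetnet` object.
#' @return `clustering_distribution()`: a tibble (`k`, `n_nodes`, `c_k`);
#'   `global_clustering()`: a single number in \[0, 1\].
#' @export
clustering_distribution <- function(x) {
  local_clustering(x) |>
    dplyr::group_by(k = .data$degree) |>
    dplyr::summarise(n_nodes = dplyr::n(), c_k = mean(.data$clustering),
                     .groups = "drop") |>
    dplyr::arrange(.data$k)
}

#' @rdname clustering_distribution
#' @export
global_clustering <- function(x) {
  mean(local_clustering(x)$clustering)
}

#' Network density
#'
#' D = average_k / (N - 1) with average_k = 2E/N, i.e. the fraction of the
#' N(N-1)/2 possible pairs that is realised.
#'
#' @param x A `hetnet` object.
#' @return A single number in \[0, 1\].
#' @export
graph_density <- function(x) {
  g <- as_graph(x)
  n <- igraph::vcount(g)
  if (n < 2) abort("Density needs at least 2 nodes.", class = "hetnet_empty_error")
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' @rdname graph_density
#' @return `average_degree()`: 2E/N.
#' @export
average_degree <- function(x) {
  g <- as_graph(x)
  2 * igraph::ecount(g) / igraph::vcount(g)
}

#' Shortest-path structure
#'
#' All distances are breadth-first shortest paths on the undirected graph.
#' The histogram, mean and diameter are taken over unordered *connected*
#' pairs only: pairs in different components (or involving isolated nodes)
#' are excluded rather than treated as infinite, and the diameter is the
#' maximum finite distance.
#'
#' @param x A `hetnet` object.
#' @return `shortest_path_lengths()`: tibble (`from`, `to`, `distance`)
#'   over connected unordered pairs; `path_length_histogram()`: tibble
#'   (`length`, `n_pairs`); `mean_path_length()` and `graph_diameter()`:
#'   single numbers.
#' @export
shortest_path_lengths <- function(x) {
  g <- as_graph(x)
  ids <- igraph::V(g)$name
  d <- igraph::distances(g)
  ut <- upper.tri(d)
  idx <- which(ut & is.finite(d), arr.ind = TRUE)
  tibble::tibble(from = ids[idx[, 1]], to = ids[idx[, 2]],
                 distance = as.integer(d[idx]))
}

#' @rdname shortest_path_lengths
#' @export
path_length_histogram <- function(x) {
  shortest_path_lengths(x) |>
    dplyr::filter(.data$distance > 0) |>
    dplyr::count(length = .data$distance, name = "n_pairs") |>
    dplyr::arrange(.data$length)
}

#' @rdname shortest_path_lengths
#' @export
mean_path_length <- function(x) {
  h <- path_length_histogram(x)
  if (nrow(h) == 0) abort("no connected pairs", class = "hetnet_empty_error")
  sum(h$length * h$n_pairs) / sum(h$n_pairs)
}

#' @rdname shortest_path_lengths
#' @export
graph_diameter <- function(x) {
  h <- path_length_histogram(x)
  if (nrow(h) == 0) abort("no connected pairs", class = "hetnet_empty_error")
  max(h$length)
}

#' Connected components and relative connectivity
#'
#' The relative connectivity f is the size of the largest connected
#' component divided by the total node count; 0 < f <= 1, and f = 1 for a
#' connected graph.
#'
#' @param x A `hetnet` object.
#' @return `graph_components()`: tibble (`id`, `component`, `component_size`),
#'   components numbered by decreasing size (ties by smallest member id);
#'   `relative_connectivity()`: a single number.
#' @export
graph_components <- function(x) {
  g <- as_graph(x)
  comp <- igraph::components(g)
  ids <- igraph::V(g)$name
  first_id <- vapply(seq_along(comp$csize),
                     function(i) min(ids[comp$membership == i]), character(1))
  ord <- order(-comp$csize, first_id)
  renum <- match(seq_along(comp$csize), ord)
  tibble::tibble(id = ids,
                 component = renum[comp$membership],
                 component_size = as.integer(comp$csize[comp$membership])) |>
    dplyr::arrange(.data$component, .data$id)
}

#' @rdname graph_components
#' @export
relative_connectivity <- function(x) {
  g <- as_graph(x)
  if (igraph::vcount(g) == 0) abort("empty graph", class = "hetnet_empty_error")
  max(igraph::components(g)$csize) / igraph::vcount(g)
}

#' Fraction of edges incident to a node subset
#'
#' The share of all edges with at least one endpoint in `ids`. When the
#' subset is an independent set this equals the subset's degree sum over E
#' — the usual way a hub set's "share of all links" is reported.
#'
#' @param x A `hetnet` object.
#' @param ids Character vector of node ids (must all exist in the graph).
#' @return A single number in \[0, 1\]; 0 for an empty subset.
#' @export
edge_share <- function(x, ids) {
  g <- as_graph(x)
  if (igraph::ecount(g) == 0) abort("edge_share() needs at least one edge.")
  if (length(ids) == 0) return(0)
  missing <- setdiff(ids, igraph::V(g)$name)
  if (length(missing) > 0) {
    abort(paste0("Unknown node(s): ", paste(head(missing, 5), collapse = ", ")),
          class = "hetnet_lookup_error")
  }
  ends <- igraph::as_edgelist(g, names = TRUE)
  mean(ends[, 1] %in% ids | ends[, 2] %in% ids)
}

#' Full topological profile
#'
#' Computes every distribution and scalar metric in one pass: N, E,
#' density, average degree 2E/N, mean path length, diameter, global
#' clustering coefficient and relative connectivity, plus the P(k), C(k)
#' and path-length tables. On a graph with no connected pairs the
#' path-based scalars are `NA` with a warning.
#'
#' @param x A `hetnet` object.
#' @return A `hetnet_profile` object; see [glance.hetnet_profile()] for the
#'   one-row scalar summary and [autoplot.hetnet_profile()] for plots.
#' @examples
#' glance(topology_profile(gen_hetnet_like(seed = 1)))
#' @export
topology_profile <- function(x) {
  g <- as_graph(x)
  if (igraph::vcount(g) == 0) abort("empty graph", class = "hetnet_empty_error")
  hist <- path_length_histogram(g)
  if (nrow(hist) > 0) {
    mpl <- sum(hist$length * hist$n_pairs) / sum(hist$n_pairs)
    diam <- max(hist$length)
  } else {
    warn("Graph has no connected pairs; path metrics are NA.")
    mpl <- NA_real_
    diam <- NA_integer_
  }
  scalars <- tibble::tibble(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    density = if (igraph::vcount(g) >= 2) graph_density(g) else NA_real_,
    average_degree = average_degree(g),
    mean_path_length = mpl,
    diameter = diam,
    global_clustering = global_clustering(g),
    relative_connectivity = relative_connectivity(g)
  )
  structure(list(
    scalars = scalars,
    degree_distribution = degree_distribution(g),
    clustering_distribution = clustering_distribution(g),
    path_length_histogram = hist
  ), class = "hetnet_profile")
}

#' @export
print.hetnet_profile <- function(x, ...) {
  cat("<topological profile>\n")
  print(as.data.frame(x$scalars), row.names = FALSE)
  cat("degree support: k = ", min(x$degree_distribution$k), "..",
      max(x$degree_distribution$k), "\n", sep = "")
  invisible(x)
}

#' One-row scalar summary of a topological profile
#'
#' @param x A `hetnet_profile` from [topology_profile()].
#' @param ... Unused.
#' @return A one-row tibble of the scalar metrics.
#' @export
glance.hetnet_profile <- function(x, ...) x$scalars

#' @export
tidy.hetnet_profile <- function(x, ...) {
  dplyr::bind_rows(
    x$degree_distribution |>
      dplyr::transmute(distribution = "P(k)", k = .data$k, value = .data$p_k),
    x$clustering_distribution |>
      dplyr::transmute(distribution = "C(k)", k = .data$k, value = .data$c_k),
    x$path_length_histogram |>
      dplyr::transmute(distribution = "path lengths", k = .data$length,
                       value = as.numeric(.data$n_pairs))
  )
}
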