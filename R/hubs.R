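#' Hub identification criteria
#'
#' Four alternative criteria designate the highly connected protomers of a
#' receptor network as hubs:
#'
#' * [hubs_degree_threshold()] — every node with degree strictly greater
#'   than `t` (the classic "degree > 5" and "degree > 8" rules);
#' * [hubs_top_percentile()] — the top `1 - q` fraction of the high-degree
#'   nodes (nearest rank on the descending degree sequence; ties at the
#'   realized cutoff are included);
#' * [hubs_relative_connectivity()] — the successive-subgraph procedure:
#'   hubs are the nodes before the first rise of the relative connectivity
#'   f along the degree-ordered prefix subgraphs (hubs connect mostly to
#'   non-hubs, so f falls while hubs are being added and first rises when a
#'   node arrives that ties them together);
#' * [nonhub_degree_one()] — the degree-1 periphery, the complement view.
#'
#' All four accept either a `hetnet` graph or a plain data frame of
#' (`id`, `degree`) rows — e.g. a published degree table — except
#' `hubs_relative_connectivity()`, which needs the graph structure itself.
#'
#' @param x A `hetnet` object, or (except for
#'   `hubs_relative_connectivity()`) a data frame with columns `id` and
#'   `degree`.
#' @param t Degree threshold; hubs have degree strictly greater than `t`.
#' @return A `hetnet_hubs` object: `criterion`, realized `cutoff`, `hubs`
#'   (tibble `id`, `degree`, sorted by decreasing degree then ascending
#'   id), `status`, and for the relative-connectivity criterion the
#'   `f_trajectory` tibble. `tidy()` returns the hub tibble.
#' @examples
#' hubs_degree_threshold(gpcr_reference_degrees(), 8)
#' @export
hubs_degree_threshold <- function(x, t) {
  stopifnot(t >= 0)
  deg <- degree_frame(x)
  hubs <- deg[deg$degree > t, , drop = FALSE]
  new_hubs(criterion = paste0("degree>", t), cutoff = t, hubs = hubs)
}

#' @param q Quantile defining the "top `1 - q`" high-degree slice
#'   (default 0.95, i.e. the top 5% of nodes by degree).
#' @rdname hubs_degree_threshold
#' @export
hubs_top_percentile <- function(x, q = 0.95) {
  stopifnot(q > 0, q < 1)
  deg <- degree_frame(x)
  n <- nrow(deg)
  if (n < 1) abort("empty graph", class = "hetnet_empty_error")
  # round before ceiling: (1 - 0.95) * 20 is 1 + 4.4e-16 in binary
  n_top <- max(1L, ceiling(round((1 - q) * n, 9)))
  cutoff <- deg$degree[n_top]  # deg is sorted descending
  hubs <- deg[deg$degree >= cutoff, , drop = FALSE]
  status <- if (length(unique(deg$degree)) == 1) "degenerate" else "ok"
  new_hubs(criterion = paste0("top", round(100 * q), "pct"), cutoff = cutoff,
           hubs = hubs, status = status)
}

#' @rdname hubs_degree_threshold
#' @export
nonhub_degree_one <- function(x) {
  deg <- degree_frame(x)
  out <- deg[deg$degree == 1, , drop = FALSE]
  dplyr::arrange(out, .data$id)
}

#' @rdname hubs_degree_threshold
#' @export
hubs_relative_connectivity <- function(x) {
  g <- as_graph(x)
  if (igraph::vcount(g) < 2) {
    abort("Relative-connectivity hub selection needs at least 2 nodes.",
          class = "hetnet_empty_error")
  }
  if (igraph::ecount(g) == 0) {
    abort("Relative-connectivity hub selection needs at least one edge.",
          class = "hetnet_empty_error")
  }
  deg <- degree_frame(g)  # descending degree, ties ascending id
  ids <- deg$id
  n <- length(ids)
  # f_k = |largest component of the induced prefix subgraph| / k; track the
  # largest component exactly with union-find as nodes arrive.
  parent <- seq_len(n)
  size <- rep(1L, n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pos <- setNames(seq_len(n), ids)
  adj <- igraph::adjacent_vertices(g, ids)
  largest <- 0L
  f <- numeric(n)
  comp_max <- integer(n)
  stop_k <- NA_integer_
  for (k in seq_len(n)) {
    largest <- max(largest, 1L)
    nbrs <- igraph::V(g)$name[adj[[k]]]
    for (nb in nbrs) {
      j <- pos[[nb]]
      if (j < k) {
        rk <- find(k); rj <- find(j)
        if (rk != rj) {
          if (size[rk] < size[rj]) { tmp <- rk; rk <- rj; rj <- tmp }
          parent[rj] <- rk
          size[rk] <- size[rk] + size[rj]
          if (size[rk] > largest) largest <- size[rk]
        }
      }
    }
    comp_max[k] <- largest
    f[k] <- largest / k
    # exact rational comparison f_k > f_{k-1}
    if (k > 1 && is.na(stop_k) &&
        comp_max[k] * (k - 1) > comp_max[k - 1] * k) {
      stop_k <- k
      break
    }
  }
  if (is.na(stop_k)) {
    traj <- tibble::tibble(k = seq_len(n), id = ids,
                           largest_component = comp_max, f = f)
    return(new_hubs(criterion = "relative_connectivity", cutoff = NA_integer_,
                    hubs = deg[0, ], status = "no boundary found",
                    f_trajectory = traj))
  }
  traj <- tibble::tibble(k = seq_len(stop_k), id = ids[seq_len(stop_k)],
                         largest_component = comp_max[seq_len(stop_k)],
                         f = f[seq_len(stop_k)])
  hubs <- deg[seq_len(stop_k - 1), , drop = FALSE]
  new_hubs(criterion = "relative_connectivity",
           cutoff = min(hubs$degree), hubs = hubs, f_trajectory = traj)
}

degree_frame <- function(x) {
  if (is_hetnet(x) || igraph::is_igraph(x)) {
    node_degree(x)
  } else {
    d <- tibble::as_tibble(x)
    if (!all(c("id", "degree") %in% names(d))) {
      abort("Degree table input needs `id` and `degree` columns.")
    }
    d |>
      dplyr::transmute(id = as.character(.data$id),
                       degree = as.integer(.data$degree)) |>
      dplyr::arrange(dplyr::desc(.data$degree), .data$id)
  }
}

new_hubs <- function(criterion, cutoff, hubs, status = "ok", f_trajectory = NULL) {
  structure(list(criterion = criterion, cutoff = cutoff,
                 hubs = tibble::as_tibble(hubs), status = status,
                 f_trajectory = f_trajectory),
            class = "hetnet_hubs")
}

#' @export
print.hetnet_hubs <- function(x, ...) {
  cat("<hubs: ", x$criterion, "> ", nrow(x$hubs), " hub(s)",
      if (!is.na(x$cutoff)) paste0(", cutoff ", x$cutoff) else "",
      if (x$status != "ok") paste0(" [", x$status, "]") else "",
      "\n", sep = "")
  if (nrow(x$hubs) > 0) {
    print(as.data.frame(head(x$hubs, 15)), row.names = FALSE)
    if (nrow(x$hubs) > 15) cat("... and ", nrow(x$hubs) - 15, " more\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.hetnet_hubs <- function(x, ...) x$hubs

#' @export
glance.hetnet_hubs <- function(x, ...) {
  tibble::tibble(criterion = x$criterion, cutoff = x$cutoff,
                 n_hubs = nrow(x$hubs), status = x$status)
}
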