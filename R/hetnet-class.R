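#' The `hetnet` graph container
#'
#' A `hetnet` is a simple undirected graph of receptor protomers: no
#' self-loops, no parallel edges, isolated nodes permitted. Nodes carry a
#' GPCR family label (`F1` = Class A / rhodopsin-like, `F2` = Class B /
#' Secretin-like, `F3` = Class C / metabotropic-glutamate-like, or
#' `unknown`) and an optional display name. Edges carry the detection
#' evidence (`methods`), a supporting publication count and a
#' `controversial` flag. Internally the graph is an [igraph][igraph::igraph]
#' object; use [node_table()] and [edge_table()] to get tibble views, or
#' [as.igraph()][igraph::as.igraph] for the raw graph.
#'
#' @param edges A data frame of raw edge records. The endpoint columns are
#'   `protomer_a` and `protomer_b` (or, failing those names, the first two
#'   columns). Optional columns: `methods` (semicolon-separated evidence
#'   tags), `n_publications`, `controversial`.
#' @param nodes Optional node-attribute data frame with columns `id`,
#'   `family` (one of `A`,`B`,`C`,`F1`,`F2`,`F3`, case-insensitive) and
#'   optionally `display_name`. Ids present here but absent from `edges`
#'   become isolated nodes.
#'
#' @return A `hetnet` object. `attr(x, "dropped")` records how many
#'   self-loops and duplicate edges were removed during normalisation.
#' @examples
#' g <- hetnet(data.frame(protomer_a = c("DRD2", "DRD2", "AA2AR"),
#'                        protomer_b = c("AA2AR", "DRD2", "DRD2")))
#' n_edges(g)  # 1: the self-loop and the reversed duplicate are removed
#' @export
hetnet <- function(edges, nodes = NULL) {
  normalize_graph(edges, nodes)
}

valid_families <- c("F1", "F2", "F3", "unknown")

canonical_family <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- dplyr::case_when(
    x %in% c("F1", "A", "CLASSA", "CLASS A", "1") ~ "F1",
    x %in% c("F2", "B", "CLASSB", "CLASS B", "2") ~ "F2",
    x %in% c("F3", "C", "CLASSC", "CLASS C", "3") ~ "F3",
    TRUE ~ "unknown"
  )
  out[is.na(x) | x == ""] <- "unknown"
  out
}

new_hetnet <- function(graph, dropped = list(self_loops = 0L, duplicates = 0L)) {
  structure(list(graph = graph), dropped = dropped, class = "hetnet")
}

is_hetnet <- function(x) inherits(x, "hetnet")

# Accept a hetnet or a bare igraph everywhere internally.
as_graph <- function(x) {
  if (is_hetnet(x)) return(x$graph)
  if (igraph::is_igraph(x)) return(x)
  abort("`x` must be a `hetnet` object (see `hetnet()`) or an igraph graph.")
}

#' @importFrom igraph as.igraph
#' @export
as.igraph.hetnet <- function(x, ...) x$graph

#' Number of nodes / edges in a `hetnet`
#'
#' @param x A `hetnet` object.
#' @return An integer count.
#' @export
n_nodes <- function(x) igraph::vcount(as_graph(x))

#' @rdname n_nodes
#' @export
n_edges <- function(x) igraph::ecount(as_graph(x))

#' Tibble views of a `hetnet`
#'
#' `node_table()` returns one row per protomer (`id`, `family`,
#' `display_name`); `edge_table()` one row per heteromer pair
#' (`protomer_a`, `protomer_b`, `methods`, `n_publications`,
#' `controversial`). Endpoints are ordered so `protomer_a < protomer_b`.
#'
#' @param x A `hetnet` object.
#' @return A tibble.
#' @export
node_table <- function(x) {
  g <- as_graph(x)
  tibble::tibble(
    id = igraph::V(g)$name,
    family = igraph::V(g)$family %||% rep("unknown", igraph::vcount(g)),
    display_name = igraph::V(g)$display_name %||% rep(NA_character_, igraph::vcount(g))
  )
}

#' @rdname node_table
#' @export
edge_table <- function(x) {
  g <- as_graph(x)
  if (igraph::ecount(g) == 0) {
    return(tibble::tibble(
      protomer_a = character(), protomer_b = character(),
      methods = character(), n_publications = integer(),
      controversial = logical()
    ))
  }
  ends <- igraph::as_edgelist(g, names = TRUE)
  a <- pmin(ends[, 1], ends[, 2])
  b <- pmax(ends[, 1], ends[, 2])
  tibble::tibble(
    protomer_a = a,
    protomer_b = b,
    methods = igraph::E(g)$methods %||% rep("", length(a)),
    n_publications = as.integer(igraph::E(g)$n_publications %||% rep(0L, length(a))),
    controversial = as.logical(igraph::E(g)$controversial %||% rep(FALSE, length(a)))
  ) |>
    dplyr::arrange(.data$protomer_a, .data$protomer_b)
}

#' @export
print.hetnet <- function(x, ...) {
  fam <- table(factor(node_table(x)$family, levels = valid_families))
  cat("<hetnet> ", n_nodes(x), " protomers, ", n_edges(x), " heteromer pairs\n", sep = "")
  cat("  families: ",
      paste0(names(fam)[fam > 0], "=", fam[fam > 0], collapse = ", "),
      "\n", sep = "")
  dropped <- attr(x, "dropped")
  if (!is.null(dropped) && (dropped$self_loops > 0 || dropped$duplicates > 0)) {
    cat("  normalisation dropped ", dropped$self_loops, " self-loop(s), merged ",
        dropped$duplicates, " duplicate edge(s)\n", sep = "")
  }
  invisible(x)
}
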