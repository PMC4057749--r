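#' Read a raw receptor-interaction edge table
#'
#' Parses TSV/CSV edge tables or Cytoscape SIF files into raw edge records.
#' Records are returned in input order, unnormalised: self-loops and
#' duplicates survive until [normalize_graph()]. TSV/CSV files need a header
#' with endpoint columns `protomer_a`, `protomer_b` (or the first two
#' columns are taken as endpoints); extra columns are carried along by
#' name. SIF rows are `source relation target [target ...]`; one record is
#' emitted per (source, target) pair and the relation token is ignored
#' (every edge is a heteromer interaction).
#'
#' @param path Path to the file.
#' @param dialect One of `"tsv"`, `"csv"`, `"sif"`. Defaults from the file
#'   extension, falling back to `"tsv"`.
#' @return A tibble of raw records with columns `protomer_a`, `protomer_b`,
#'   any extra attribute columns, and `line` (1-based source line).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("protomer_a\tprotomer_b", "DRD2\tAA2AR", "DRD2\tDRD2"), f)
#' read_edge_table(f)
#' @export
read_edge_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Edge table not found: '", path, "'"), class = "hetnet_io_error")
  }
  dialect <- dialect %||% guess_dialect(path)
  dialect <- rlang::arg_match(dialect, c("tsv", "csv", "sif"))
  if (dialect == "sif") {
    return(read_sif(path))
  }
  delim <- if (dialect == "csv") "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0) {
    warn(paste0("Edge table '", path, "' contains no records."))
    return(tibble::tibble(protomer_a = character(), protomer_b = character(),
                          line = integer()))
  }
  nm <- names(raw)
  if (!all(c("protomer_a", "protomer_b") %in% nm)) {
    if (ncol(raw) < 2) {
      abort(paste0("Edge table '", path, "' needs two identifier columns."),
            class = "hetnet_format_error")
    }
    names(raw)[1:2] <- c("protomer_a", "protomer_b")
  }
  raw$line <- seq_len(nrow(raw)) + 1L  # header is line 1
  bad <- which(is.na(raw$protomer_a) | raw$protomer_a == "" |
                 is.na(raw$protomer_b) | raw$protomer_b == "")
  if (length(bad) > 0) {
    abort(paste0("Row with fewer than 2 identifiers at line ", raw$line[bad[1]],
                 " of '", path, "'"), class = "hetnet_format_error")
  }
  tibble::as_tibble(raw)
}

guess_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = "csv", sif = "sif", "tsv")
}

read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(trimws(lines) != "")
  if (length(keep) == 0) {
    warn(paste0("SIF file '", path, "' contains no records."))
    return(tibble::tibble(protomer_a = character(), protomer_b = character(),
                          line = integer()))
  }
  recs <- purrr::map(keep, function(i) {
    tokens <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tokens) == 1) {
      # a lone node: legal SIF, declares an isolated node
      return(tibble::tibble(protomer_a = tokens[1], protomer_b = NA_character_,
                            line = i))
    }
    if (length(tokens) < 3) {
      abort(paste0("SIF row with fewer than 2 identifiers at line ", i,
                   " of '", path, "'"), class = "hetnet_format_error")
    }
    tibble::tibble(protomer_a = tokens[1], protomer_b = tokens[-(1:2)], line = i)
  })
  dplyr::bind_rows(recs)
}

#' Read a node-attribute table
#'
#' @param path TSV/CSV file with columns `id`, `family` and optionally
#'   `display_name`. Family labels `A`/`B`/`C` and `F1`/`F2`/`F3` are both
#'   accepted.
#' @return A tibble with columns `id`, `family` (canonical `F1`/`F2`/`F3`/
#'   `unknown`), `display_name`.
#' @export
read_node_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Node table not found: '", path, "'"), class = "hetnet_io_error")
  }
  delim <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  if (!"id" %in% names(raw)) {
    abort(paste0("Node table '", path, "' needs an `id` column."),
          class = "hetnet_format_error")
  }
  tibble::tibble(
    id = toupper(trimws(raw$id)),
    family = canonical_family(raw$family %||% rep(NA_character_, nrow(raw))),
    display_name = as.character(raw$display_name %||% rep(NA_character_, nrow(raw)))
  )
}

#' Normalise raw edge records into a simple undirected graph
#'
#' Applies the normalisation used throughout the analysis: identifiers are
#' upper-cased; self-loops (homodimer records) are dropped; duplicate
#' unordered pairs — including reciprocal detections A-B / B-A — are merged,
#' with evidence tag sets unioned, `n_publications` taking the maximum of
#' the duplicates (counts are never summed, so support is never inflated)
#' and `controversial` the logical OR. Ids appearing only in `nodes` are
#' added as isolated nodes; the network keeps them in all downstream
#' metrics.
#'
#' @inheritParams hetnet
#' @param allow_isolated If `FALSE`, warn when the attribute table names ids
#'   never seen in the edge records (they are still added as isolated
#'   nodes). Default `TRUE`: disconnected protomers are a normal feature of
#'   heteroreceptor networks.
#' @return A `hetnet` object; `attr(, "dropped")` counts removed self-loops
#'   and merged duplicates. Normalisation is idempotent.
#' @export
normalize_graph <- function(edges, nodes = NULL, allow_isolated = TRUE) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0 && !all(c("protomer_a", "protomer_b") %in% names(edges))) {
    if (ncol(edges) < 2) {
      abort("Edge records need two identifier columns.", class = "hetnet_format_error")
    }
    names(edges)[1:2] <- c("protomer_a", "protomer_b")
  }
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(protomer_a = character(), protomer_b = character())
  }
  # lone-node SIF records contribute a node but no edge
  lone <- edges[is.na(edges$protomer_b), , drop = FALSE]
  edges <- edges[!is.na(edges$protomer_b) & !is.na(edges$protomer_a), , drop = FALSE]

  a <- toupper(trimws(edges$protomer_a))
  b <- toupper(trimws(edges$protomer_b))
  methods <- if ("methods" %in% names(edges)) as.character(edges$methods) else rep("", length(a))
  methods[is.na(methods)] <- ""
  npub <- if ("n_publications" %in% names(edges)) {
    suppressWarnings(as.integer(edges$n_publications))
  } else rep(NA_integer_, length(a))
  contro <- if ("controversial" %in% names(edges)) {
    tolower(as.character(edges$controversial)) %in% c("true", "t", "1", "yes")
  } else rep(FALSE, length(a))

  loops <- a == b
  n_loops <- sum(loops)
  a2 <- pmin(a[!loops], b[!loops])
  b2 <- pmax(a[!loops], b[!loops])
  rec <- tibble::tibble(a = a2, b = b2,
                        methods = methods[!loops],
                        n_publications = npub[!loops],
                        controversial = contro[!loops])
  merged <- rec |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(
      methods = merge_method_tags(.data$methods),
      n_publications = if (all(is.na(.data$n_publications))) 0L else
        max(.data$n_publications, na.rm = TRUE),
      controversial = any(.data$controversial),
      .groups = "drop"
    )
  n_dups <- nrow(rec) - nrow(merged)

  ids <- sort(unique(c(merged$a, merged$b, toupper(trimws(lone$protomer_a)))))
  fam <- setNames(rep("unknown", length(ids)), ids)
  disp <- setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(nodes)) {
    nodes <- tibble::as_tibble(nodes)
    if (!"id" %in% names(nodes)) {
      abort("Node attribute table needs an `id` column.", class = "hetnet_format_error")
    }
    nid <- toupper(trimws(nodes$id))
    extra <- setdiff(nid, ids)
    if (length(extra) > 0 && !allow_isolated) {
      warn(paste0(length(extra), " attribute-table id(s) never appear in the edge",
                  " records; added as isolated nodes: ",
                  paste(head(extra, 5), collapse = ", "),
                  if (length(extra) > 5) ", ..." else ""))
    }
    ids <- c(ids, extra)  # attribute-only ids become isolated nodes
    fam <- c(fam, setNames(rep("unknown", length(extra)), extra))
    disp <- c(disp, setNames(rep(NA_character_, length(extra)), extra))
    fam[nid] <- canonical_family(nodes$family %||% rep(NA_character_, nrow(nodes)))
    if ("display_name" %in% names(nodes)) disp[nid] <- as.character(nodes$display_name)
  }
  ord <- order(ids)
  ids <- ids[ord]

  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  igraph::V(g)$family <- unname(fam[ids])
  igraph::V(g)$display_name <- unname(disp[ids])
  if (nrow(merged) > 0) {
    g <- igraph::add_edges(g, rbind(merged$a, merged$b))
    igraph::E(g)$methods <- merged$methods
    igraph::E(g)$n_publications <- merged$n_publications
    igraph::E(g)$controversial <- merged$controversial
  }
  new_hetnet(g, dropped = list(self_loops = as.integer(n_loops),
                               duplicates = as.integer(n_dups)))
}

merge_method_tags <- function(x) {
  tags <- sort(unique(unlist(strsplit(x[x != ""], ";[ ]*"))))
  paste(tags, collapse = ";")
}

#' Write a `hetnet` to disk
#'
#' `"tsv"` writes the normalised edge table (round-trips through
#' [read_edge_table()] + [normalize_graph()]); `"sif"` writes Cytoscape SIF
#' with relation token `pp` plus lone-node rows for isolated nodes. A
#' companion node-attribute table can be written with `nodes_path` so family
#' labels survive the round trip.
#'
#' @param x A `hetnet` object.
#' @param path Output file path.
#' @param dialect `"tsv"` or `"sif"`.
#' @param nodes_path Optional path for the node-attribute TSV.
#' @return `path`, invisibly.
#' @export
write_graph_table <- function(x, path, dialect = c("tsv", "sif"), nodes_path = NULL) {
  dialect <- rlang::arg_match(dialect)
  et <- edge_table(x)
  nt <- node_table(x)
  if (dialect == "tsv") {
    readr::write_tsv(et, path, progress = FALSE)
  } else {
    iso <- setdiff(nt$id, unique(c(et$protomer_a, et$protomer_b)))
    lines <- c(paste(et$protomer_a, "pp", et$protomer_b), iso)
    writeLines(lines, path)
  }
  if (!is.null(nodes_path)) {
    readr::write_tsv(nt, nodes_path, progress = FALSE)
  }
  invisible(path)
}
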