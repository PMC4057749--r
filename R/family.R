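#' Family composition of a heteroreceptor network
#'
#' Counts protomers per GPCR family and partitions the edges into
#' intrafamily (F1-F1, F2-F2, F3-F3) and interfamily pairs. Edges with an
#' endpoint of unknown family are reported in their own `unknown` row so
#' the edge partition always sums exactly to the edge count.
#'
#' @param x A `hetnet` object.
#' @return A `hetnet_family_summary`: a list with tibbles `nodes`
#'   (`family`, `n_nodes`) and `edges` (`type`, `n_edges`).
#' @examples
#' g <- gen_hetnet_like(seed = 1)
#' family_summary(g)
#' @export
family_summary <- function(x) {
  nt <- node_table(x)
  et <- edge_table(x)
  fam <- setNames(nt$family, nt$id)
  node_counts <- nt |>
    dplyr::count(family = factor(.data$family, levels = valid_families),
                 name = "n_nodes", .drop = FALSE) |>
    dplyr::mutate(family = as.character(.data$family))
  fa <- fam[et$protomer_a]
  fb <- fam[et$protomer_b]
  type <- dplyr::case_when(
    fa == "unknown" | fb == "unknown" ~ "unknown",
    fa == fb ~ paste0(fa, "-", fa),
    TRUE ~ "interfamily"
  )
  lv <- c("F1-F1", "F2-F2", "F3-F3", "interfamily", "unknown")
  edge_counts <- tibble::tibble(type = factor(type, levels = lv)) |>
    dplyr::count(.data$type, name = "n_edges", .drop = FALSE) |>
    dplyr::mutate(type = as.character(.data$type))
  structure(list(nodes = node_counts, edges = edge_counts),
            class = "hetnet_family_summary")
}

#' @export
print.hetnet_family_summary <- function(x, ...) {
  cat("<family composition>\n")
  cat("protomers per family:\n")
  print(as.data.frame(x$nodes), row.names = FALSE)
  cat("heteromer pairs by family pairing:\n")
  print(as.data.frame(x$edges), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.hetnet_family_summary <- function(x, ...) {
  dplyr::bind_rows(
    x$nodes |> dplyr::rename(item = "family", n = "n_nodes") |>
      dplyr::mutate(what = "nodes", .before = 1),
    x$edges |> dplyr::rename(item = "type", n = "n_edges") |>
      dplyr::mutate(what = "edges", .before = 1)
  )
}

#' Percentage share, rounded half away from zero
#'
#' Small helper matching how shares are conventionally reported for this
#' network (integer percent by default): e.g. 15 of 46 Secretin-family
#' receptors with an observed interaction is a 33% coverage.
#'
#' @param numerator,denominator Counts.
#' @param digits Decimal places of the reported percentage.
#' @return A single number, `100 * numerator / denominator` rounded half
#'   away from zero to `digits` places.
#' @examples
#' percent_share(15, 46)   # 33
#' percent_share(56, 156)  # 36
#' @export
percent_share <- function(numerator, denominator, digits = 0) {
  if (denominator == 0) abort("percent_share(): denominator is zero.")
  round_half_away(100 * numerator / denominator, digits)
}

# round() half-to-even differs from how percentages are conventionally
# printed; round half away from zero instead.
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
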