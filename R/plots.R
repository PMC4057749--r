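#' Plot a topological profile
#'
#' Draws the degree distribution P(k) and clustering distribution C(k) on
#' log-log axes (the scale on which power-law behaviour is a straight
#' line) and the path-length histogram on linear axes.
#'
#' @param object A `hetnet_profile` from [topology_profile()].
#' @param which One or more of `"degree"`, `"clustering"`, `"paths"`.
#' @param ... Unused.
#' @return A ggplot object (facetted when several panels are requested).
#' @export
autoplot.hetnet_profile <- function(object, which = c("degree", "clustering"), ...) {
  which <- match.arg(which, c("degree", "clustering", "paths"), several.ok = TRUE)
  d <- tidy(object)
  keep <- c(degree = "P(k)", clustering = "C(k)", paths = "path lengths")[which]
  d <- d[d$distribution %in% keep & d$k > 0 & d$value > 0, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$distribution), scales = "free") +
    ggplot2::labs(x = "k", y = NULL) +
    ggplot2::theme_minimal()
  if (all(keep != "path lengths")) {
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
  p
}

#' Plot a classification's distributions with their fitted power laws
#'
#' P(k) and C(k) points on log-log axes with the fitted power-law lines
#' overlaid; the subtitle reports the label and the competing R-squared
#' values.
#'
#' @param object A `hetnet_classification` from [classify_network()].
#' @param x A `hetnet` object (the distributions are recomputed from it).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_classification <- function(object, x, ...) {
  stopifnot(inherits(object, "hetnet_classification"))
  pk <- degree_distribution(x) |>
    dplyr::transmute(distribution = "P(k)", k = .data$k, value = .data$p_k)
  ck <- clustering_distribution(x) |>
    dplyr::transmute(distribution = "C(k)", k = .data$k, value = .data$c_k)
  d <- dplyr::bind_rows(pk, ck)
  d <- d[d$k > 0 & d$value > 0, ]
  lines <- purrr::compact(list(
    if (!is.null(object$fits$pk_power)) {
      tibble::tibble(distribution = "P(k)", slope = object$fits$pk_power$slope,
                     intercept = object$fits$pk_power$intercept)
    },
    if (!is.null(object$fits$ck_power)) {
      tibble::tibble(distribution = "C(k)", slope = object$fits$ck_power$slope,
                     intercept = object$fits$ck_power$intercept)
    }
  )) |> dplyr::bind_rows()
  g <- glance(object)
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$k), y = log10(.data$value))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept),
                         linetype = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$distribution), scales = "free") +
    ggplot2::labs(
      x = "log10 k", y = "log10 value",
      subtitle = sprintf("label: %s | P(k) R2 power %.2f vs linear %.2f",
                         object$label %||% NA,
                         g$pk_power_r2, g$pk_linear_r2)
    ) +
    ggplot2::theme_minimal()
}
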