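#' Competing fits to a degree or clustering distribution
#'
#' `fit_powerlaw()` fits `y = a * k^(-gamma)` by least squares on the
#' (log10 k, log10 y) points; `fit_linear()` fits `y = a + b k` on the
#' untransformed points. Both are fit on the raw unique-k distribution
#' table — no logarithmic binning, no CCDF — matching how such
#' distributions are conventionally plotted and scored for this kind of
#' network. R-squared is computed as 1 - SS_res/SS_tot on the same
#' (possibly transformed) points used for the fit.
#'
#' A distribution with zero variance on the fitted scale (SS_tot = 0) is
#' degenerate: the fit is reported with R-squared 1 and `degenerate =
#' TRUE`, and [classify_network()] refuses to score it.
#'
#' @param distribution A data frame whose first column is `k` and second
#'   the distribution value (e.g. the `k`/`p_k` columns of
#'   [degree_distribution()], or `k`/`c_k` of [clustering_distribution()]).
#'   Columns named `k` and one of `p_k`, `c_k`, `y`, `value` are used when
#'   present.
#' @return A `hetnet_fit` object with fields `model`, `slope`, `intercept`,
#'   `exponent` (gamma, power-law only), `r_squared` (clamped to \[0, 1\]),
#'   `r_squared_raw`, `degenerate`, `n_points`. [tidy()] and [glance()]
#'   methods are provided.
#' @examples
#' d <- data.frame(k = c(1, 2, 4, 8), p_k = c(1, 2, 4, 8)^-2)
#' glance(fit_powerlaw(d))  # gamma = 2, R^2 = 1
#' @export
fit_powerlaw <- function(distribution) {
  d <- extract_ky(distribution)
  d <- d[d$k > 0 & d$y > 0, , drop = FALSE]
  if (nrow(d) < 3) {
    abort("insufficient support: need >= 3 points with k > 0 and y > 0",
          class = "hetnet_fit_error")
  }
  lx <- log10(d$k)
  ly <- log10(d$y)
  ls_fit("power-law", lx, ly, n_input = nrow(d))
}

#' @rdname fit_powerlaw
#' @export
fit_linear <- function(distribution) {
  d <- extract_ky(distribution)
  if (nrow(d) < 3) {
    abort("insufficient support: need >= 3 points", class = "hetnet_fit_error")
  }
  ls_fit("linear", d$k, d$y, n_input = nrow(d))
}

extract_ky <- function(distribution) {
  d <- as.data.frame(distribution)
  ycol <- intersect(c("p_k", "c_k", "y", "value"), names(d))
  if ("k" %in% names(d) && length(ycol) > 0) {
    data.frame(k = as.numeric(d$k), y = as.numeric(d[[ycol[1]]]))
  } else {
    data.frame(k = as.numeric(d[[1]]), y = as.numeric(d[[2]]))
  }
}

ls_fit <- function(model, xs, ys, n_input) {
  fit <- lm(ys ~ xs)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ys - mean(ys))^2)
  degenerate <- ss_tot < 1e-12
  r2_raw <- if (degenerate) 1 else 1 - ss_res / ss_tot
  slope <- unname(coef(fit)[2])
  structure(list(
    model = model,
    slope = slope,
    intercept = unname(coef(fit)[1]),
    exponent = if (model == "power-law") -slope else NA_real_,
    r_squared = min(1, max(0, r2_raw)),
    r_squared_raw = r2_raw,
    degenerate = degenerate,
    n_points = n_input
  ), class = "hetnet_fit")
}

#' @export
print.hetnet_fit <- function(x, ...) {
  cat("<", x$model, " fit> ", sep = "")
  if (x$model == "power-law") cat("gamma = ", signif(x$exponent, 4), ", ", sep = "")
  cat("slope = ", signif(x$slope, 4), ", R^2 = ", signif(x$r_squared, 4),
      if (x$degenerate) " (degenerate)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.hetnet_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.hetnet_fit <- function(x, ...) {
  tibble::tibble(model = x$model, slope = x$slope, intercept = x$intercept,
                 exponent = x$exponent, r_squared = x$r_squared,
                 r_squared_raw = x$r_squared_raw, degenerate = x$degenerate,
                 n_points = x$n_points)
}

#' Classify a network as random, scale-free or hierarchical
#'
#' Implements the three-model decision rule over competing fits to the
#' degree distribution P(k) and the clustering distribution C(k):
#'
#' 1. If the power-law fit to P(k) does not beat the linear fit by at least
#'    `delta` in R-squared, the degree distribution carries no heavy-tail
#'    signal: **random**.
#' 2. Otherwise, if C(k) follows a power law with exponent within
#'    `gamma_tolerance` of -1 (C(k) ~ 1/k) at R-squared >=
#'    `ck_r2_threshold`: **hierarchical**.
#' 3. Otherwise: **scale-free**.
#'
#' @param x A `hetnet` object (distributions and all four fits are
#'   computed), or a `hetnet_profile`.
#' @param delta Required R-squared margin of the P(k) power-law fit over
#'   the linear fit (default 0.1).
#' @param gamma_tolerance Tolerance around exponent 1 for C(k) ~ k^-1
#'   (default 0.3).
#' @param ck_r2_threshold Minimum R-squared of the C(k) power-law fit for a
#'   hierarchical call (default 0.7).
#' @return A `hetnet_classification` object: `label` (`"random"`,
#'   `"scale-free"`, `"hierarchical"`, or `NA` when the P(k) fits are
#'   degenerate), plus the four `hetnet_fit`s as evidence. `tidy()` returns
#'   the model-comparison table of R-squared values.
#' @examples
#' classify_network(gen_scale_free(300, 2, seed = 1))
#' @export
classify_network <- function(x, delta = 0.1, gamma_tolerance = 0.3,
                             ck_r2_threshold = 0.7) {
  if (inherits(x, "hetnet_profile")) {
    pk <- x$degree_distribution
    ck <- x$clustering_distribution
  } else {
    g <- as_graph(x)
    pk <- degree_distribution(g)
    ck <- clustering_distribution(g)
  }
  fits <- list(
    pk_linear = try_fit(fit_linear, pk),
    pk_power = try_fit(fit_powerlaw, pk),
    ck_linear = try_fit(fit_linear, ck),
    ck_power = try_fit(fit_powerlaw, ck)
  )
  classify_from_fits(fits, delta = delta, gamma_tolerance = gamma_tolerance,
                     ck_r2_threshold = ck_r2_threshold)
}

try_fit <- function(f, d) {
  tryCatch(f(d), hetnet_fit_error = function(e) NULL)
}

#' Apply the classification rule to precomputed fits
#'
#' @param fits A named list with elements `pk_linear`, `pk_power`,
#'   `ck_linear`, `ck_power`. Each is a [fit_powerlaw()]/[fit_linear()]
#'   result (or any list with `r_squared`, `exponent`, `degenerate`
#'   fields); `ck_*` entries may be `NULL` when C(k) offers no support
#'   (e.g. a triangle-free graph), which rules out the hierarchical label.
#' @inheritParams classify_network
#' @return A `hetnet_classification` object.
#' @export
classify_from_fits <- function(fits, delta = 0.1, gamma_tolerance = 0.3,
                               ck_r2_threshold = 0.7) {
  pk_lin <- fits$pk_linear
  pk_pow <- fits$pk_power
  ck_pow <- fits$ck_power
  degenerate <- is.null(pk_lin) || is.null(pk_pow) ||
    isTRUE(pk_lin$degenerate) || isTRUE(pk_pow$degenerate)
  label <- if (degenerate) {
    NA_character_
  } else if (pk_pow$r_squared - pk_lin$r_squared < delta) {
    "random"
  } else if (!is.null(ck_pow) && !isTRUE(ck_pow$degenerate) &&
             abs(ck_pow$exponent - 1) <= gamma_tolerance &&
             ck_pow$r_squared >= ck_r2_threshold) {
    "hierarchical"
  } else {
    "scale-free"
  }
  structure(list(
    label = label,
    degenerate = degenerate,
    fits = fits,
    thresholds = list(delta = delta, gamma_tolerance = gamma_tolerance,
                      ck_r2_threshold = ck_r2_threshold)
  ), class = "hetnet_classification")
}

#' @export
print.hetnet_classification <- function(x, ...) {
  cat("<network classification> ",
      if (is.na(x$label)) "not classified (degenerate distribution)" else x$label,
      "\n", sep = "")
  print(as.data.frame(tidy(x)), row.names = FALSE)
  invisible(x)
}

#' Model-comparison table of a classification
#'
#' @param x A `hetnet_classification`.
#' @param ... Unused.
#' @return A tibble with one row per (distribution, model) fit: R-squared
#'   and, for power laws, the exponent.
#' @export
tidy.hetnet_classification <- function(x, ...) {
  rows <- purrr::imap(x$fits, function(f, nm) {
    if (is.null(f)) return(NULL)
    tibble::tibble(
      distribution = if (startsWith(nm, "pk")) "P(k)" else "C(k)",
      model = f$model,
      r_squared = f$r_squared,
      exponent = f$exponent %||% NA_real_,
      degenerate = f$degenerate
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
glance.hetnet_classification <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    pk_linear_r2 = x$fits$pk_linear$r_squared %||% NA_real_,
    pk_power_r2 = x$fits$pk_power$r_squared %||% NA_real_,
    ck_linear_r2 = x$fits$ck_linear$r_squared %||% NA_real_,
    ck_power_r2 = x$fits$ck_power$r_squared %||% NA_real_,
    pk_gamma = x$fits$pk_power$exponent %||% NA_real_,
    ck_gamma = x$fits$ck_power$exponent %||% NA_real_
  )
}
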