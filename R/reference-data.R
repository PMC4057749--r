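#' Published summary tables of the curated GPCR heteroreceptor network
#'
#' The curated GPCR heteroreceptor network (156 protomers, 260
#' experimentally supported heteromer pairs) was distributed as an online
#' resource; its full edge list is not redistributed here. What this
#' package ships are the *published summary tables*: the degrees of the 29
#' most-connected protomers (`gpcr_reference_degrees()`) and the reported
#' summary counts — family composition, intra-/interfamily edge partition,
#' disconnected and degree-1 protomer counts, clustered protomer count
#' (`gpcr_reference_counts()`). These serve as inputs for arithmetic
#' checks and as target constraints for [gen_hetnet_like()].
#'
#' @return `gpcr_reference_degrees()`: a tibble (`id`, `degree`), 29 rows,
#'   degrees 17 down to 6. `gpcr_reference_counts()`: a named integer
#'   vector of summary counts.
#' @examples
#' hubs_degree_threshold(gpcr_reference_degrees(), 5)
#' gpcr_reference_counts()[["protomers"]]
#' @export
gpcr_reference_degrees <- function() {
  path <- system.file("extdata", "gpcr_hetnet_hub_degrees.csv", package = "hetnet",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = "ci", progress = FALSE)
}

#' @rdname gpcr_reference_degrees
#' @export
gpcr_reference_counts <- function() {
  path <- system.file("extdata", "gpcr_hetnet_counts.csv", package = "hetnet",
                      mustWork = TRUE)
  tbl <- readr::read_csv(path, col_types = "ci", progress = FALSE)
  setNames(as.integer(tbl$value), tbl$quantity)
}
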