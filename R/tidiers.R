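#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a spike-in report
#'
#' @param x `scm_spikein_report`.
#' @param ... Unused.
#' @return Tibble with one row per control class and the rate as a
#'   percentage alongside the unit-interval estimate.
#' @export
tidy.scm_spikein_report <- function(x, ...) {
  as_tibble(x) |> mutate(rate_pct = 100 * .data$rate)
}

#' @rdname tidy.scm_spikein_report
#' @export
glance.scm_spikein_report <- function(x, ...) {
  tibble(n_classes = nrow(x), total_calls = sum(x$n_calls))
}

#' Tidy a clustering result
#'
#' @param x `scm_cluster`.
#' @param ... Unused.
#' @return Tibble with `cell`, `cluster`, `dim1`, `dim2`.
#' @export
tidy.scm_cluster <- function(x, ...) x$labels

#' @rdname tidy.scm_cluster
#' @export
glance.scm_cluster <- function(x, ...) {
  tibble(n_cells = nrow(x$labels),
         n_clusters = length(unique(x$labels$cluster)),
         n_pcs = x$params$n_pcs,
         method = x$params$method)
}

#' Tidy a marker table
#'
#' @param x `scm_markers`.
#' @param ... Unused.
#' @export
tidy.scm_markers <- function(x, ...) as_tibble(x)

#' @rdname tidy.scm_markers
#' @export
glance.scm_markers <- function(x, ...) {
  tibble(n_tested = sum(!is.na(x$p_adj)),
         n_selected = sum(x$selected),
         min_p_adj = suppressWarnings(min(x$p_adj, na.rm = TRUE)))
}
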