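#' Tidy a gene network into its edge table
#' @param x A [gene_network()].
#' @param ... Unused.
#' @return Tibble with columns `from`, `to`, `weight`.
#' @export
tidy.gene_network <- function(x, ...) x$edges

#' One-row network summary
#' @param x A [gene_network()].
#' @param ... Unused.
#' @return Tibble with `n_nodes`, `n_edges`, `n_candidates` (degree >=
#'   1), `mean_degree`, `mean_weight_sum` (both over candidates),
#'   `max_degree`.
#' @export
glance.gene_network <- function(x, ...) {
  cand <- node_candidates(x)
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_candidates = nrow(cand),
         mean_degree = if (nrow(cand) > 0) mean(cand$degree) else NA_real_,
         mean_weight_sum = if (nrow(cand) > 0) mean(cand$weight_sum)
           else NA_real_,
         max_degree = if (nrow(cand) > 0) max(cand$degree) else 0L)
}

#' Tidy a hub selection into its member table
#' @param x A `hub_selection`.
#' @param ... Unused.
#' @return The members tibble with `level` and the semicolon-joined
#'   neighbor sets.
#' @export
tidy.hub_selection <- function(x, ...) {
  x$members |>
    mutate(level = x$level,
           edges = vapply(.data$edges, paste, character(1),
                          collapse = ";"))
}

#' One-row hub-selection summary
#' @param x A `hub_selection`.
#' @param ... Unused.
#' @return Tibble with `level`, `n_members`, `cutoff_weight`,
#'   `cutoff_degree`, `mean_degree`, `degree_min`, `degree_max`.
#' @export
glance.hub_selection <- function(x, ...) {
  m <- x$members
  tibble(level = x$level, n_members = nrow(m),
         cutoff_weight = x$cutoff_weight,
         cutoff_degree = x$cutoff_degree,
         mean_degree = if (nrow(m) > 0) mean(m$degree) else NA_real_,
         degree_min = if (nrow(m) > 0) min(m$degree) else NA_integer_,
         degree_max = if (nrow(m) > 0) max(m$degree) else NA_integer_)
}

#' Tidy a scale-free fit into its degree-frequency table
#' @param x A `scale_free_fit`.
#' @param ... Unused.
#' @return Tibble `degree`, `n_nodes`, `log10_degree`, `log10_n_nodes`,
#'   `fitted`.
#' @export
tidy.scale_free_fit <- function(x, ...) {
  x$data |>
    mutate(log10_degree = log10(.data$degree),
           log10_n_nodes = log10(.data$n_nodes),
           fitted = x$intercept + x$slope * log10(.data$degree))
}

#' One-row scale-free fit summary
#' @param x A `scale_free_fit`.
#' @param ... Unused.
#' @return Tibble with `slope`, `intercept`, `r_squared`,
#'   `n_distinct_degrees`.
#' @export
glance.scale_free_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, n_distinct_degrees = nrow(x$data))
}
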