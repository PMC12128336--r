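#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a scale-free topology fit
#'
#' Log-log degree-frequency scatter with the fitted regression line and
#' the R-squared in the subtitle.
#'
#' @param object A `scale_free_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scale_free_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$log10_degree,
                                  .data$log10_n_nodes)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "log10 degree", y = "log10 number of nodes",
      title = paste0("Scale-free topology",
                     if (!is.null(object$group))
                       paste0(" (", object$group, ")")),
      subtitle = sprintf("slope = %.2f, R^2 = %.2f", object$slope,
                         object$r_squared))
}

#' Plot a connectivity-versus-penalty curve
#'
#' @param object A `connectivity_curve` from [connectivity_curve()].
#' @param lambda_used Optional penalty to mark with a vertical line
#'   (e.g. the analytic [mb_lambda()] value).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.connectivity_curve <- function(object, lambda_used = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$lambda,
                                            .data$n_edges)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "penalty lambda", y = "edges",
                  title = "Connectivity vs penalty")
  if (!is.null(lambda_used)) {
    p <- p + ggplot2::geom_vline(xintercept = as_lambda(lambda_used),
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Degree-distribution plot of a network
#'
#' @param network A [gene_network()].
#' @return A ggplot (bar chart of node counts per degree, degree >= 1).
#' @export
plot_degree_distribution <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  d <- node_candidates(network) |> count(.data$degree)
  ggplot2::ggplot(d, ggplot2::aes(.data$degree, .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "degree", y = "nodes",
                  title = paste0("Degree distribution",
                                 if (!is.null(network$group))
                                   paste0(" (", network$group, ")")))
}

#' Volcano-style DEG plot
#'
#' Log2 median difference (tumor minus normal) against -log10 p-value,
#' with selected genes highlighted.
#'
#' @param deg A [deg_table()].
#' @return A ggplot.
#' @export
plot_deg <- function(deg) {
  stopifnot(is.data.frame(deg),
            all(c("p_value", "selected", "log2_median_normal",
                  "log2_median_tumor") %in% names(deg)))
  d <- deg |>
    mutate(log2_diff = .data$log2_median_tumor -
             .data$log2_median_normal,
           neg_log10_p = -log10(pmax(.data$p_value, 1e-300)))
  ggplot2::ggplot(d, ggplot2::aes(.data$log2_diff, .data$neg_log10_p,
                                  colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 median difference (tumor - normal)",
                  y = "-log10 p", colour = "selected",
                  title = "Differential expression")
}
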