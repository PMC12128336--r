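#' Candidate hub genes of a network
#'
#' Every node with at least one edge, with its degree and edge-weight
#' sum.  Isolated nodes are excluded.
#'
#' @param network A [gene_network()].
#' @return A tibble with columns `gene`, `degree`, `weight_sum`, sorted
#'   by decreasing degree, then weight sum, then gene id.
#' @export
node_candidates <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  filter(network$nodes, .data$degree >= 1)
}

hub_edge_sets <- function(network, genes) {
  lapply(setNames(genes, genes), function(g) neighbors_of(network, g))
}

#' Select hub genes by weighted degree centrality
#'
#' Hub genes are the candidates (degree >= 1) whose edge-weight sum and
#' degree both reach their cutoffs.  By default each cutoff is the mean
#' of that statistic over all candidates, and the comparison is
#' inclusive (`>=`); `strict = TRUE` switches to `>`.  Explicit cutoffs
#' override the means.
#'
#' @param network A [gene_network()].
#' @param cutoff_weight,cutoff_degree Optional explicit cutoffs; `NULL`
#'   (default) uses the candidate means.
#' @param strict Use strict (`>`) instead of inclusive (`>=`)
#'   comparisons.
#' @return An object of class `hub_selection`: a list with `level`
#'   (`"hub"`), `members` (tibble `gene`, `degree`, `weight_sum`, `edges`
#'   list-column of neighbor sets), `cutoff_weight`, `cutoff_degree`,
#'   `strict` and `group`.  An empty selection is allowed.
#' @export
select_hubs <- function(network, cutoff_weight = NULL, cutoff_degree = NULL,
                        strict = FALSE) {
  stopifnot(inherits(network, "gene_network"))
  cand <- node_candidates(network)
  if (nrow(cand) == 0) abort("Network has no nodes with degree >= 1.")
  cutoff_weight <- cutoff_weight %||% mean(cand$weight_sum)
  cutoff_degree <- cutoff_degree %||% mean(cand$degree)
  keep <- if (strict) {
    cand$weight_sum > cutoff_weight & cand$degree > cutoff_degree
  } else {
    cand$weight_sum >= cutoff_weight & cand$degree >= cutoff_degree
  }
  members <- cand[keep, ]
  members$edges <- unname(hub_edge_sets(network, members$gene))
  structure(list(level = "hub", members = members,
                 cutoff_weight = cutoff_weight,
                 cutoff_degree = cutoff_degree,
                 strict = strict, group = network$group),
            class = "hub_selection")
}

## Placeholder selection for a network without connected nodes.
empty_hub_selection <- function(network, level = "hub") {
  structure(list(level = level,
                 members = tibble(gene = character(), degree = integer(),
                                  weight_sum = numeric(), edges = list()),
                 cutoff_weight = NA_real_, cutoff_degree = NA_real_,
                 strict = FALSE, group = network$group),
            class = "hub_selection")
}

#' @export
print.hub_selection <- function(x, ...) {
  cat("<hub_selection [", x$level,
      if (!is.null(x$group)) paste0(", ", x$group), "]> ",
      nrow(x$members), " members (cutoffs: weight ",
      signif(x$cutoff_weight, 4), ", degree ",
      signif(x$cutoff_degree, 4), ")\n", sep = "")
  invisible(x)
}

#' Gene ids of a hub selection
#' @param hubs A `hub_selection` (or a character vector, returned as is).
#' @return Character vector of member genes.
#' @export
hub_genes <- function(hubs) {
  if (is.character(hubs)) return(hubs)
  stopifnot(inherits(hubs, "hub_selection"))
  hubs$members$gene
}

#' Hub-of-hub extraction on the hub-induced subnetwork
#'
#' Induces the subnetwork on the hub genes only, recomputes degree and
#' weight sum within it, and keeps the hubs with induced degree >= 2 (a
#' gene connected to a single other hub is not itself a hub of hubs).
#' The same mean-based cutoff logic as [select_hubs()] is then applied
#' within the induced network to flag the `selected` top tier.
#'
#' @param network A [gene_network()].
#' @param hubs A `hub_selection` from [select_hubs()] (or a character
#'   vector of hub genes).
#' @inheritParams select_hubs
#' @return A `hub_selection` with `level = "hub_of_hub"`, `members`
#'   carrying induced statistics plus a logical `selected` column, and
#'   the induced `gene_network` in `$network`.
#' @export
hub_of_hub <- function(network, hubs, strict = FALSE) {
  stopifnot(inherits(network, "gene_network"))
  genes <- hub_genes(hubs)
  sub <- induce_subnetwork(network, genes)
  cand <- node_candidates(sub)
  members <- filter(cand, .data$degree >= 2)
  cutoff_weight <- if (nrow(cand) > 0) mean(cand$weight_sum) else NA_real_
  cutoff_degree <- if (nrow(cand) > 0) mean(cand$degree) else NA_real_
  members$selected <- if (strict) {
    members$weight_sum > cutoff_weight & members$degree > cutoff_degree
  } else {
    members$weight_sum >= cutoff_weight & members$degree >= cutoff_degree
  }
  members$edges <- unname(hub_edge_sets(sub, members$gene))
  structure(list(level = "hub_of_hub", members = members,
                 cutoff_weight = cutoff_weight,
                 cutoff_degree = cutoff_degree,
                 strict = strict, group = network$group, network = sub),
            class = "hub_selection")
}

#' Export a hub table as TSV
#'
#' Writes `gene`, `level`, `degree`, `weight_sum` and the semicolon-joined
#' neighbor set per hub.
#'
#' @param hubs A `hub_selection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hub_table <- function(hubs, path) {
  stopifnot(inherits(hubs, "hub_selection"))
  out <- hubs$members |>
    mutate(level = hubs$level,
           edges = vapply(.data$edges, paste, character(1),
                          collapse = ";")) |>
    select("gene", "level", "degree", "weight_sum", "edges")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Scale-free topology diagnostic
#'
#' Regresses `log10(number of nodes)` on `log10(degree)` over the raw
#' (unbinned) degree-frequency pairs of all degrees >= 1.  A strong
#' linear fit (R-squared near 1, negative slope) indicates an
#' approximately power-law degree distribution.
#'
#' @param network A [gene_network()].
#' @return An object of class `scale_free_fit` with fields `data`
#'   (tibble `degree`, `n_nodes`), `slope`, `intercept`, `r_squared`;
#'   or `NULL` with a warning when fewer than 3 distinct degrees are
#'   present.  A constant response (all frequencies equal) is reported
#'   as `slope = 0`, `r_squared = 0`.
#' @export
scale_free_fit <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  deg <- network$nodes$degree
  deg <- deg[deg >= 1]
  tab <- table(deg)
  if (length(tab) < 3) {
    warn("Fewer than 3 distinct degrees; scale-free fit refused.")
    return(NULL)
  }
  data <- tibble(degree = as.integer(names(tab)),
                 n_nodes = as.integer(tab))
  lx <- log10(data$degree)
  ly <- log10(data$n_nodes)
  if (stats::var(ly) == 0) {
    fit <- list(slope = 0, intercept = ly[1], r_squared = 0)
  } else {
    m <- lm(ly ~ lx)
    ## summary.lm warns on exact fits; an exact power law is legitimate here
    r2 <- suppressWarnings(summary(m)$r.squared)
    fit <- list(slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
                r_squared = r2)
  }
  structure(c(list(data = data), fit, list(group = network$group)),
            class = "scale_free_fit")
}

#' @export
print.scale_free_fit <- function(x, ...) {
  cat(sprintf("<scale_free_fit%s> slope = %.3f, R^2 = %.3f (%d degrees)\n",
              if (!is.null(x$group)) paste0(" [", x$group, "]") else "",
              x$slope, x$r_squared, nrow(x$data)))
  invisible(x)
}
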