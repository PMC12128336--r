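#' Construct an undirected weighted gene network
#'
#' @param edges Data frame with columns `from`, `to`, `weight`.  Endpoint
#'   order within a row is irrelevant; rows are canonicalized so that
#'   `from < to` lexicographically and sorted.  Duplicate pairs and
#'   self-loops are rejected.
#' @param genes Optional gene universe; endpoints not listed are added,
#'   listed genes without edges become isolated (degree-0) nodes.
#' @param group Optional group label (e.g. `"normal"`).
#' @return An object of class `gene_network`: a list with `edges` (tibble
#'   `from`, `to`, `weight`), `nodes` (tibble `gene`, `degree`,
#'   `weight_sum`, sorted by decreasing degree then weight), and `group`.
#' @examples
#' net <- gene_network(data.frame(from = c("A", "B"), to = c("B", "C"),
#'                                weight = c(0.2, 0.4)))
#' net$nodes
#' @export
gene_network <- function(edges, genes = NULL, group = NULL) {
  edges <- as_tibble(edges)
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  edges <- edges |>
    mutate(from = as.character(.data$from), to = as.character(.data$to))
  if (any(edges$from == edges$to)) abort("Self-loops are not allowed.")
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0)) {
    abort("Edge weights must be finite and nonnegative.")
  }
  edges <- edges |>
    mutate(a = pmin(.data$from, .data$to), b = pmax(.data$from, .data$to)) |>
    select(from = "a", to = "b", "weight") |>
    arrange(.data$from, .data$to)
  if (anyDuplicated(paste(edges$from, edges$to))) {
    abort("Duplicate edges are not allowed.")
  }
  genes <- sort(unique(c(genes, edges$from, edges$to)))
  ends <- c(edges$from, edges$to)
  w <- c(edges$weight, edges$weight)
  degree <- table(factor(ends, levels = genes))
  weight_sum <- vapply(split(w, factor(ends, levels = genes)),
                       function(v) sum(v), numeric(1))
  nodes <- tibble(gene = genes,
                  degree = as.integer(degree),
                  weight_sum = unname(weight_sum)) |>
    arrange(dplyr::desc(.data$degree), dplyr::desc(.data$weight_sum),
            .data$gene)
  structure(list(edges = edges, nodes = nodes, group = group),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("<gene_network", if (!is.null(x$group)) paste0(" [", x$group, "]"),
      "> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Neighbor set of a node
#' @param network A `gene_network`.
#' @param gene A gene id.
#' @return Sorted character vector of neighbors (empty if the gene is
#'   isolated or absent).
#' @export
neighbors_of <- function(network, gene) {
  stopifnot(inherits(network, "gene_network"))
  e <- network$edges
  sort(c(e$to[e$from == gene], e$from[e$to == gene]))
}

#' Induced subnetwork on a gene subset
#'
#' Keeps only the edges with both endpoints in `genes`; all of `genes`
#' present in the network remain as nodes (possibly isolated).
#'
#' @param network A `gene_network`.
#' @param genes Character vector of genes.
#' @return A `gene_network`.
#' @export
induce_subnetwork <- function(network, genes) {
  stopifnot(inherits(network, "gene_network"))
  genes <- intersect(network$nodes$gene, genes)
  e <- network$edges |>
    filter(.data$from %in% genes & .data$to %in% genes)
  gene_network(e, genes = genes, group = network$group)
}

#' Convert a gene network to an igraph object
#' @param network A `gene_network`.
#' @return An undirected `igraph` graph with a `weight` edge attribute;
#'   isolated nodes are preserved.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes["gene"])
}

#' Write a network to disk
#'
#' Formats: `"edgelist"` (TSV with columns `source`, `target`, `weight`,
#' `source < target`, rows sorted; isolated nodes are not representable),
#' `"graphml"` (keeps weights and isolated nodes), and `"sif"` (Simple
#' Interaction Format; weights are dropped, a format limitation, and
#' isolated nodes appear as single-column lines).
#'
#' @param network A `gene_network`.
#' @param path Output file path.
#' @param format One of `"edgelist"`, `"graphml"`, `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path,
                          format = c("edgelist", "graphml", "sif")) {
  stopifnot(inherits(network, "gene_network"))
  format <- match.arg(format)
  if (format == "edgelist") {
    out <- network$edges |>
      select(source = "from", target = "to", "weight")
    readr::write_tsv(out, path, progress = FALSE)
  } else if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  } else {
    e <- network$edges
    lines <- paste(e$from, "pp", e$to, sep = "\t")
    isolated <- setdiff(network$nodes$gene, c(e$from, e$to))
    writeLines(c(lines, isolated), path)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path Input file path.
#' @param format `"edgelist"` or `"graphml"` (SIF drops weights and is
#'   not read back).
#' @param group Optional group label for the result.
#' @return A `gene_network`.
#' @export
read_network <- function(path, format = c("edgelist", "graphml"),
                         group = NULL) {
  format <- match.arg(format)
  if (format == "edgelist") {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            source = readr::col_character(),
                            target = readr::col_character(),
                            weight = readr::col_double()))
    gene_network(df |> select(from = "source", to = "target", "weight"),
                 group = group)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    e <- igraph::as_data_frame(g, what = "edges")
    v <- igraph::as_data_frame(g, what = "vertices")
    ## igraph stores the id in `name`
    gene_network(tibble(from = e$from, to = e$to, weight = e$weight),
                 genes = v$name, group = group)
  }
}
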