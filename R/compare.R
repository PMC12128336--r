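#' Common and group-specific hubs
#'
#' Intersects two hub selections and reports the shared hubs, the hubs
#' specific to each group, and the share of each hub set that is common
#' (percentages rounded half-up to one decimal).
#'
#' @param hubs_a,hubs_b Two `hub_selection`s (or character vectors) over
#'   comparable gene universes.
#' @return An object of class `hub_comparison`: list with `common`,
#'   `only_a`, `only_b` (sorted character vectors), the group labels, and
#'   `pct_common_a`, `pct_common_b`.
#' @export
common_hubs <- function(hubs_a, hubs_b) {
  a <- hub_genes(hubs_a)
  b <- hub_genes(hubs_b)
  common <- sort(intersect(a, b))
  structure(list(common = common,
                 only_a = sort(setdiff(a, b)),
                 only_b = sort(setdiff(b, a)),
                 n_a = length(a), n_b = length(b),
                 group_a = if (inherits(hubs_a, "hub_selection"))
                   hubs_a$group else NULL,
                 group_b = if (inherits(hubs_b, "hub_selection"))
                   hubs_b$group else NULL,
                 pct_common_a = pct(length(common), length(a)),
                 pct_common_b = pct(length(common), length(b))),
            class = "hub_comparison")
}

#' @export
print.hub_comparison <- function(x, ...) {
  cat("<hub_comparison> ", length(x$common), " common hubs (",
      x$pct_common_a, "% of ", x$n_a, "; ", x$pct_common_b, "% of ",
      x$n_b, ")\n", sep = "")
  invisible(x)
}

#' Edges shared by common hubs across two networks
#'
#' For each common hub, the neighbors adjacent to it in **both**
#' networks.  The operation is symmetric in the two networks.
#'
#' @param network_a,network_b Two [gene_network()]s.
#' @param common Character vector of common hub genes (or a
#'   `hub_comparison`, whose `$common` is used).
#' @return A list with `per_hub` (tibble `gene`, `degree_a`, `degree_b`,
#'   `n_shared`, `shared` list-column), `n_with_shared` (hubs with >= 1
#'   shared edge), `pct_with_shared`, and `shared_range`
#'   (`c(min, max)` of `n_shared` among hubs with >= 1, or `c(0, 0)`).
#' @export
shared_edges <- function(network_a, network_b, common) {
  if (inherits(common, "hub_comparison")) common <- common$common
  stopifnot(is.character(common))
  per_hub <- tibble(gene = common) |>
    mutate(shared = unname(lapply(.data$gene, function(g) {
      intersect(neighbors_of(network_a, g), neighbors_of(network_b, g))
    })),
    degree_a = vapply(.data$gene, function(g)
      length(neighbors_of(network_a, g)), integer(1), USE.NAMES = FALSE),
    degree_b = vapply(.data$gene, function(g)
      length(neighbors_of(network_b, g)), integer(1), USE.NAMES = FALSE),
    n_shared = vapply(.data$shared, length, integer(1))) |>
    select("gene", "degree_a", "degree_b", "n_shared", "shared")
  with_shared <- per_hub$n_shared[per_hub$n_shared >= 1]
  list(per_hub = per_hub,
       n_with_shared = length(with_shared),
       pct_with_shared = if (nrow(per_hub) > 0)
         pct(length(with_shared), nrow(per_hub)) else NA_real_,
       shared_range = if (length(with_shared) > 0)
         range(with_shared) else c(0L, 0L))
}

#' Project one group's hubs into the other group's network
#'
#' Evaluates the hub genes selected in group A against the full network
#' of group B: which hubs retain at least one edge there ("identified"),
#' with what degrees, and how many of their B-neighbors coincide with
#' their own A-edge sets.
#'
#' @param hubs A `hub_selection` (its `members$edges` provide the home
#'   edge sets).
#' @param network The other group's [gene_network()].
#' @return A list with `per_hub` (tibble `gene`, `degree_own`,
#'   `degree_other`, `identified`, `n_shared_edges`, `shared` list) and a
#'   `summary` list: `n_hubs`, `n_identified`, `pct_identified`,
#'   `mean_degree_identified`, `degree_range` (among identified),
#'   `n_with_shared`, `pct_with_shared`, `shared_range`.
#' @export
project_hubs <- function(hubs, network) {
  stopifnot(inherits(hubs, "hub_selection"),
            inherits(network, "gene_network"))
  members <- hubs$members
  per_hub <- tibble(gene = members$gene,
                    degree_own = members$degree,
                    own_edges = members$edges) |>
    mutate(other_edges = unname(lapply(.data$gene, neighbors_of,
                                       network = network)),
           degree_other = vapply(.data$other_edges, length, integer(1)),
           identified = .data$degree_other >= 1,
           shared = Map(intersect, .data$own_edges, .data$other_edges),
           n_shared_edges = vapply(.data$shared, length, integer(1))) |>
    select("gene", "degree_own", "degree_other", "identified",
           "n_shared_edges", "shared")
  ident <- per_hub[per_hub$identified, ]
  with_shared <- per_hub$n_shared_edges[per_hub$n_shared_edges >= 1]
  summary <- list(
    n_hubs = nrow(per_hub),
    n_identified = nrow(ident),
    pct_identified = if (nrow(per_hub) > 0)
      pct(nrow(ident), nrow(per_hub)) else NA_real_,
    mean_degree_identified = if (nrow(ident) > 0)
      mean(ident$degree_other) else NA_real_,
    degree_range = if (nrow(ident) > 0)
      range(ident$degree_other) else c(0L, 0L),
    n_with_shared = length(with_shared),
    pct_with_shared = if (nrow(ident) > 0)
      pct(length(with_shared), nrow(ident)) else NA_real_,
    shared_range = if (length(with_shared) > 0)
      range(with_shared) else c(0L, 0L))
  list(per_hub = per_hub, summary = summary)
}

#' Intersect the DEG set with the two hub sets
#'
#' Computes the three-way Venn decomposition of the DEG-selected genes
#' and the two hub sets, splits each hub category by tumor-vs-normal
#' direction, and extracts the headline list: common hubs that are also
#' DEG-selected, with their directions.
#'
#' @param deg A DEG table from [deg_table()] (needs columns `gene`,
#'   `selected`, `direction`).
#' @param hubs_a,hubs_b Hub selections (or character vectors) of the two
#'   groups.
#' @return An object of class `deg_hub_intersection`: list with `venn`
#'   (tibble of the 7 region counts with gene lists), `categories`
#'   (tibble per hub category: `n_hubs`, `n_deg`, `n_up`, `n_down`,
#'   `n_tie`), and `highlighted` (tibble `gene`, `direction`, `p_value`
#'   if available).
#' @export
intersect_deg_hubs <- function(deg, hubs_a, hubs_b) {
  stopifnot(is.data.frame(deg),
            all(c("gene", "selected", "direction") %in% names(deg)))
  d <- deg$gene[deg$selected]
  a <- hub_genes(hubs_a)
  b <- hub_genes(hubs_b)
  region <- function(in_d, in_a, in_b) {
    u <- sort(unique(c(d, a, b)))
    keep <- (u %in% d) == in_d & (u %in% a) == in_a & (u %in% b) == in_b
    u[keep]
  }
  regions <- list(
    deg_only = region(TRUE, FALSE, FALSE),
    hubs_a_only = region(FALSE, TRUE, FALSE),
    hubs_b_only = region(FALSE, FALSE, TRUE),
    deg_and_a = region(TRUE, TRUE, FALSE),
    deg_and_b = region(TRUE, FALSE, TRUE),
    a_and_b = region(FALSE, TRUE, TRUE),
    center = region(TRUE, TRUE, TRUE))
  venn <- tibble(region = names(regions),
                 n = unname(vapply(regions, length, integer(1))),
                 genes = unname(regions))
  dir_of <- setNames(deg$direction, deg$gene)
  split_dirs <- function(genes) {
    in_deg <- intersect(genes, d)
    dirs <- dir_of[in_deg]
    tibble(n_hubs = length(genes), n_deg = length(in_deg),
           n_up = sum(dirs == "up"), n_down = sum(dirs == "down"),
           n_tie = sum(dirs == "tie"))
  }
  categories <- bind_rows(
    common = split_dirs(intersect(a, b)),
    only_a = split_dirs(setdiff(a, b)),
    only_b = split_dirs(setdiff(b, a)),
    .id = "category")
  hl_genes <- sort(intersect(intersect(a, b), d))
  highlighted <- deg[deg$gene %in% hl_genes,
                     intersect(c("gene", "direction", "p_value"),
                               names(deg))] |>
    arrange(.data$gene)
  structure(list(venn = venn, categories = categories,
                 highlighted = as_tibble(highlighted)),
            class = "deg_hub_intersection")
}

#' @export
print.deg_hub_intersection <- function(x, ...) {
  cat("<deg_hub_intersection>\n")
  print(select(x$venn, "region", "n"))
  cat("highlighted (common hubs in DEG set): ",
      paste(x$highlighted$gene, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Re-test differential expression over the hub-gene universe
#'
#' Reapplies the combined BH step-up / raw-p criterion with the multiple
#' testing burden `m` restricted to the union of the two hub sets.  Hub
#' genes can reach significance here even when they missed the cut in
#' the genome-wide pass, because the smaller universe loosens the BH
#' critical values.
#'
#' @param deg A DEG table covering (at least) all hub genes, with
#'   columns `gene` and `p_value`.
#' @inheritParams intersect_deg_hubs
#' @inheritParams bh_select
#' @return A [bh_select()] table over the hub union.
#' @export
retest_hub_significance <- function(deg, hubs_a, hubs_b,
                                    fdr_level = 0.001,
                                    raw_p_cutoff = 0.001) {
  union_genes <- sort(unique(c(hub_genes(hubs_a), hub_genes(hubs_b))))
  missing <- setdiff(union_genes, deg$gene)
  if (length(missing) > 0) {
    abort(paste0("Hub gene(s) absent from the DEG table: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  bh_select(deg[deg$gene %in% union_genes, c("gene", "p_value")],
            fdr_level = fdr_level, raw_p_cutoff = raw_p_cutoff)
}
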