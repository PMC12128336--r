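#' Pipeline configuration
#'
#' Validates and bundles every tunable of the analysis.  The resolved
#' configuration is echoed into the summary report of [run_pipeline()]
#' for provenance.
#'
#' @param fdr_level BH false-discovery-rate level `q`, in (0, 1].
#' @param raw_p_cutoff Raw p-value ceiling combined with the BH step-up
#'   selection.
#' @param alpha_mb Significance level of the analytic LASSO penalty.
#' @param symmetrization_rule `"OR"` or `"AND"`.
#' @param wilcoxon_variant `"signed_rank_paired"` or `"rank_sum"`.
#' @param zero_method Zero-difference convention of the paired test,
#'   `"pratt"` or `"wilcoxon"`.
#' @param zero_filter_fraction Maximum tolerated fraction of zero entries
#'   per gene.
#' @param hub_cutoff_override Optional named list
#'   `list(normal = c(weight, degree), tumor = c(weight, degree))` of
#'   explicit hub cutoffs replacing the candidate means.
#' @param network_genes Which genes enter network estimation: the
#'   DEG-selected set (`"deg"`, default) or all post-filter genes
#'   (`"filtered"`).  The analytic penalty is always calibrated on the
#'   post-filter gene count.
#' @param use_middle_rank Use [middle_rank_threshold()] instead of
#'   [bh_select()] for the DEG selection flag.
#' @param seed Integer seed recorded and applied by [run_pipeline()].
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(fdr_level = 0.001, raw_p_cutoff = 0.001,
                            alpha_mb = 0.1,
                            symmetrization_rule = c("OR", "AND"),
                            wilcoxon_variant = c("signed_rank_paired",
                                                 "rank_sum"),
                            zero_method = c("pratt", "wilcoxon"),
                            zero_filter_fraction = 0.5,
                            hub_cutoff_override = NULL,
                            network_genes = c("deg", "filtered"),
                            use_middle_rank = FALSE, seed = 1L) {
  in_unit <- function(x) is.numeric(x) && length(x) == 1 && x > 0 && x <= 1
  if (!in_unit(fdr_level)) abort("`fdr_level` must be in (0, 1].")
  if (!in_unit(raw_p_cutoff)) abort("`raw_p_cutoff` must be in (0, 1].")
  if (!is.numeric(alpha_mb) || alpha_mb <= 0) {
    abort("`alpha_mb` must be positive.")
  }
  if (!in_unit(zero_filter_fraction)) {
    abort("`zero_filter_fraction` must be in (0, 1].")
  }
  if (!is.null(hub_cutoff_override)) {
    ok <- is.list(hub_cutoff_override) &&
      all(names(hub_cutoff_override) %in% c("normal", "tumor")) &&
      all(vapply(hub_cutoff_override, length, integer(1)) == 2)
    if (!ok) {
      abort(paste0("`hub_cutoff_override` must be a named list of ",
                   "c(weight, degree) pairs for 'normal'/'tumor'."))
    }
  }
  structure(list(fdr_level = fdr_level, raw_p_cutoff = raw_p_cutoff,
                 alpha_mb = alpha_mb,
                 symmetrization_rule = match.arg(symmetrization_rule),
                 wilcoxon_variant = match.arg(wilcoxon_variant),
                 zero_method = match.arg(zero_method),
                 zero_filter_fraction = zero_filter_fraction,
                 hub_cutoff_override = hub_cutoff_override,
                 network_genes = match.arg(network_genes),
                 use_middle_rank = use_middle_rank,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full differential network analysis
#'
#' Chains the whole pipeline on a paired study: zero filtering, paired
#' Wilcoxon DEG selection, the analytic penalty, per-group network
#' estimation, hub and hub-of-hub extraction, scale-free diagnostics,
#' all cross-group comparisons, and the summary report.
#'
#' @param study An [expression_study()].
#' @param config A [pipeline_config()].
#' @return An object of class `hubnet_analysis`: a list with elements
#'   `filtered` (study after zero filtering), `deg` (DEG table),
#'   `lambda` ([mb_lambda()] object), `networks`, `hubs`, `hub_of_hubs`,
#'   `scale_free` (per-group lists with `$normal`/`$tumor`),
#'   `comparison`, `shared`, `projection` (`normal_in_tumor`,
#'   `tumor_in_normal`), `venn`, `hub_retest`, `report`, `config`.
#' @export
run_pipeline <- function(study, config = pipeline_config()) {
  stopifnot(inherits(study, "expression_study"),
            inherits(config, "pipeline_config"))
  set.seed(config$seed)
  filtered <- filter_zero_genes(study, config$zero_filter_fraction)
  deg <- deg_table(filtered, variant = config$wilcoxon_variant,
                   fdr_level = config$fdr_level,
                   raw_p_cutoff = config$raw_p_cutoff,
                   zero_method = config$zero_method)
  if (config$use_middle_rank) {
    retained <- middle_rank_threshold(deg[, c("gene", "p_value")],
                                      fdr_level = config$fdr_level)
    deg$selected <- deg$gene %in% retained
  }
  lambda <- mb_lambda(n_pairs(filtered), nrow(filtered$values),
                      config$alpha_mb)
  net_genes <- if (config$network_genes == "deg") {
    deg$gene[deg$selected]
  } else {
    gene_ids(filtered)
  }
  if (length(net_genes) < 2) {
    abort(paste0("Only ", length(net_genes), " gene(s) would enter ",
                 "network estimation; need >= 2. Consider ",
                 "network_genes = 'filtered'."))
  }
  networks <- lapply(c(normal = "normal", tumor = "tumor"), function(g) {
    estimate_network(filtered, g, genes = net_genes, lambda = lambda,
                     rule = config$symmetrization_rule)
  })
  hubs <- lapply(c(normal = "normal", tumor = "tumor"), function(g) {
    net <- networks[[g]]
    if (nrow(node_candidates(net)) == 0) {
      warn(paste0("The ", g, " network has no connected nodes at this ",
                  "penalty; hub set is empty."))
      return(empty_hub_selection(net))
    }
    ov <- config$hub_cutoff_override[[g]]
    select_hubs(net,
                cutoff_weight = if (!is.null(ov)) ov[1],
                cutoff_degree = if (!is.null(ov)) ov[2])
  })
  hub_of_hubs <- lapply(c(normal = "normal", tumor = "tumor"),
                        function(g) hub_of_hub(networks[[g]], hubs[[g]]))
  scale_free <- lapply(networks, function(net) {
    tryCatch(suppressWarnings(scale_free_fit(net)),
             error = function(e) NULL)
  })
  comparison <- common_hubs(hubs$normal, hubs$tumor)
  shared <- shared_edges(networks$normal, networks$tumor, comparison)
  projection <- list(
    normal_in_tumor = project_hubs(hubs$normal, networks$tumor),
    tumor_in_normal = project_hubs(hubs$tumor, networks$normal))
  venn <- intersect_deg_hubs(deg, hubs$normal, hubs$tumor)
  hub_retest <- retest_hub_significance(deg, hubs$normal, hubs$tumor,
                                        fdr_level = config$fdr_level,
                                        raw_p_cutoff = config$raw_p_cutoff)
  n_cand <- vapply(networks, function(n) nrow(node_candidates(n)),
                   numeric(1))
  n_hub <- vapply(hubs, function(h) nrow(h$members), numeric(1))
  report <- build_report(
    counts = list(
      genes_in = nrow(study$values),
      genes_after_filter = nrow(filtered$values),
      deg_selected = sum(deg$selected),
      network_genes = length(net_genes),
      candidates_normal = n_cand[["normal"]],
      candidates_tumor = n_cand[["tumor"]],
      hubs_normal = n_hub[["normal"]],
      hubs_tumor = n_hub[["tumor"]],
      hub_of_hubs_normal = nrow(hub_of_hubs$normal$members),
      hub_of_hubs_tumor = nrow(hub_of_hubs$tumor$members),
      common_hubs = length(comparison$common),
      common_hubs_in_deg = nrow(venn$highlighted),
      hubs_significant_retest = sum(hub_retest$selected)),
    ratios = list(
      hubs_normal = c(n_hub[["normal"]], n_cand[["normal"]]),
      hubs_tumor = c(n_hub[["tumor"]], n_cand[["tumor"]]),
      common_of_normal = c(length(comparison$common), n_hub[["normal"]]),
      common_of_tumor = c(length(comparison$common), n_hub[["tumor"]]),
      common_with_shared_edges = c(shared$n_with_shared,
                                   max(1, length(comparison$common)))),
    cutoffs = list(
      normal = c(weight = hubs$normal$cutoff_weight,
                 degree = hubs$normal$cutoff_degree),
      tumor = c(weight = hubs$tumor$cutoff_weight,
                degree = hubs$tumor$cutoff_degree)),
    lambda = lambda, config = config)
  structure(list(filtered = filtered, deg = deg, lambda = lambda,
                 networks = networks, hubs = hubs,
                 hub_of_hubs = hub_of_hubs, scale_free = scale_free,
                 comparison = comparison, shared = shared,
                 projection = projection, venn = venn,
                 hub_retest = hub_retest, report = report,
                 config = config),
            class = "hubnet_analysis")
}

#' @export
print.hubnet_analysis <- function(x, ...) {
  cat("<hubnet_analysis>\n")
  print(x$report)
  invisible(x)
}
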