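gene_universe <- function(p) {
  sprintf("g%0*d", nchar(p), seq_len(p))
}

#' Build a sparse precision matrix with a planted topology
#'
#' Constructs the adjacency of the requested topology, assigns each edge
#' a precision entry of +/- `magnitude` (random signs), sets the
#' diagonal to 1, and then boosts the whole diagonal uniformly by
#' exactly the amount needed to bring the smallest eigenvalue to 0.1,
#' guaranteeing positive definiteness while inflating the diagonal (and
#' hence attenuating the implied partial correlations) as little as
#' possible.
#'
#' @param p Number of genes.
#' @param topology One of `"chain"`, `"hub_star"`,
#'   `"preferential_attachment"`, `"erdos_renyi"`.
#' @param magnitude Absolute off-diagonal precision entry per edge.
#' @param density Edge probability (`erdos_renyi` only).
#' @param n_hubs Number of star centers (`hub_star`; default 10% of `p`,
#'   at least 2).  Every non-center gene attaches to one random center.
#' @param hub_centers Optional explicit center genes (`hub_star`),
#'   overriding `n_hubs`.
#' @param pa_m Edges added per step (`preferential_attachment`).
#' @param seed Optional RNG seed (local to this call).
#' @return An object of class `precision_truth`: list with `omega`
#'   (precision matrix with gene dimnames), `adjacency` (tibble `from`,
#'   `to`, with `from < to`), `hubs` (planted hub genes: the star
#'   centers, or nodes of planted degree >= 3 for other topologies),
#'   `topology`, `magnitude`, `min_eigenvalue`.
#' @export
make_precision <- function(p,
                           topology = c("chain", "hub_star",
                                        "preferential_attachment",
                                        "erdos_renyi"),
                           magnitude = 0.3, density = 0.02, n_hubs = NULL,
                           hub_centers = NULL, pa_m = 1, seed = NULL) {
  topology <- match.arg(topology)
  stopifnot(p >= 2)
  if (!is.numeric(magnitude) || magnitude <= 0) {
    abort("`magnitude` must be positive.")
  }
  if (!is.null(seed)) set.seed(seed)
  genes <- gene_universe(p)
  centers <- NULL
  edges <- switch(topology,
    chain = cbind(seq_len(p - 1), seq(2, p)),
    erdos_renyi = {
      if (density < 0 || density > 1) abort("`density` must be in [0, 1].")
      pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
      pairs[runif(nrow(pairs)) < density, , drop = FALSE]
    },
    preferential_attachment = {
      g <- igraph::sample_pa(p, power = 1, m = pa_m, directed = FALSE)
      el <- igraph::as_edgelist(g, names = FALSE)
      el[el[, 1] != el[, 2], , drop = FALSE]
    },
    hub_star = {
      if (is.null(hub_centers)) {
        n_hubs <- n_hubs %||% max(2L, round(0.1 * p))
        centers <- sort(sample.int(p, n_hubs))
      } else {
        centers <- sort(match(hub_centers, genes))
        if (anyNA(centers)) abort("`hub_centers` must be gene ids g...")
      }
      leaves <- setdiff(seq_len(p), centers)
      cbind(leaves,
            centers[sample.int(length(centers), length(leaves),
                               replace = TRUE)])
    })
  edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                        pmax(edges[, 1], edges[, 2])))
  omega <- matrix(0, p, p, dimnames = list(genes, genes))
  if (nrow(edges) > 0) {
    signs <- sample(c(-1, 1), nrow(edges), replace = TRUE)
    omega[edges] <- signs * magnitude
    omega[edges[, c(2, 1), drop = FALSE]] <- signs * magnitude
  }
  diag(omega) <- 1
  e0 <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (e0 < 0.1) diag(omega) <- 1 + (0.1 - e0)
  if (nrow(edges) > 0 && magnitude / diag(omega)[1] < 0.05) {
    abort(paste0("Infeasible magnitude/density: the diagonal boost ",
                 "needed for positive definiteness drives the implied ",
                 "partial correlations below 0.05. Use a smaller edge ",
                 "magnitude or a sparser topology."))
  }
  min_eig <- min(eigen(omega, symmetric = TRUE,
                       only.values = TRUE)$values)
  adjacency <- tibble(from = genes[edges[, 1]], to = genes[edges[, 2]]) |>
    arrange(.data$from, .data$to)
  deg <- table(factor(c(adjacency$from, adjacency$to), levels = genes))
  hubs <- if (topology == "hub_star") {
    genes[centers]
  } else {
    names(deg)[deg >= 3]
  }
  structure(list(omega = omega, adjacency = adjacency, hubs = hubs,
                 topology = topology, magnitude = magnitude,
                 min_eigenvalue = min_eig),
            class = "precision_truth")
}

#' @export
print.precision_truth <- function(x, ...) {
  cat("<precision_truth [", x$topology, "]> ", nrow(x$omega), " genes, ",
      nrow(x$adjacency), " edges, ", length(x$hubs),
      " planted hubs, min eigenvalue ", signif(x$min_eigenvalue, 3),
      "\n", sep = "")
  invisible(x)
}

#' Generate a paired two-group expression study from planted truths
#'
#' Draws, per patient, a scalar random effect shared by the patient's
#' normal and tumor samples, then a multivariate normal vector per group
#' with covariance equal to the inverse of that group's planted precision
#' matrix, all on the log2 scale on top of per-gene baselines.  Tumor
#' samples additionally receive the planted log2 shifts of the DE genes.
#' Values are mapped to a nonnegative expression-like scale by
#' `pmax(2^x - 1, 0)`.  Because the downstream tests are rank-based, the
#' transform does not affect the DEG stage except through the ties it
#' creates at zero.
#'
#' @param truth_normal,truth_tumor [make_precision()] objects over the
#'   same gene universe.
#' @param n_pairs Number of patients (one normal + one tumor sample
#'   each).
#' @param de Optional tibble with columns `gene`, `log2_shift` (positive
#'   = up in tumor).
#' @param baseline_range Per-gene log2 baselines are drawn uniformly from
#'   this range.
#' @param pair_sd Standard deviation of the shared patient effect on the
#'   log2 scale.
#' @param n_low_genes Number of genes forced to a low baseline
#'   (`low_baseline`) so that roughly half or more of their values floor
#'   at zero, to exercise zero filtering.
#' @param low_baseline Log2 baseline of the low-expression genes.
#' @param seed Optional RNG seed; the same seed reproduces the study
#'   bit for bit.
#' @return A list with `study` (an [expression_study()]) and `truth`
#'   (class `synthetic_truth`: the two precision truths, the `de` table
#'   with directions, `pair_sd`, `baselines`, `seed`).
#' @export
generate_paired_study <- function(truth_normal, truth_tumor, n_pairs,
                                  de = NULL, baseline_range = c(4, 12),
                                  pair_sd = 0.5, n_low_genes = 0,
                                  low_baseline = -1, seed = NULL) {
  stopifnot(inherits(truth_normal, "precision_truth"),
            inherits(truth_tumor, "precision_truth"))
  genes <- rownames(truth_normal$omega)
  if (!identical(genes, rownames(truth_tumor$omega))) {
    abort("The two precision truths must share one gene universe.")
  }
  p <- length(genes)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(de)) {
    de <- as_tibble(de)
    stopifnot(all(c("gene", "log2_shift") %in% names(de)))
    if (!all(de$gene %in% genes)) abort("DE genes must be in the universe.")
    de$direction <- ifelse(de$log2_shift > 0, "up",
                           ifelse(de$log2_shift < 0, "down", "tie"))
  } else {
    de <- tibble(gene = character(), log2_shift = numeric(),
                 direction = character())
  }
  baselines <- runif(p, baseline_range[1], baseline_range[2])
  names(baselines) <- genes
  if (n_low_genes > 0) {
    low <- sample(genes, n_low_genes)
    baselines[low] <- low_baseline
  }
  shift <- setNames(numeric(p), genes)
  shift[de$gene] <- de$log2_shift

  draw_group <- function(truth) {
    sigma <- chol2inv(chol(truth$omega))
    z <- matrix(rnorm(n_pairs * p), n_pairs, p)
    z %*% chol(sigma)
  }
  patient_effect <- rnorm(n_pairs, 0, pair_sd)
  xn <- draw_group(truth_normal)
  xt <- draw_group(truth_tumor)
  log2_normal <- sweep(xn, 2, baselines, "+") + patient_effect
  log2_tumor <- sweep(sweep(xt, 2, baselines + shift, "+"), 1,
                      patient_effect, "+")

  patients <- sprintf("P%0*d", nchar(n_pairs), seq_len(n_pairs))
  values <- cbind(t(pmax(2^log2_normal - 1, 0)),
                  t(pmax(2^log2_tumor - 1, 0)))
  rownames(values) <- genes
  colnames(values) <- c(paste0(patients, "-N"), paste0(patients, "-T"))
  samples <- tibble(sample_id = colnames(values),
                    patient_id = rep(patients, 2),
                    group = rep(c("normal", "tumor"), each = n_pairs))
  truth <- structure(list(normal = truth_normal, tumor = truth_tumor,
                          de = de, pair_sd = pair_sd,
                          baselines = baselines, seed = seed),
                     class = "synthetic_truth")
  list(study = expression_study(values, samples), truth = truth)
}

#' Simulate a study from a named preset
#'
#' Presets bundle the generator settings used throughout the package's
#' calibration and recovery experiments:
#' \describe{
#'   \item{`null`}{One shared Erdos-Renyi precision (mean planted degree
#'     2, magnitude 0.3) for both groups, no expression shifts: tumor and
#'     normal are exchangeable.}
#'   \item{`de_only`}{Same shared network, but 10% of genes receive a
#'     +/- 1.5 log2 shift (alternating signs).}
#'   \item{`rewire`}{Two hub-star networks (10% of genes are centers,
#'     magnitude 0.35) sharing 30% of their centers; no shifts.  Used for
#'     edge/hub recovery scoring.}
#'   \item{`paperlike`}{Independent preferential-attachment networks per
#'     group, 15% DE genes with log2 shifts of 1 to 2, and 5% of genes at
#'     a low baseline so that the zero filter has work to do.}
#' }
#'
#' @param preset Preset name.
#' @param p Number of genes.
#' @param n_pairs Number of patients.
#' @param seed RNG seed (drives topology sampling and data generation).
#' @param ... Passed on to [generate_paired_study()] (e.g. `pair_sd`).
#' @return As [generate_paired_study()]: list with `study` and `truth`.
#' @export
simulate_study <- function(preset = c("null", "de_only", "rewire",
                                      "paperlike"),
                           p = 100, n_pairs = 50, seed = 1, ...) {
  preset <- match.arg(preset)
  set.seed(seed)
  genes <- gene_universe(p)
  if (preset %in% c("null", "de_only")) {
    truth <- make_precision(p, "erdos_renyi", magnitude = 0.3,
                            density = min(1, 2 / (p - 1)))
    de <- NULL
    if (preset == "de_only") {
      n_de <- max(1L, round(0.1 * p))
      de_genes <- sort(sample(genes, n_de))
      de <- tibble(gene = de_genes,
                   log2_shift = 1.5 * rep_len(c(1, -1), n_de))
    }
    return(generate_paired_study(truth, truth, n_pairs, de = de,
                                 seed = NULL, ...))
  }
  if (preset == "rewire") {
    n_hubs <- max(2L, round(0.1 * p))
    n_shared <- round(0.3 * n_hubs)
    shared <- sample(genes, n_hubs + 2 * (n_hubs - n_shared))
    centers_n <- sort(c(shared[seq_len(n_shared)],
                        shared[n_shared + seq_len(n_hubs - n_shared)]))
    centers_t <- sort(c(shared[seq_len(n_shared)],
                        shared[n_hubs + seq_len(n_hubs - n_shared)]))
    truth_n <- make_precision(p, "hub_star", magnitude = 0.35,
                              hub_centers = centers_n)
    truth_t <- make_precision(p, "hub_star", magnitude = 0.35,
                              hub_centers = centers_t)
    return(generate_paired_study(truth_n, truth_t, n_pairs, de = NULL,
                                 seed = NULL, ...))
  }
  ## paperlike
  truth_n <- make_precision(p, "preferential_attachment", magnitude = 0.3)
  truth_t <- make_precision(p, "preferential_attachment", magnitude = 0.3)
  n_de <- max(1L, round(0.15 * p))
  de_genes <- sort(sample(genes, n_de))
  de <- tibble(gene = de_genes,
               log2_shift = sample(c(-1, 1), n_de, replace = TRUE) *
                 runif(n_de, 1, 2))
  generate_paired_study(truth_n, truth_t, n_pairs, de = de,
                        n_low_genes = max(1L, round(0.05 * p)),
                        seed = NULL, ...)
}

edge_keys <- function(x) {
  if (inherits(x, "gene_network")) x <- x$edges
  if (inherits(x, "precision_truth")) x <- x$adjacency
  stopifnot(is.data.frame(x), all(c("from", "to") %in% names(x)))
  unique(paste(pmin(x$from, x$to), pmax(x$from, x$to), sep = "\r"))
}

#' Score edge recovery against a planted truth
#'
#' Edge-set precision is `|est & true| / |est|` (1 when both sets are
#' empty, 0 when only the estimate is empty and the truth is not);
#' recall is `|est & true| / |true|`; F1 is their harmonic mean (0 when
#' both are 0).
#'
#' @param estimated A [gene_network()], [make_precision()] truth, or any
#'   data frame with `from`/`to` columns.
#' @param truth Same accepted types, the planted adjacency.
#' @return A one-row tibble: `n_estimated`, `n_true`, `n_shared`,
#'   `precision`, `recall`, `f1`.
#' @export
score_recovery <- function(estimated, truth) {
  est <- edge_keys(estimated)
  tru <- edge_keys(truth)
  shared <- length(intersect(est, tru))
  precision <- if (length(est) == 0) {
    if (length(tru) == 0) 1 else 0
  } else shared / length(est)
  recall <- if (length(tru) == 0) {
    if (length(est) == 0) 1 else 0
  } else shared / length(tru)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  tibble(n_estimated = length(est), n_true = length(tru),
         n_shared = shared, precision = precision, recall = recall,
         f1 = f1)
}
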