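#' Standardize a samples-by-genes matrix
#'
#' Centers every column to mean 0 and scales it to sample standard
#' deviation 1 (n - 1 denominator).  Zero-variance columns are removed
#' with a warning naming them, since they carry no correlation
#' information and would break the scaling.
#'
#' @param x Numeric matrix, observations in rows, genes in columns.
#' @return The standardized matrix (possibly with fewer columns).
#' @export
standardize_matrix <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  sds <- apply(x, 2, stats::sd)
  zero_var <- sds == 0 | !is.finite(sds)
  if (any(zero_var)) {
    warn(paste0("Removing ", sum(zero_var), " zero-variance gene(s): ",
                paste(head(colnames(x)[zero_var], 5), collapse = ", ")))
    x <- x[, !zero_var, drop = FALSE]
    sds <- sds[!zero_var]
  }
  if (ncol(x) == 0) abort("No genes left after removing zero variance.")
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Standardized expression matrix of one group
#'
#' Prepares one group's expression for network estimation: the values
#' are put on the `log2(x + 1)` scale (co-expression is modelled on the
#' log scale, where expression is approximately Gaussian), each sample's
#' mean log-expression over **all** genes of the study is subtracted
#' (removing sample-level offsets such as residual depth or
#' patient-specific shifts, which would otherwise act as a common factor
#' connecting every gene pair), and each gene is then standardized
#' within the group (mean 0, sample sd 1, n - 1 denominator).
#' Standardization is per group because the two group networks are
#' estimated independently.
#'
#' @inheritParams group_matrix
#' @param log2_transform Model co-expression on the `log2(x + 1)` scale
#'   (default) rather than the raw scale.
#' @param center_samples Remove each sample's mean log-expression
#'   (computed over all genes of the study, before any `genes` subset)
#'   prior to per-gene standardization.
#' @return Numeric matrix (patients x genes), standardized per column.
#' @export
standardize_group <- function(study, group = c("normal", "tumor"),
                              genes = NULL, log2_transform = TRUE,
                              center_samples = TRUE) {
  m <- group_matrix(study, group)
  if (log2_transform) m <- log2(m + 1)
  if (center_samples) m <- sweep(m, 2, colMeans(m))
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing) > 0) {
      abort(paste0("Gene(s) not in study: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    m <- m[genes, , drop = FALSE]
  }
  standardize_matrix(t(m))
}

soft_threshold <- function(x, lambda) {
  sign(x) * pmax(0, abs(x) - lambda)
}

## Cyclic coordinate descent for the LASSO in covariance form:
## minimize (1/(2n))||y - X b||^2 + lambda ||b||_1 given G = X'X/n and
## c0 = X'y/n.  Coordinates listed in `skip` are pinned at zero (used to
## exclude the response gene when G is the full gene-gene Gram matrix).
## Full sweeps alternate with active-set sweeps; convergence when a full
## sweep changes no coefficient by more than `tol`.
lasso_cov <- function(G, c0, lambda, tol = 1e-7, max_sweeps = 10000,
                      skip = integer(0), context = NULL) {
  p <- length(c0)
  beta <- numeric(p)
  dg <- diag(G)
  idx <- setdiff(seq_len(p), skip)
  sweeps <- 0
  overrun <- function() {
    abort(paste0("LASSO coordinate descent did not converge within ",
                 max_sweeps, " sweeps",
                 if (!is.null(context)) paste0(" (", context, ")"), "."))
  }
  update_one <- function(j) {
    act <- which(beta != 0)
    gb <- if (length(act) > 0) sum(G[j, act] * beta[act]) else 0
    r <- c0[j] - gb + dg[j] * beta[j]
    soft_threshold(r, lambda) / dg[j]
  }
  repeat {
    sweeps <- sweeps + 1
    if (sweeps > max_sweeps) overrun()
    dmax <- 0
    for (j in idx) {
      bn <- update_one(j)
      if (bn != beta[j]) {
        dmax <- max(dmax, abs(bn - beta[j]))
        beta[j] <- bn
      }
    }
    if (dmax < tol) break
    repeat {
      sweeps <- sweeps + 1
      if (sweeps > max_sweeps) overrun()
      active <- setdiff(which(beta != 0), skip)
      dmax_a <- 0
      for (j in active) {
        bn <- update_one(j)
        if (bn != beta[j]) {
          dmax_a <- max(dmax_a, abs(bn - beta[j]))
          beta[j] <- bn
        }
      }
      if (dmax_a < tol) break
    }
  }
  beta
}

#' Fit a single LASSO regression
#'
#' Minimizes \eqn{(1/(2n)) \lVert y - X\beta \rVert_2^2 +
#' \lambda \lVert \beta \rVert_1} without an intercept, by cyclic
#' coordinate descent with active-set passes.  The `1/(2n)` loss scaling
#' makes `lambda` directly comparable with [mb_lambda()].  Inputs are
#' expected standardized; the fit is deterministic given the column
#' order.
#'
#' @param y Response vector (length n).
#' @param x Predictor matrix (n x p).
#' @param lambda Penalty (a nonnegative number or an [mb_lambda()]
#'   object).
#' @param tol Convergence tolerance on the maximum coefficient change per
#'   sweep.
#' @param max_sweeps Sweep budget before a non-convergence error.
#' @return Named numeric vector of coefficients (names from
#'   `colnames(x)`).
#' @export
fit_lasso <- function(y, x, lambda, tol = 1e-7, max_sweeps = 10000) {
  stopifnot(is.numeric(y), is.matrix(x), length(y) == nrow(x))
  lambda <- as_lambda(lambda)
  n <- nrow(x)
  G <- crossprod(x) / n
  c0 <- drop(crossprod(x, y)) / n
  beta <- lasso_cov(G, c0, lambda, tol = tol, max_sweeps = max_sweeps)
  names(beta) <- colnames(x)
  beta
}

#' LASSO neighborhood selection over all genes
#'
#' Regresses every gene on all remaining genes at one shared penalty and
#' records the genes with nonzero coefficients as its probabilistic
#' neighbors.  Genes are processed in lexicographic order and the
#' gene-gene Gram matrix is computed once, so the result is deterministic
#' and independent of the input column order.
#'
#' @param x Standardized matrix (samples x genes) with gene column names,
#'   e.g. from [standardize_group()].
#' @param lambda Shared penalty (number or [mb_lambda()] object).
#' @inheritParams fit_lasso
#' @return A tibble with columns `gene`, `neighbor`, `coefficient` (one
#'   row per selected directed neighbor), carrying the full gene universe
#'   in `attr(, "genes")` and the penalty in `attr(, "lambda")`.
#' @export
estimate_neighborhoods <- function(x, lambda, tol = 1e-7,
                                   max_sweeps = 10000) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  lambda <- as_lambda(lambda)
  if (ncol(x) < 2) abort("Need at least 2 genes for neighborhood selection.")
  genes <- sort(colnames(x))
  x <- x[, genes, drop = FALSE]
  n <- nrow(x)
  G <- crossprod(x) / n
  rows <- vector("list", length(genes))
  for (j in seq_along(genes)) {
    beta <- lasso_cov(G, G[, j], lambda, tol = tol,
                      max_sweeps = max_sweeps, skip = j,
                      context = paste0("gene ", genes[j]))
    nz <- which(beta != 0)
    if (length(nz) > 0) {
      rows[[j]] <- tibble(gene = genes[j], neighbor = genes[nz],
                          coefficient = beta[nz])
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(gene = character(), neighbor = character(),
                  coefficient = numeric())
  }
  attr(out, "genes") <- genes
  attr(out, "lambda") <- lambda
  out
}

#' Symmetrize directed neighborhoods into an undirected network
#'
#' Under the `OR` rule an edge joins genes i and j when either selected
#' the other; under `AND` both directed selections are required.  The
#' edge weight is the mean of the available absolute coefficients (one or
#' two values).
#'
#' @param neighborhoods Output of [estimate_neighborhoods()].
#' @param rule `"OR"` (default) or `"AND"`.
#' @param genes Gene universe for the node set; defaults to
#'   `attr(neighborhoods, "genes")`.  Genes without edges appear as
#'   isolated nodes.
#' @param group Optional group label stored on the network.
#' @return A [gene_network()].
#' @export
symmetrize <- function(neighborhoods, rule = c("OR", "AND"), genes = NULL,
                       group = NULL) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(neighborhoods),
            all(c("gene", "neighbor", "coefficient") %in%
                  names(neighborhoods)))
  genes <- genes %||% attr(neighborhoods, "genes") %||%
    sort(unique(c(neighborhoods$gene, neighborhoods$neighbor)))
  edges <- neighborhoods |>
    mutate(from = pmin(.data$gene, .data$neighbor),
           to = pmax(.data$gene, .data$neighbor)) |>
    group_by(.data$from, .data$to) |>
    summarise(weight = mean(abs(.data$coefficient)),
              n_directions = dplyr::n(), .groups = "drop")
  if (rule == "AND") edges <- filter(edges, .data$n_directions == 2)
  gene_network(select(edges, "from", "to", "weight"), genes = genes,
               group = group)
}

#' Edge count as a function of the penalty
#'
#' Re-estimates the neighborhood network (OR rule) over a grid of
#' penalties and reports the number of undirected edges at each, the
#' diagnostic used to judge whether the analytic penalty yields a
#' reasonable connectivity.  Counts are nonincreasing in `lambda` up to
#' solver tolerance.
#'
#' @inheritParams estimate_neighborhoods
#' @param lambda_grid Numeric vector (length >= 2) of penalties.
#' @return A tibble of class `connectivity_curve` with columns `lambda`
#'   and `n_edges`, sorted by `lambda`.
#' @export
connectivity_curve <- function(x, lambda_grid, tol = 1e-7,
                               max_sweeps = 10000) {
  stopifnot(is.numeric(lambda_grid), length(lambda_grid) >= 2,
            all(lambda_grid >= 0))
  lambda_grid <- sort(unique(lambda_grid))
  n_edges <- vapply(lambda_grid, function(l) {
    nb <- estimate_neighborhoods(x, l, tol = tol, max_sweeps = max_sweeps)
    net <- symmetrize(nb, rule = "OR")
    nrow(net$edges)
  }, numeric(1))
  out <- tibble(lambda = lambda_grid, n_edges = as.integer(n_edges))
  class(out) <- c("connectivity_curve", class(out))
  out
}

#' Estimate one group's gene network
#'
#' Standardizes the group's expression, runs neighborhood selection at
#' the given (or analytic) penalty, and symmetrizes.
#'
#' @inheritParams standardize_group
#' @param lambda Penalty; `NULL` computes [mb_lambda()] from the group
#'   sample size, the number of genes entering the regression, and
#'   `alpha`.
#' @param alpha Significance level for the analytic penalty when
#'   `lambda` is `NULL`.
#' @param rule Symmetrization rule, `"OR"` or `"AND"`.
#' @inheritParams fit_lasso
#' @return A [gene_network()] labelled with the group.
#' @export
estimate_network <- function(study, group = c("normal", "tumor"),
                             genes = NULL, lambda = NULL, alpha = 0.1,
                             rule = c("OR", "AND"), tol = 1e-7,
                             max_sweeps = 10000, log2_transform = TRUE,
                             center_samples = TRUE) {
  group <- match.arg(group)
  x <- standardize_group(study, group, genes,
                         log2_transform = log2_transform,
                         center_samples = center_samples)
  if (is.null(lambda)) lambda <- mb_lambda(nrow(x), ncol(x), alpha)
  nb <- estimate_neighborhoods(x, lambda, tol = tol,
                               max_sweeps = max_sweeps)
  symmetrize(nb, rule = match.arg(rule), group = group)
}
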