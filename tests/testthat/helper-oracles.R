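# Independent reference implementations used as oracles.  These stay
# deliberately naive (enumeration / brute force) and share no code with
# the package internals they check.

# Two-sided paired signed-rank p-value by full enumeration of all 2^m
# sign assignments (Pratt zero handling: rank |d| with zeros included,
# drop the zero ranks).
oracle_signed_rank <- function(d) {
  nonzero <- d != 0
  if (!any(nonzero)) return(1)
  r_all <- rank(abs(d))
  r <- r_all[nonzero]
  w_obs <- sum(r[d[nonzero] > 0])
  m <- length(r)
  s <- sum(r)
  w_all <- vapply(0:(2^m - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0])
  }, numeric(1))
  mean(abs(w_all - s / 2) >= abs(w_obs - s / 2) - 1e-9)
}

# BH step-up by exhaustive threshold search: among all candidate
# rejection sets {p <= t}, keep the largest whose size k satisfies
# t <= (k / m) * q for some achievable t.
oracle_bh_selected <- function(p, q, raw_cutoff = 1) {
  m <- length(p)
  if (m == 0) return(logical(0))
  best <- 0
  for (t in sort(unique(p))) {
    k <- sum(p <= t)
    if (t <= k / m * q) best <- max(best, k)
  }
  ord <- order(p)
  sel <- logical(m)
  if (best > 0) sel[ord[seq_len(best)]] <- TRUE
  sel & p <= raw_cutoff
}

soft <- function(x, l) sign(x) * pmax(0, abs(x) - l)

# Random matrix whose columns satisfy the x'x / n = 1 convention.
unit_norm_columns <- function(n, p) {
  x <- matrix(rnorm(n * p), n, p)
  x <- sweep(x, 2, colMeans(x))
  x <- sweep(x, 2, sqrt(colSums(x^2) / n), "/")
  colnames(x) <- sprintf("v%02d", seq_len(p))
  x
}

# Matrix with exactly orthonormal columns in the X'X / n = I sense.
orthonormal_design <- function(n, p) {
  q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  x <- q * sqrt(n)
  colnames(x) <- sprintf("v%02d", seq_len(p))
  x
}

# Build an expression_study directly from per-group matrices
# (genes x patients), bypassing file IO.
study_from_groups <- function(normal, tumor) {
  p <- nrow(normal)
  n <- ncol(normal)
  genes <- rownames(normal) %||% sprintf("g%02d", seq_len(p))
  patients <- sprintf("P%02d", seq_len(n))
  values <- cbind(normal, tumor)
  rownames(values) <- genes
  colnames(values) <- c(paste0(patients, "-N"), paste0(patients, "-T"))
  samples <- tibble::tibble(
    sample_id = colnames(values),
    patient_id = rep(patients, 2),
    group = rep(c("normal", "tumor"), each = n))
  expression_study(values, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_study <- function() {
  normal <- matrix(c(10, 12, 5, 6, 100, 90), nrow = 3, byrow = TRUE,
                   dimnames = list(c("gA", "gB", "gC"), NULL))
  tumor <- matrix(c(20, 25, 2, 3, 80, 70), nrow = 3, byrow = TRUE,
                  dimnames = list(c("gA", "gB", "gC"), NULL))
  study_from_groups(normal, tumor)
}

# A gene_network realizing a prescribed degree sequence (deterministic).
network_from_degrees <- function(degrees) {
  g <- igraph::realize_degseq(degrees)
  el <- igraph::as_edgelist(g, names = FALSE)
  genes <- sprintf("n%03d", seq_along(degrees))
  gene_network(tibble::tibble(from = genes[el[, 1]], to = genes[el[, 2]],
                              weight = 1),
               genes = genes)
}

# Random weighted network on `p` nodes (for IO round trips etc.).
random_network <- function(p, density = 0.15) {
  genes <- sprintf("n%03d", seq_len(p))
  pairs <- t(combn(genes, 2))
  keep <- runif(nrow(pairs)) < density
  gene_network(tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2],
                              weight = runif(sum(keep))),
               genes = genes)
}
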