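test_that("standardization hits its postconditions and is idempotent", {
  set.seed(20)
  x <- matrix(rlnorm(200), 20, 10,
              dimnames = list(NULL, sprintf("g%02d", 1:10)))
  s <- standardize_matrix(x)
  expect_lt(max(abs(colMeans(s))), 1e-12)
  expect_lt(max(abs(apply(s, 2, sd) - 1)), 1e-12)
  expect_equal(unclass(standardize_matrix(s))[, ],
               unclass(s)[, ], tolerance = 1e-12)

  # constant gene removed with warning
  x[, 3] <- 7
  expect_warning(s2 <- standardize_matrix(x), "g03")
  expect_equal(ncol(s2), 9)
})

test_that("univariate fit equals the soft-threshold closed form", {
  set.seed(21)
  n <- 50
  x <- unit_norm_columns(n, 1)
  resid <- rnorm(n)
  resid <- resid - x %*% crossprod(x, resid) / n   # orthogonal to x
  for (r in c(0.9, 0.5, -0.7)) {
    y <- drop(r * x + resid * 0.1)
    y <- y - mean(y)
    stopifnot(abs(crossprod(x, y) / n - r) < 1e-9)
    expect_equal(unname(fit_lasso(y, x, 0.889165)),
                 unname(soft(r, 0.889165)), tolerance = 1e-9)
  }
  # the printed-penalty case: r = 0.9 leaves beta = 0.010835
  y <- drop(0.9 * x)
  expect_equal(unname(fit_lasso(y, x, 0.889165)), 0.010835,
               tolerance = 1e-9)
})

test_that("penalty at or above max |x_j'y / n| zeroes every coefficient", {
  set.seed(22)
  x <- unit_norm_columns(40, 6)
  y <- rnorm(40)
  lam_max <- max(abs(crossprod(x, y) / 40))
  expect_true(all(fit_lasso(y, x, lam_max) == 0))
  expect_true(all(fit_lasso(y, x, lam_max * 2) == 0))
})

test_that("lambda = 0 on full-rank n > p designs recovers OLS", {
  set.seed(23)
  for (i in 1:5) {
    n <- 60; p <- 5
    x <- matrix(rnorm(n * p), n, p) %*%
      chol(0.5 * diag(p) + 0.5)          # correlated design
    x <- scale(x)
    colnames(x) <- sprintf("v%d", 1:p)
    y <- drop(scale(x %*% rnorm(p) + rnorm(n)))
    ols <- solve(crossprod(x), crossprod(x, y))
    expect_equal(unname(fit_lasso(y, x, 0, tol = 1e-10)),
                 unname(drop(ols)), tolerance = 1e-6)
  }
})

test_that("orthonormal designs solve in closed form to 1e-8", {
  set.seed(24)
  for (i in 1:10) {
    n <- 40; p <- sample(2:5, 1)
    x <- orthonormal_design(n, p)
    y <- rnorm(n)
    lam <- runif(1, 0.05, 0.5)
    want <- unname(soft(drop(crossprod(x, y) / n), lam))
    expect_equal(unname(fit_lasso(y, x, lam, tol = 1e-12)), want,
                 tolerance = 1e-8)
  }
})

test_that("coordinate descent agrees with glmnet on general designs", {
  skip_if_not_installed("glmnet")
  set.seed(25)
  n <- 80; p <- 12
  x <- scale(matrix(rnorm(n * p), n, p) %*% chol(0.6 * diag(p) + 0.4))
  colnames(x) <- sprintf("v%02d", 1:p)
  y <- drop(scale(x[, 1] * 0.5 - x[, 2] * 0.3 + rnorm(n)))
  for (lam in c(0.05, 0.15, 0.4)) {
    ours <- fit_lasso(y, x, lam, tol = 1e-10)
    ref <- glmnet::glmnet(x, y, lambda = lam, standardize = FALSE,
                          intercept = FALSE, thresh = 1e-14)
    expect_equal(unname(ours), unname(drop(as.matrix(ref$beta))),
                 tolerance = 1e-5)
  }
})

test_that("two perfectly correlated genes select each other", {
  set.seed(26)
  v <- scale(rnorm(30))[, 1]
  x <- cbind(gA = v, gB = v)
  nb <- estimate_neighborhoods(x, 0.3)
  expect_equal(nb$gene, c("gA", "gB"))
  expect_equal(nb$neighbor, c("gB", "gA"))
  expect_true(all(nb$coefficient > 0))
})

test_that("independent genes stay unconnected at the analytic penalty", {
  lam <- mb_lambda(500, 3, 0.1)
  n_edges <- vapply(1:200, function(s) {
    set.seed(s)
    x <- standardize_matrix(matrix(rnorm(500 * 3), 500, 3,
                                   dimnames = list(NULL, c("a", "b", "c"))))
    nrow(symmetrize(estimate_neighborhoods(x, lam))$edges)
  }, numeric(1))
  # mean false-edge count consistent with the alpha = 0.1 calibration
  expect_lte(mean(n_edges), 0.1 + 3 * sqrt(0.1 / 200))
})

test_that("a planted chain is recovered exactly at the interior", {
  set.seed(27)
  truth <- make_precision(20, "chain", magnitude = 0.4)
  sigma <- chol2inv(chol(truth$omega))
  x <- matrix(rnorm(400 * 20), 400, 20) %*% chol(sigma)
  colnames(x) <- rownames(truth$omega)
  nb <- estimate_neighborhoods(standardize_matrix(x),
                               mb_lambda(400, 20, 0.1))
  genes <- rownames(truth$omega)
  for (i in 2:19) {
    got <- sort(nb$neighbor[nb$gene == genes[i]])
    expect_identical(got, sort(genes[c(i - 1, i + 1)]),
                     info = genes[i])
  }
})

test_that("symmetrization rules and weights follow their contracts", {
  nb <- tibble::tibble(gene = "A", neighbor = "B", coefficient = -0.2)
  attr(nb, "genes") <- c("A", "B")
  or_net <- symmetrize(nb, "OR")
  and_net <- symmetrize(nb, "AND")
  expect_equal(nrow(or_net$edges), 1)
  expect_equal(or_net$edges$weight, 0.2)
  expect_equal(nrow(and_net$edges), 0)

  # reciprocal selections average their absolute coefficients
  nb2 <- tibble::tibble(gene = c("A", "B"), neighbor = c("B", "A"),
                        coefficient = c(0.2, -0.4))
  expect_equal(symmetrize(nb2, "OR")$edges$weight, 0.3)
  expect_equal(symmetrize(nb2, "AND")$edges$weight, 0.3)
})

test_that("OR edges always contain AND edges", {
  set.seed(28)
  sim <- simulate_study("rewire", p = 30, n_pairs = 60, seed = 4)
  x <- standardize_group(sim$study, "normal")
  nb <- estimate_neighborhoods(x, mb_lambda(60, 30, 0.1))
  or_keys <- paste(symmetrize(nb, "OR")$edges$from,
                   symmetrize(nb, "OR")$edges$to)
  and_keys <- paste(symmetrize(nb, "AND")$edges$from,
                    symmetrize(nb, "AND")$edges$to)
  expect_true(all(and_keys %in% or_keys))
})

test_that("estimation is invariant to gene input order", {
  set.seed(29)
  sim <- simulate_study("rewire", p = 25, n_pairs = 80, seed = 9)
  x <- standardize_group(sim$study, "tumor")
  net1 <- symmetrize(estimate_neighborhoods(x, 0.25))
  perm <- sample(ncol(x))
  net2 <- symmetrize(estimate_neighborhoods(x[, perm], 0.25))
  expect_equal(net1$edges, net2$edges, tolerance = 1e-8)
})

test_that("connectivity decreases with the penalty, with known endpoints", {
  set.seed(30)
  x <- matrix(rnorm(60 * 8), 60, 8) %*% chol(0.55 * diag(8) + 0.45)
  colnames(x) <- sprintf("g%d", 1:8)
  x <- standardize_matrix(x)
  curve <- connectivity_curve(x, c(2, 0.6, 0.3, 0.15, 0.05, 0))
  expect_equal(curve$lambda, sort(curve$lambda))
  expect_true(all(diff(curve$n_edges) <= 0))
  expect_equal(curve$n_edges[curve$lambda == 2], 0)       # lambda -> large
  expect_equal(curve$n_edges[curve$lambda == 0], 8 * 7 / 2) # OLS limit
})

test_that("edge recall improves with sample size on a planted graph", {
  truth <- make_precision(20, "hub_star", magnitude = 0.35, n_hubs = 2,
                          seed = 33)
  recall_at <- function(n_pairs, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- generate_paired_study(truth, truth, n_pairs, seed = s)
      net <- estimate_network(sim$study, "normal",
                              lambda = mb_lambda(n_pairs, 20, 0.1))
      score_recovery(net, truth)$recall
    }, numeric(1)))
  }
  seeds <- 1:20
  expect_gte(recall_at(400, seeds), recall_at(100, seeds))
})
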