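test_that("zero filter keeps genes at exactly half zeros and drops beyond", {
  normal <- rbind(gA = c(0, 0), gB = c(0, 5), gC = c(1, 2))
  tumor <- rbind(gA = c(0, 3), gB = c(0, 6), gC = c(3, 4))
  study <- study_from_groups(normal, tumor)
  # gA: zeros in 3 of 4 samples -> removed; gB: 2 of 4 -> kept
  kept <- filter_zero_genes(study, 0.5)
  expect_identical(gene_ids(kept), c("gB", "gC"))
  expect_error(filter_zero_genes(subset_genes(study, "gA"), 0.25),
               "All genes removed")
})

test_that("zero filter matches a brute-force recount on random matrices", {
  set.seed(101)
  for (rep in 1:5) {
    vals <- matrix(rpois(100 * 10, 2), 100, 10)
    vals[runif(length(vals)) < 0.3] <- 0
    rownames(vals) <- sprintf("g%03d", 1:100)
    study <- study_from_groups(vals[, 1:5], vals[, 6:10])
    frac <- sample(c(0.3, 0.5, 0.8), 1)
    kept <- tryCatch(gene_ids(filter_zero_genes(study, frac)),
                     error = function(e) character())
    manual <- rownames(vals)[vapply(seq_len(nrow(vals)), function(i) {
      sum(vals[i, ] == 0) <= frac * 10
    }, logical(1))]
    expect_identical(kept, manual)
  }
})

test_that("paired signed-rank p-values match spec'd exact cases", {
  set.seed(5)
  normal <- matrix(runif(5, 10, 20), nrow = 1,
                   dimnames = list("gA", NULL))
  study <- study_from_groups(normal, normal + 1)
  # all five differences positive: most extreme of 2^5 assignments
  expect_equal(wilcoxon_test(study)$p_value, 2 / 32)

  # tumor identical to normal: every difference zero, p = 1
  study2 <- study_from_groups(normal, normal)
  expect_equal(wilcoxon_test(study2)$p_value, 1)

  # a constant gene is flagged with a warning, not an error
  const <- study_from_groups(matrix(5, 1, 5, dimnames = list("gK", NULL)),
                             matrix(5, 1, 5, dimnames = list("gK", NULL)))
  expect_warning(p3 <- wilcoxon_test(const), "identical")
  expect_equal(p3$p_value, 1)
})

test_that("rank-sum p-values are invariant under monotone transforms", {
  set.seed(6)
  normal <- matrix(rlnorm(40, 3), nrow = 4,
                   dimnames = list(paste0("g", 1:4), NULL))
  tumor <- normal * matrix(rlnorm(40, 0, 0.5), nrow = 4)
  study <- study_from_groups(normal, tumor)
  study_log <- study_from_groups(log2(normal + 1), log2(tumor + 1))
  expect_equal(wilcoxon_test(study, "rank_sum")$p_value,
               wilcoxon_test(study_log, "rank_sum")$p_value)
  # the paired variant ranks difference magnitudes, so only transforms
  # that preserve them (e.g. rescaling) leave its p-values unchanged
  study_scaled <- study_from_groups(normal * 3, tumor * 3)
  expect_equal(wilcoxon_test(study)$p_value,
               wilcoxon_test(study_scaled)$p_value)
})

test_that("exact signed-rank p equals full 2^n enumeration for n <= 8", {
  set.seed(7)
  cases <- c(
    lapply(1:12, function(i) rnorm(sample(3:8, 1))),          # generic
    lapply(1:6, function(i) round(rnorm(sample(4:8, 1)) * 2) / 2), # ties
    list(c(0, 0, 1, -2, 3), c(1, 1, -1, -1, 2, 2), c(0, 1)))  # zeros
  for (d in cases) {
    expect_equal(hubnetdiff:::signed_rank_p(d), oracle_signed_rank(d),
                 info = paste(d, collapse = ","))
  }
})

test_that("exact signed-rank agrees with wilcox.test absent ties/zeros", {
  set.seed(8)
  for (i in 1:10) {
    d <- rnorm(sample(5:12, 1))
    expect_equal(hubnetdiff:::signed_rank_p(d),
                 stats::wilcox.test(d, exact = TRUE)$p.value)
  }
})

test_that("normal approximation tracks the exact tail for larger n", {
  set.seed(9)
  d <- rnorm(30) + 0.3
  p_exact <- hubnetdiff:::signed_rank_p(d, exact_max_n = 40)
  p_approx <- hubnetdiff:::signed_rank_p(d, exact_max_n = 25)
  expect_lt(abs(p_exact - p_approx) / p_exact, 0.05)
  set.seed(16)
  d2 <- rnorm(40) * 2
  expect_lt(abs(hubnetdiff:::signed_rank_p(d2, exact_max_n = 50) -
                  hubnetdiff:::signed_rank_p(d2, exact_max_n = 25)) /
              hubnetdiff:::signed_rank_p(d2, exact_max_n = 50), 0.05)
})

test_that("bh_select implements the step-up rule with a raw-p guard", {
  d <- tibble::tibble(gene = paste0("g", 1:4),
                      p_value = c(1e-4, 5e-4, 2e-3, 0.5))
  out <- bh_select(d, fdr_level = 0.001, raw_p_cutoff = 0.001)
  expect_equal(sum(out$selected), 2)
  expect_equal(out$gene[out$selected], c("g1", "g2"))
  expect_equal(out$bh_critical, (1:4) / 4 * 0.001)

  # all p = 1: nothing selected
  all1 <- tibble::tibble(gene = paste0("g", 1:5), p_value = rep(1, 5))
  expect_equal(sum(bh_select(all1, 0.05, 1)$selected), 0)

  # single gene at the boundary p = q/m: inclusive, but raw cutoff rules
  one <- tibble::tibble(gene = "g1", p_value = 0.001)
  expect_true(bh_select(one, 0.001, 0.001)$selected)
  expect_false(bh_select(one, 0.001, 0.0005)$selected)

  # empty input
  expect_equal(nrow(bh_select(all1[0, ], 0.05, 1)), 0)
})

test_that("bh_select equals brute-force threshold search (m <= 12)", {
  set.seed(10)
  for (i in 1:300) {
    m <- sample(1:12, 1)
    p <- round(runif(m), sample(c(1, 2, 4), 1))  # coarse: frequent ties
    q <- sample(c(0.001, 0.01, 0.05, 0.2, 1), 1)
    raw <- sample(c(0.001, 0.05, 1), 1)
    d <- tibble::tibble(gene = sprintf("g%02d", 1:m), p_value = p)
    got <- bh_select(d, q, raw)
    want <- oracle_bh_selected(p, q, raw)
    expect_equal(sort(got$gene[got$selected]),
                 sort(d$gene[want]),
                 info = paste("case", i))
  }
})

test_that("selection is monotone in the FDR level", {
  set.seed(12)
  d <- tibble::tibble(gene = sprintf("g%02d", 1:30),
                      p_value = rbeta(30, 0.3, 3))
  prev <- 0
  for (q in c(1e-4, 1e-3, 1e-2, 0.1, 0.5, 1)) {
    cur <- sum(bh_select(d, q, raw_p_cutoff = 1)$selected)
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("tied p-values share the selection outcome", {
  d <- tibble::tibble(gene = c("gB", "gA", "gC"),
                      p_value = c(0.01, 0.01, 0.9))
  out <- bh_select(d, fdr_level = 0.05, raw_p_cutoff = 1)
  expect_equal(out$selected[out$gene %in% c("gA", "gB")], c(TRUE, TRUE))
  # ties broken lexicographically for the rank order
  expect_equal(out$gene, c("gA", "gB", "gC"))
})

test_that("direction classification uses log2(x + 1) group medians", {
  study <- toy_study()
  dir <- classify_direction(study)
  expect_equal(dir$direction, c("up", "down", "down"))

  # identical groups tie with equal medians
  normal <- matrix(1:6, nrow = 2, dimnames = list(c("g1", "g2"), NULL))
  same <- study_from_groups(normal, normal)
  dir2 <- classify_direction(same)
  expect_true(all(dir2$direction == "tie"))
  expect_equal(dir2$log2_median_normal, dir2$log2_median_tumor)

  # 4-fold change: log2 median difference ~ 2 at high expression
  set.seed(13)
  base <- matrix(runif(10, 4000, 8000), nrow = 1,
                 dimnames = list("gX", NULL))
  fold <- classify_direction(study_from_groups(base, base * 4))
  expect_equal(fold$direction, "up")
  expect_equal(fold$log2_median_tumor - fold$log2_median_normal, 2,
               tolerance = 1e-3)
})

test_that("middle-rank threshold retains strictly-below-threshold ranks", {
  d <- tibble::tibble(gene = paste0("g", 1:4),
                      p_value = c(1e-4, 2e-4, 0.5, 0.9))
  expect_identical(middle_rank_threshold(d, 0.001), "g1")
  # all p equal: one shared level, nothing strictly below
  same <- tibble::tibble(gene = paste0("g", 1:6), p_value = rep(0.2, 6))
  expect_identical(middle_rank_threshold(same, 0.001), character())
  expect_identical(middle_rank_threshold(d[0, ], 0.001), character())
})

test_that("family-wise error of the null DEG stage stays at the BH level", {
  # global null: both groups drawn from one exchangeable distribution
  set.seed(14)
  n_rep <- 2000
  any_hit <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    vals <- matrix(rexp(5 * 16), nrow = 5,
                   dimnames = list(paste0("g", 1:5), NULL))
    study <- study_from_groups(vals[, 1:8], vals[, 9:16])
    sel <- bh_select(wilcoxon_test(study), fdr_level = 0.05,
                     raw_p_cutoff = 1)
    any_hit[r] <- any(sel$selected)
  }
  rate <- mean(any_hit)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("deg_table combines test, selection and direction", {
  set.seed(15)
  normal <- matrix(rlnorm(6 * 10, 5), nrow = 6,
                   dimnames = list(paste0("g", 1:6), NULL))
  tumor <- normal
  tumor[1, ] <- tumor[1, ] * 8   # strong planted shift
  study <- study_from_groups(normal, tumor)
  out <- deg_table(study, fdr_level = 0.05, raw_p_cutoff = 0.05)
  expect_named(out, c("gene", "p_value", "rank", "bh_critical",
                      "selected", "direction", "log2_median_normal",
                      "log2_median_tumor"))
  expect_equal(out$rank, 1:6)
  expect_true(out$selected[out$gene == "g1"])
  expect_equal(out$direction[out$gene == "g1"], "up")
})
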