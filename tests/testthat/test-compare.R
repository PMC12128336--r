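test_that("common hubs and percentages follow set arithmetic", {
  cmp <- common_hubs(c("A", "B"), c("B", "C"))
  expect_equal(cmp$common, "B")
  expect_equal(cmp$only_a, "A")
  expect_equal(cmp$only_b, "C")
  expect_equal(cmp$pct_common_a, 50)
  expect_equal(cmp$pct_common_b, 50)

  disj <- common_hubs(c("A", "B"), c("C", "D"))
  expect_equal(length(disj$common), 0)
  expect_equal(disj$pct_common_a, 0)

  set.seed(50)
  pool <- sprintf("g%03d", 1:60)
  a <- sample(pool, 25); b <- sample(pool, 18)
  got <- common_hubs(a, b)
  expect_setequal(got$common, intersect(a, b))
  expect_setequal(got$only_a, setdiff(a, b))
  expect_setequal(got$only_b, setdiff(b, a))
})

test_that("shared edges are the per-hub neighbor intersections", {
  net_a <- gene_network(tibble::tibble(from = c("H", "H"),
                                       to = c("X", "Y"), weight = 1))
  net_b <- gene_network(tibble::tibble(from = c("H", "H"),
                                       to = c("Y", "Z"), weight = 1))
  sh <- shared_edges(net_a, net_b, "H")
  expect_equal(sh$per_hub$shared[[1]], "Y")
  expect_equal(sh$per_hub$n_shared, 1)
  expect_equal(sh$n_with_shared, 1)

  # symmetric in the two networks
  sh_rev <- shared_edges(net_b, net_a, "H")
  expect_equal(sh_rev$per_hub$shared, sh$per_hub$shared)

  # identical networks: every hub shares all of its edges
  set.seed(51)
  net <- random_network(25, 0.15)
  hubs <- node_candidates(net)$gene[1:5]
  sh_id <- shared_edges(net, net, hubs)
  expect_equal(sh_id$per_hub$n_shared, sh_id$per_hub$degree_a)
  expect_equal(sh_id$n_with_shared, 5)

  # seeded pair: brute-force neighbor intersections
  net2 <- random_network(25, 0.15)
  common <- intersect(node_candidates(net)$gene,
                      node_candidates(net2)$gene)
  got <- shared_edges(net, net2, common)
  for (i in seq_along(common)) {
    expect_equal(got$per_hub$shared[[i]],
                 intersect(neighbors_of(net, common[i]),
                           neighbors_of(net2, common[i])))
  }
})

test_that("projection into the own network is the identity", {
  set.seed(52)
  net <- random_network(30, 0.12)
  hubs <- select_hubs(net, cutoff_weight = 0, cutoff_degree = 2)
  proj <- project_hubs(hubs, net)
  expect_true(all(proj$per_hub$identified))
  expect_equal(proj$per_hub$degree_other, proj$per_hub$degree_own)
  expect_equal(proj$per_hub$n_shared_edges, proj$per_hub$degree_own)
  expect_equal(proj$summary$n_identified, nrow(hubs$members))
})

test_that("projection summaries equal a brute-force recomputation", {
  set.seed(53)
  net_a <- random_network(30, 0.12)
  net_b <- random_network(30, 0.1)
  hubs <- select_hubs(net_a, cutoff_weight = 0, cutoff_degree = 2)
  proj <- project_hubs(hubs, net_b)
  manual_deg <- vapply(hubs$members$gene, function(g)
    length(neighbors_of(net_b, g)), integer(1))
  expect_equal(proj$per_hub$degree_other, unname(manual_deg))
  expect_equal(proj$summary$n_identified, sum(manual_deg >= 1))
  expect_equal(proj$summary$pct_identified,
               pct(sum(manual_deg >= 1), length(manual_deg)))
  ident <- manual_deg[manual_deg >= 1]
  expect_equal(proj$summary$mean_degree_identified, mean(ident))
  expect_equal(proj$summary$degree_range, range(ident))

  # a hub absent from the other network is simply not identified
  lonely <- gene_network(tibble::tibble(from = "Q1", to = "Q2",
                                        weight = 1))
  proj2 <- project_hubs(hubs, lonely)
  expect_equal(proj2$summary$n_identified, 0)
})

test_that("DEG/hub Venn regions match brute-force enumeration", {
  deg <- tibble::tibble(gene = c("g1", "g2", "g3"),
                        p_value = c(1e-5, 1e-4, 2e-3),
                        selected = c(TRUE, TRUE, FALSE),
                        direction = c("up", "down", "up"))
  out <- intersect_deg_hubs(deg, c("g1", "g3"), c("g1", "g4"))
  expect_equal(out$venn$n[out$venn$region == "center"], 1)
  expect_equal(out$highlighted$gene, "g1")
  expect_equal(out$highlighted$direction, "up")

  # empty DEG set: all DEG-involving regions empty
  deg0 <- deg; deg0$selected <- FALSE
  out0 <- intersect_deg_hubs(deg0, c("g1", "g3"), c("g1", "g4"))
  expect_equal(nrow(out0$highlighted), 0)
  expect_equal(sum(out0$venn$n[grepl("deg|center", out0$venn$region)]), 0)

  # seeded random sets: all 7 regions against direct enumeration,
  # and the regions partition the union
  set.seed(54)
  pool <- sprintf("g%03d", 1:40)
  d_genes <- sample(pool, 15)
  a <- sample(pool, 12); b <- sample(pool, 10)
  degr <- tibble::tibble(gene = pool, p_value = runif(40),
                         selected = pool %in% d_genes,
                         direction = sample(c("up", "down"), 40, TRUE))
  res <- intersect_deg_hubs(degr, a, b)
  u <- union(union(d_genes, a), b)
  expect_equal(sum(res$venn$n), length(u))
  manual_center <- intersect(intersect(d_genes, a), b)
  expect_setequal(res$venn$genes[[which(res$venn$region == "center")]],
                  manual_center)
  manual_deg_only <- setdiff(setdiff(d_genes, a), b)
  expect_setequal(res$venn$genes[[which(res$venn$region == "deg_only")]],
                  manual_deg_only)
  # per-category direction splits
  com <- res$categories[res$categories$category == "common", ]
  in_deg <- intersect(intersect(a, b), d_genes)
  expect_equal(com$n_deg, length(in_deg))
  expect_equal(com$n_up,
               sum(degr$direction[degr$gene %in% in_deg] == "up"))
})

test_that("hub-universe re-test loosens the BH burden", {
  set.seed(55)
  m <- 200
  deg <- tibble::tibble(gene = sprintf("g%03d", 1:m),
                        p_value = c(runif(5, 0, 5e-4), runif(m - 5)))
  hubs <- deg$gene[1:20]
  full <- bh_select(deg, 0.001, 0.001)
  re <- retest_hub_significance(deg, hubs, character(), 0.001, 0.001)
  expect_equal(nrow(re), 20)
  # every gene significant genome-wide among hubs stays significant
  full_sel <- full$gene[full$selected & full$gene %in% hubs]
  expect_true(all(full_sel %in% re$gene[re$selected]))
  expect_error(retest_hub_significance(deg, "absent", character()),
               "absent")
})
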