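test_that("the log composite likelihood matches worked single-quartet values", {
  tab <- one_quartet_table(c(1, 0, 0))
  expect_equal(log_composite_likelihood(tab, matrix(c(0.5, 0.25, 0.25), 1)),
               log(0.5), tolerance = 1e-12)
  tab2 <- one_quartet_table(c(1 / 3, 1 / 3, 1 / 3))
  expect_equal(log_composite_likelihood(tab2, matrix(1 / 3, 1, 3)),
               log(1 / 3), tolerance = 1e-12)
  # terms with X = 0 contribute nothing even when the expected CF is 0
  expect_equal(log_composite_likelihood(tab, matrix(c(0.5, 0.5, 0), 1)),
               log(0.5), tolerance = 1e-12)
})

test_that("the log composite likelihood is additive over 4-taxon sets", {
  net <- sim_net_retry(6, 0, seed = 41)
  gt <- simulate_gene_trees(net, 100, seed = 42)
  tab <- observed_cf(gt)
  ex <- expected_cf_network(net, tab)
  full <- log_composite_likelihood(tab, ex)
  parts <- vapply(seq_len(nrow(tab)), function(i)
    log_composite_likelihood(
      qcfnet:::new_cf_table(as.data.frame(tab)[i, , drop = FALSE],
                            attr(tab, "taxa")),
      ex[i, , drop = FALSE]),
    0.0)
  expect_equal(full, sum(parts), tolerance = 1e-10)
})

test_that("per-quartet terms are maximised at expected = observed", {
  # multinomial property on a simplex grid
  x <- c(0.55, 0.3, 0.15)
  tab <- one_quartet_table(x)
  at_x <- log_composite_likelihood(tab, matrix(x, 1))
  step <- 0.1
  for (p1 in seq(step, 1 - 2 * step, by = step))
    for (p2 in seq(step, 1 - p1 - step + 1e-9, by = step)) {
      p <- c(p1, p2, 1 - p1 - p2)
      expect_lte(log_composite_likelihood(tab, matrix(p, 1)), at_x + 1e-12)
    }
})

test_that("the R and C++ likelihood paths agree", {
  net <- sim_net_retry(7, 1, seed = 43)
  gt <- simulate_gene_trees(net, 200, seed = 44)
  tab <- observed_cf(gt)
  cm <- qcfnet:::cf_matrix(tab)
  map <- qcfnet:::compile_cf_map(net, cm$quartets)
  ex <- expected_cf_network(net, tab)
  expect_equal(qcfnet:::cpp_map_logcl(map, net$length, net$gamma,
                                      cm$X, cm$use, 1e-12),
               log_composite_likelihood(tab, ex), tolerance = 1e-9)
})

test_that("logCL is invariant under consistent taxon relabeling", {
  net <- sim_net_retry(6, 1, seed = 45)
  gt <- simulate_gene_trees(net, 150, seed = 46)
  tab <- observed_cf(gt)
  ll <- log_composite_likelihood(tab, expected_cf_network(net, tab))
  perm <- setNames(sprintf("x%02d", seq_along(net$taxa)), net$taxa)
  rel <- net
  rel$labels <- ifelse(is.na(net$labels), NA, unname(perm[net$labels]))
  rel <- qcfnet:::net_refresh(rel)
  gt2 <- lapply(gt, function(p) { p$tip.label <- unname(perm[p$tip.label]); p })
  tab2 <- observed_cf(gt2)
  ll2 <- log_composite_likelihood(tab2, expected_cf_network(rel, tab2))
  expect_equal(ll, ll2, tolerance = 1e-10)
})

test_that("a flat observed CF drives the internal branch to the star limit", {
  tab <- one_quartet_table(c(1 / 3, 1 / 3, 1 / 3))
  topo <- quartet_tree_net(1.0)
  sc <- optimize_parameters(topo, tab, seed = 1)
  expect_equal(sc$logCL, log(1 / 3), tolerance = 1e-4)
  qn <- extract_quarnet(sc$network, sc$network$taxa)
  internal <- sum(qn$length[qcfnet:::popcount4(
    qcfnet:::edge_clusters_mask(qn, qn$taxa)) == 2])
  expect_lt(internal, 0.01)
})

test_that("optimisation inverts the closed form on noiseless quartet data", {
  x <- c(1 - 2 / 3 * exp(-1), exp(-1) / 3, exp(-1) / 3)
  tab <- one_quartet_table(x)
  topo <- quartet_tree_net(0.3)
  sc <- optimize_parameters(topo, tab, seed = 2)
  qn <- extract_quarnet(sc$network, sc$network$taxa)
  internal <- sum(qn$length[qcfnet:::popcount4(
    qcfnet:::edge_clusters_mask(qn, qn$taxa)) == 2])
  expect_equal(internal, 1.0, tolerance = 0.01)
})

test_that("noiseless network data recover gamma and fit the CFs", {
  net <- sim_net_retry(8, 1, seed = 47)
  tab <- noiseless_table(net)
  start <- net
  map <- qcfnet:::compile_cf_map(net, qcfnet:::cf_matrix(tab)$quartets)
  par <- qcfnet:::free_parameters(net, map)
  start$length[par$len_ids] <- pmax(start$length[par$len_ids], 0.1) * 1.7
  start$gamma[par$gam_minor] <- 0.3
  start$gamma[par$gam_major] <- 0.7
  sc <- optimize_parameters(start, tab, seed = 3)
  truth_ll <- log_composite_likelihood(tab, expected_cf_network(net, tab))
  expect_gte(sc$logCL, truth_ll - 1e-4)
  expect_equal(unname(sc$network$gamma[par$gam_minor]), 0.5, tolerance = 0.05)
  fit_cf <- expected_cf_network(sc$network, tab)
  expect_lt(max(abs(fit_cf - qcfnet:::cf_matrix(tab)$X)), 5e-3)
})

test_that("optimisation never returns a score below its starting point", {
  for (i in 1:4) {
    net <- sim_net_retry(6, i %% 2, seed = 50 + i)
    gt <- simulate_gene_trees(net, 100, seed = 60 + i)
    tab <- observed_cf(gt)
    ex0 <- expected_cf_network(net, tab)
    ll0 <- log_composite_likelihood(tab, ex0)
    sc <- optimize_parameters(net, tab, seed = i)
    expect_gte(sc$logCL, ll0 - 1e-9)
  }
})

test_that("full-table rescoring flips scope and uses all quartets", {
  net <- sim_net_retry(7, 0, seed = 55)
  gt <- simulate_gene_trees(net, 200, seed = 56)
  tab <- observed_cf(gt)
  sub <- subsample_quartets(tab, 0.5, seed = 9)
  sc_sub <- optimize_parameters(net, sub, seed = 1, scope = "subsample")
  sc_full <- final_full_score(sc_sub$network, tab, seed = 1)
  expect_identical(sc_sub$scope, "subsample")
  expect_identical(sc_full$scope, "full")
  # roughly twice as many terms on the full scale
  expect_lt(sc_full$logCL, sc_sub$logCL)
})
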