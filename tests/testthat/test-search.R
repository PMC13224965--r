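test_that("NNI on the internal edge of a quartet tree yields another resolution", {
  net <- quartet_tree_net(1.0)
  legal <- qcfnet:::legal_foci(net, "NNI")
  expect_gte(length(legal), 1L)
  set.seed(1)
  cand <- propose_move(net, "NNI", legal[1])
  expect_false(is.null(cand))
  expect_length(validate_network(cand), 0)
  expect_gt(hwcd(net, cand), 0)   # a different quartet topology
})

test_that("adding a reticulation yields a valid h+1 network with gamma 0.5", {
  net <- sim_net_retry(8, 0, seed = 71)
  set.seed(4)
  added <- NULL
  for (i in 1:200) {
    focus <- sample.int(qcfnet:::n_edges(net), 1)
    cand <- propose_move(net, "add_reticulation", focus)
    if (!is.null(cand)) { added <- cand; break }
  }
  expect_false(is.null(added))
  expect_equal(added$h, 1L)
  expect_length(validate_network(added), 0)
  expect_setequal(round(added$gamma[!is.na(added$gamma)], 10), 0.5)
})

test_that("random move proposals always pass validation", {
  set.seed(5)
  net <- sim_net_retry(8, 1, seed = 72)
  n_ok <- 0
  for (i in 1:120) {
    mv <- sample(qcfnet:::move_types, 1)
    legal <- qcfnet:::legal_foci(net, mv)
    if (length(legal) == 0) next
    cand <- propose_move(net, mv, legal[sample.int(length(legal), 1)])
    if (is.null(cand)) next
    expect_length(validate_network(cand), 0)
    expect_identical(cand$taxa, net$taxa)
    expect_lte(cand$h, net$h + (mv == "add_reticulation"))
    n_ok <- n_ok + 1
  }
  expect_gt(n_ok, 20)
})

test_that("focus selection is uniform at prob_qr = 0 and weighted otherwise", {
  net <- sim_net_retry(6, 1, seed = 73)
  gt <- simulate_gene_trees(net, 100, seed = 74)
  tab <- observed_cf(gt)
  # prob_qr = 0 never needs expected CFs
  set.seed(6)
  f <- replicate(50, select_focus(net, tab, NULL, 0, "NNI"))
  expect_true(all(f %in% qcfnet:::legal_foci(net, "NNI")))

  # give one quartet all the weight: expected CFs equal the observed ones
  # everywhere except quartet 1, which is maximally wrong
  X <- qcfnet:::cf_matrix(tab)$X
  ex <- X; ex[1, ] <- c(0, 0, 1)
  W <- quartet_weights(tab, ex)
  expect_true(W[1] > 0 && all(W[-1] < 1e-12))
  map <- qcfnet:::compile_cf_map(net, qcfnet:::cf_matrix(tab)$quartets)
  spanned <- qcfnet:::map_spanned_ids(map, 1L)
  set.seed(7)
  draws <- replicate(200, select_focus(net, tab, ex, 1, "add_reticulation",
                                       map = map))
  expect_true(all(draws %in% spanned))
  # the spanned edges are hit roughly uniformly
  tb <- table(factor(draws, levels = spanned))
  p0 <- 1 / length(spanned)
  se <- sqrt(p0 * (1 - p0) / 200)
  expect_true(all(abs(tb / 200 - p0) < 4 * se))

  # zero weights everywhere: weighted mode falls back to uniform legal foci
  set.seed(8)
  d2 <- replicate(50, select_focus(net, tab, X, 1, "NNI", map = map))
  expect_true(all(d2 %in% qcfnet:::legal_foci(net, "NNI")))
})

test_that("the true network is a fixed point on its own expected CFs", {
  net <- sim_net_retry(7, 1, seed = 75)
  tab <- noiseless_table(net)
  run <- hill_climb_run(net, tab,
                        qcf_search_config(h = 1, max_failures = 25,
                                          optimizer = qcf_control(starts = 1)),
                        run_seed = 11)
  expect_equal(run$n_accepted, 0L)
  expect_true(qcfnet:::network_identical(
    qcfnet:::net_refresh(run$final$network),
    qcfnet:::net_refresh(optimize_parameters(net, tab, seed = 11)$network)) ||
    hwcd(run$final$network, net) == 0)
})

test_that("a single misfit quartet drives one NNI acceptance", {
  tab <- one_quartet_table(c(0, 1, 0))
  start <- quartet_tree_net(1.0)  # ab|cd, but the data say ac|bd
  run <- hill_climb_run(start, tab,
                        qcf_search_config(h = 0, max_failures = 20,
                                          optimizer = qcf_control(starts = 1)),
                        run_seed = 12)
  expect_gte(run$n_accepted, 1L)
  # the incumbent now puts ~all probability on ac|bd
  ex <- expected_cf_network(run$final$network,
                            matrix(c("a", "b", "c", "d"), 1))
  expect_gt(ex[1, 2], 0.99)
  expect_gt(run$final$logCL, log(0.99))
  # accepted scores increase strictly along the trace
  acc <- run$trace$logCL[run$trace$accepted]
  expect_true(all(diff(c(-Inf, acc)) > 0))
})

with_seed_tree <- function(seed, taxa) {
  qcfnet:::with_local_seed(seed,
    qcfnet:::phylo_to_net(ape::rtree(length(taxa), tip.label = sample(taxa))))
}

test_that("accepted scores are strictly increasing across datasets", {
  for (i in 1:5) {
    net <- sim_net_retry(6, 0, seed = 80 + i)
    gt <- simulate_gene_trees(net, 150, seed = 90 + i)
    tab <- observed_cf(gt)
    start <- with_seed_tree(100 + i, attr(tab, "taxa"))
    run <- hill_climb_run(start, tab,
                          qcf_search_config(h = 0, max_failures = 15,
                                            optimizer = qcf_control(starts = 1)),
                          run_seed = 110 + i)
    acc <- run$trace$logCL[run$trace$accepted]
    if (length(acc) > 1) expect_true(all(diff(acc) > 0))
    expect_lte(run$final$network$h, 0L)
  }
})

test_that("multi-run search is reproducible and respects h bounds", {
  net <- sim_net_retry(6, 1, seed = 85)
  gt <- simulate_gene_trees(net, 200, seed = 86)
  fit1 <- qcfnet(gt, h = 1, runs = 2, seed = 3, max_failures = 10,
                 control = qcf_control(starts = 1))
  fit2 <- qcfnet(gt, h = 1, runs = 2, seed = 3, max_failures = 10,
                 control = qcf_control(starts = 1))
  expect_equal(fit1$logCL, fit2$logCL, tolerance = 1e-12)
  expect_true(qcfnet:::network_identical(fit1$network, fit2$network))
  expect_lte(fit1$network$h, 1L)
  for (r in fit1$runs) {
    expect_lte(r$final$network$h, 1L)
    expect_length(validate_network(r$final$network), 0)
  }
})

test_that("per-run subsampling feeds the search and full rescoring", {
  net <- sim_net_retry(7, 0, seed = 87)
  gt <- simulate_gene_trees(net, 200, seed = 88)
  tab <- observed_cf(gt)
  cfg <- qcf_search_config(h = 0, runs = 2, prop_quartets = 0.5, seed = 4,
                           max_failures = 8,
                           optimizer = qcf_control(starts = 1))
  res <- multi_run_search(list(net), tab, cfg)
  expect_identical(res$best$scope, "full")
  for (r in res$runs) expect_identical(r$final$scope, "subsample")
})
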