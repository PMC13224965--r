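test_that("quartet-tree CFs follow the coalescent closed form", {
  expect_identical(expected_cf_tree(0), c(1 / 3, 1 / 3, 1 / 3))
  expect_identical(expected_cf_tree(Inf), c(1, 0, 0))
  for (t in seq(0.1, 5, by = 0.35)) {
    cf <- expected_cf_tree(t)
    expect_equal(cf[1], 1 - (2 / 3) * exp(-t), tolerance = 1e-12)
    expect_equal(cf[2], cf[3])
    expect_equal(sum(cf), 1, tolerance = 1e-12)
  }
  expect_equal(expected_cf_tree(0.5)[1], 0.595646, tolerance = 1e-5)
  expect_error(expected_cf_tree(-0.1), "non-negative")
})

test_that("the 4-cycle quarnet matches the displayed-tree mixture", {
  qn <- cycle_quarnet(gamma = 0.3)
  cf <- expected_cf_quarnet(qn)
  # hybrid leaf a: single lineage reaches the hybrid, so the exact CF is the
  # mixture of the two displayed quartet trees
  mix_ab <- 0.3 * (1 - 2 / 3 * exp(-1)) + 0.7 * (exp(-0.5) / 3)
  expect_equal(unname(cf[1]), mix_ab, tolerance = 1e-4)
  expect_equal(sum(cf), 1, tolerance = 1e-9)
})

# closed-form CF triple with the major split at position `pos`
cf_tree_ref <- function(t, pos) {
  minor <- exp(-t) / 3
  out <- rep(minor, 3)
  out[pos] <- 1 - 2 * minor
  out
}

test_that("gamma in {0,1} collapses network CFs to the displayed tree", {
  for (g in c(0, 1)) {
    qn <- cycle_quarnet(gamma = 0.3)
    es <- which(!is.na(qn$gamma))
    minor <- es[which.min(qn$gamma[es])]
    major <- setdiff(es, minor)
    qn$gamma[minor] <- g
    qn$gamma[major] <- 1 - g
    cf <- expected_cf_quarnet(qn)
    # the retained displayed tree is ab|cd (minor kept) or ac|bd (major kept)
    if (g == 1) expect_equal(cf, cf_tree_ref(1.0, 1L), tolerance = 1e-12)
    else expect_equal(cf, cf_tree_ref(0.5, 2L), tolerance = 1e-12)
  }
})

test_that("expected CFs are continuous in lengths and gammas", {
  qn <- cycle_quarnet(gamma = 0.3)
  cf0 <- expected_cf_quarnet(qn)
  for (e in seq_len(length(qn$parent))) {
    q2 <- qn
    if (!is.na(q2$length[e])) {
      q2$length[e] <- q2$length[e] + 1e-8
      expect_lt(max(abs(expected_cf_quarnet(q2) - cf0)), 1e-6)
    }
  }
  q3 <- qn
  es <- which(!is.na(q3$gamma))
  q3$gamma[es] <- q3$gamma[es] + c(1e-8, -1e-8)
  expect_lt(max(abs(expected_cf_quarnet(q3) - cf0)), 1e-6)
})

test_that("analytic quarnet CFs agree with the Monte-Carlo oracle", {
  ngenes <- 2e4
  checked <- 0
  for (i in 1:10) {
    net <- sim_net_retry(4, i %% 2, mean_bl = runif(1, 0.5, 2), seed = 700 + i)
    cf <- expected_cf_quarnet(net)
    mc <- mc_cf_oracle(net, net$taxa, ngenes, seed = 800 + i)
    se <- pmax(sqrt(cf * (1 - cf) / ngenes), 1e-4)
    expect_lt(max(abs(mc - cf) / se), 3.5)
    checked <- checked + 1
  }
  expect_equal(checked, 10)
})

test_that("the oracle is seed-deterministic and exchangeable at t=0", {
  qn <- quartet_tree_net(0)
  f1 <- mc_cf_oracle(qn, qn$taxa, 1e4, seed = 5)
  f2 <- mc_cf_oracle(qn, qn$taxa, 1e4, seed = 5)
  expect_identical(f1, f2)
  se <- sqrt((1 / 3) * (2 / 3) / 1e4)
  expect_true(all(abs(f1 - 1 / 3) < 3 * se))
  # t = 10: essentially no ILS
  deep <- quartet_tree_net(10)
  f3 <- mc_cf_oracle(deep, deep$taxa, 1e4, seed = 6)
  expect_gte(f3[1], (1 - 2 / 3 * exp(-10)) - 3 * sqrt(1e-3 / 1e4) - 1e-3)
})

test_that("network-wide expected CFs compose and normalise", {
  net <- sim_net_retry(8, 1, seed = 31)
  ex <- expected_cf_network(net)
  expect_equal(nrow(ex), 70L)
  expect_lt(max(abs(rowSums(ex) - 1)), 1e-9)
  # tree case: every quartet equals the closed form on its internal length
  tr <- sim_net_retry(7, 0, seed = 32)
  ex2 <- expected_cf_network(tr)
  for (qi in sample(nrow(ex2), 5)) {
    qs <- enumerate_quartets(tr$taxa)[qi, ]
    qn <- extract_quarnet(tr, qs)
    expect_equal(unname(ex2[qi, ]), unname(expected_cf_quarnet(qn)),
                 tolerance = 1e-12)
  }
})

test_that("expected CFs are identical for 1 and 4 workers", {
  net <- sim_net_retry(8, 1, seed = 33)
  e1 <- expected_cf_network(net, workers = 1)
  e4 <- expected_cf_network(net, workers = 4)
  expect_identical(e1, e4)
})
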