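test_that("Newick gene-tree parsing handles the basic cases and errors", {
  phy <- parse_newick("((a,b),(c,d));")
  expect_s3_class(phy, "phylo")
  expect_setequal(phy$tip.label, c("a", "b", "c", "d"))
  expect_equal(phy$Nnode, 3L)  # rooted binary on 4 tips

  cat5 <- parse_newick("(a,(b,(c,(d,e))));")
  expect_setequal(cat5$tip.label, letters[1:5])

  expect_error(parse_newick("((a,b),(a,c));"), "duplicate")
  expect_error(parse_newick("((a,b),(c,d);"), "position")
  expect_error(parse_newick(""), "empty")
})

test_that("extended-Newick parsing recovers hybrid structure and gammas", {
  net <- parse_enewick("((a,b),(c,d));")
  expect_equal(net$h, 0L)
  expect_equal(net$taxa, c("a", "b", "c", "d"))

  hn <- parse_enewick("((a,(b)#H1:::0.3),(#H1,(c,d)));")
  expect_equal(hn$h, 1L)
  g <- sort(hn$gamma[!is.na(hn$gamma)])
  expect_equal(g, c(0.3, 0.7))

  # gamma given on one hybrid edge only: the other gets 1 - gamma
  # tag multiplicity is enforced
  expect_error(parse_enewick("((a,(b)#H1:::0.3),(c,d));"), "appears 1")
  # a 2-cycle (both hybrid edges between the same two nodes) is invalid
  expect_error(parse_enewick("(((b)#H1:::0.4,#H1),(c,d),a);"), "violates|degree")
})

test_that("write/parse round-trip preserves simulated networks", {
  for (i in 1:10) {
    h <- sample(0:3, 1)
    net <- sim_net_retry(sample((6 + 2 * h):13, 1), h, seed = 300 + i)
    rt <- parse_enewick(write_enewick(net))
    expect_true(qcfnet:::network_identical(net, rt))
    expect_valid(rt)
    if (net$h >= 1)
      expect_equal(lengths(regmatches(write_enewick(net),
                   gregexpr("#H", write_enewick(net)))), 2L * net$h)
  }
})

test_that("round-trip of a 10-taxon h=3 network has HWCD 0 to the original", {
  net <- sim_net_retry(10, 3, seed = 91)
  rt <- parse_enewick(write_enewick(net))
  root <- qcfnet:::common_root_taxon(net, rt)
  expect_identical(hwcd(net, rt, root), 0L)
})

test_that("validate_network reports named violations", {
  net <- parse_enewick("((a,(b)#H1:::0.3),(#H1,(c,d)));")
  expect_valid(net)

  # two parallel hybrid edges between the same node pair: a 2-cycle
  two <- qcf_network(parent = c(4L, 4L, 5L, 5L, 6L, 7L, 7L),
                     child = c(1L, 5L, 6L, 6L, 7L, 2L, 3L),
                     gamma = c(NA, NA, 0.4, 0.6, NA, NA, NA),
                     labels = c("a", "c", "d", NA, NA, NA, NA),
                     check = FALSE)
  expect_true("two_cycle" %in% validate_network(two))

  # 3-cycle: hybrid whose two parents are adjacent
  three <- parse_enewick_unchecked <- tryCatch(
    parse_enewick("((((b)#H1:::0.3,c),#H1),(a,d));"), error = function(e) e)
  expect_true(inherits(three, "error"))  # parser already rejects it

  # gamma sum violation
  bad <- parse_enewick("((a,(b)#H1:::0.3),(#H1,(c,d)));")
  bad$gamma[!is.na(bad$gamma)] <- c(0.3, 0.3)[seq_len(sum(!is.na(bad$gamma)))]
  expect_true("gamma_sum" %in% validate_network(bad))
})

test_that("validate_network flags multiple hybrids in one blob as not level-1", {
  skip_if_not(requireNamespace("igraph", quietly = TRUE))
  # two hybrids whose cycles share edges (constructed by hand)
  n <- qcf_network(
    parent = c(9L, 9L, 10L, 10L, 11L, 11L, 12L, 12L, 13L, 13L, 12L, 14L, 14L),
    child  = c(1L, 10L, 11L, 12L, 2L, 13L, 13L, 14L, 3L, 14L, 11L, 4L, 5L),
    gamma  = c(NA, NA, NA, NA, NA, 0.5, 0.5, 0.5, NA, 0.5, NA, NA, NA),
    labels = c("a", "b", "c", "d", "e", NA, NA, NA, NA, NA, NA, NA, NA, NA),
    check = FALSE)
  v <- validate_network(n)
  expect_true(length(v) > 0)
})

test_that("displayed trees carry the right probabilities and sum to 1", {
  net <- parse_enewick("((a,b),(c,d));")
  dt <- displayed_trees(net)
  expect_length(dt, 1L)
  expect_equal(dt[[1]]$prob, 1.0)

  hn <- parse_enewick("((a,(b)#H1:::0.3),(#H1,(c,d)));")
  dt <- displayed_trees(hn)
  expect_setequal(round(sapply(dt, `[[`, "prob"), 10), c(0.3, 0.7))

  h2 <- sim_net_retry(8, 2, seed = 47)
  dt2 <- displayed_trees(h2)
  expect_length(dt2, 4L)
  expect_equal(sum(sapply(dt2, `[[`, "prob")), 1, tolerance = 1e-12)
})

test_that("quarnet extraction restricts trees with summed internal lengths", {
  net <- sim_net_retry(10, 0, seed = 17)
  taxa <- net$taxa[c(1, 4, 6, 9)]
  qn <- extract_quarnet(net, taxa)
  expect_setequal(qn$taxa, taxa)
  expect_equal(qn$h, 0L)
  # against ape: the induced quartet topology matches keep.tip
  phy <- qcfnet:::net_to_phylo(net)
  sub <- ape::keep.tip(phy, taxa)
  expect_identical(hwcd(qn, qcfnet:::phylo_to_net(sub)), 0L)

  expect_error(extract_quarnet(net, c("t1", "t2", "t3", "zz")), "not found")
})

test_that("a cycle that does not separate the four taxa drops from the quarnet", {
  hn <- sim_net_retry(10, 1, seed = 53)
  # find the taxa below the hybrid node
  hyb <- which(qcfnet:::net_refresh(hn)$indeg == 2L)[1]
  # taxa far from the cycle: try all 4-sets until one yields a tree quarnet
  qs <- enumerate_quartets(hn$taxa)
  types <- apply(qs, 1, function(tx) extract_quarnet(hn, tx)$h)
  expect_true(any(types == 0L))  # some 4-sets avoid the cycle
  expect_true(any(types >= 1L))  # and some span it
})

test_that("quarnet extraction commutes with leaf relabeling", {
  net <- sim_net_retry(8, 1, seed = 61)
  # order-preserving relabeling: sorted order (hence canonical split order)
  # is unchanged, so expected CFs must be identical
  perm <- setNames(sprintf("x%02d", seq_along(net$taxa)), net$taxa)
  rel <- net
  rel$labels <- ifelse(is.na(net$labels), NA, unname(perm[net$labels]))
  rel <- qcfnet:::net_refresh(rel)
  for (row in list(c(2, 3, 5, 8), c(1, 2, 3, 4), c(4, 5, 6, 7))) {
    taxa <- net$taxa[row]
    cf1 <- expected_cf_quarnet(extract_quarnet(net, taxa))
    cf2 <- expected_cf_quarnet(extract_quarnet(rel, unname(perm[taxa])))
    expect_equal(unname(cf2), unname(cf1), tolerance = 1e-12)
  }
})
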