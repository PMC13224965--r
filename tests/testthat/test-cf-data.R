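test_that("quartet enumeration gives all C(n,4) sets in canonical order", {
  expect_equal(nrow(enumerate_quartets(letters[1:4])), 1L)
  q10 <- enumerate_quartets(paste0("t", 1:10))
  expect_equal(nrow(q10), 210L)
  expect_equal(nrow(enumerate_quartets(paste0("t", 1:20))), 4845L)
  # deterministic lexicographic order, rows sorted within
  expect_true(all(q10 == t(apply(q10, 1, sort))))
  expect_identical(q10, enumerate_quartets(rev(paste0("t", 1:10))))
  expect_error(enumerate_quartets(c("a", "b", "c")), "at least 4")
})

test_that("observed CFs count quartet topologies in gene trees", {
  gt <- lapply(c("((a,b),(c,d));", "((a,b),(c,d));", "((a,c),(b,d));"),
               parse_newick)
  tab <- observed_cf(gt)
  expect_equal(nrow(tab), 1L)
  expect_equal(as.numeric(tab[1, 5:7]), c(2 / 3, 1 / 3, 0))
  expect_equal(tab$ngenes, 3L)
})

test_that("observed CFs are invariant to gene-tree order and rooting", {
  net <- sim_net_retry(6, 0, seed = 11)
  gt <- simulate_gene_trees(net, 50, seed = 12)
  t1 <- observed_cf(gt)
  t2 <- observed_cf(rev(gt))
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  rerooted <- lapply(gt, function(p) ape::root(p, outgroup = "t3",
                                               resolve.root = TRUE))
  t3 <- observed_cf(rerooted, taxa = attr(t1, "taxa"))
  expect_equal(as.matrix(as.data.frame(t1)[5:7]),
               as.matrix(as.data.frame(t3)[5:7]))
})

test_that("gene trees restricted from larger trees count like quartet trees", {
  gt5 <- lapply(c("((a,b),((c,d),e));", "(((a,e),b),(c,d));",
                  "((a,c),((b,d),e));"), parse_newick)
  tab <- observed_cf(gt5, quartets = matrix(c("a", "b", "c", "d"), 1))
  expect_equal(as.numeric(tab[1, 5:7]), c(2 / 3, 1 / 3, 0))
  # gene trees missing one of the four taxa are excluded from ngenes
  gt4 <- c(gt5, list(parse_newick("((a,b),(c,e));")))
  tab2 <- observed_cf(gt4, quartets = matrix(c("a", "b", "c", "d"), 1),
                      taxa = letters[1:5])
  expect_equal(tab2$ngenes, 3L)
})

test_that("observed CFs converge to the coalescent closed form", {
  net <- quartet_tree_net(1.0)
  gt <- simulate_gene_trees(net, 1e4, seed = 77)
  tab <- observed_cf(gt)
  expected <- c(1 - 2 / 3 * exp(-1), exp(-1) / 3, exp(-1) / 3)
  se <- sqrt(expected * (1 - expected) / 1e4)
  expect_true(all(abs(as.numeric(tab[1, 5:7]) - expected) < 3 * se))
})

test_that("CF table CSV round-trips and rejects malformed rows", {
  net <- sim_net_retry(10, 0, seed = 13)
  gt <- simulate_gene_trees(net, 30, seed = 14)
  tab <- observed_cf(gt)
  expect_equal(nrow(tab), 210L)
  path <- tempfile(fileext = ".csv")
  write_cf_table(tab, path)
  rt <- read_cf_table(path)
  expect_equal(as.data.frame(tab), as.data.frame(rt), tolerance = 1e-12)

  # permuted row order on disk canonicalises to the same table
  df <- read.csv(path)
  df <- df[rev(seq_len(nrow(df))), ]
  path2 <- tempfile(fileext = ".csv")
  write.csv(df, path2, row.names = FALSE)
  expect_equal(as.data.frame(read_cf_table(path2)), as.data.frame(tab),
               tolerance = 1e-12)

  # taxa out of order within a row: CF columns are permuted along
  df2 <- read.csv(path)
  df2[1, 1:4] <- df2[1, c(3, 1, 4, 2)]
  df2[1, 5:7] <- df2[1, c(5, 7, 6)]  # 12|34 stays 12|34 under (3,1,4,2)? checked below
  path3 <- tempfile(fileext = ".csv")
  write.csv(df2, path3, row.names = FALSE)
  rt3 <- read_cf_table(path3)
  expect_equal(sort(as.numeric(rt3[1, 5:7])), sort(as.numeric(df2[1, 5:7])))

  # CFs not summing to 1 are rejected with the row number
  df3 <- read.csv(path)
  df3[2, 5:7] <- c(0.5, 0.5, 0.5)
  path4 <- tempfile(fileext = ".csv")
  write.csv(df3, path4, row.names = FALSE)
  expect_error(read_cf_table(path4), "row 2")

  # duplicated 4-taxon sets are rejected
  df4 <- read.csv(path)
  df4[2, ] <- df4[1, ]
  path5 <- tempfile(fileext = ".csv")
  write.csv(df4, path5, row.names = FALSE)
  expect_error(read_cf_table(path5), "duplicate")

  expect_error(read_cf_table(path) -> ok, NA)
  df5 <- read.csv(path)[, -8]
  path6 <- tempfile(fileext = ".csv")
  write.csv(df5, path6, row.names = FALSE)
  expect_error(read_cf_table(path6), "ngenes")
})

test_that("within-row taxon sorting permutes the CF triple coherently", {
  # build one quartet with distinct CFs, write it with taxa scrambled, and
  # check against the CF computed directly on the sorted quartet
  gt <- lapply(c("((a,b),(c,d));", "((a,c),(b,d));", "((a,b),(c,d));"),
               parse_newick)
  tab <- observed_cf(gt)  # a,b,c,d: (2/3, 1/3, 0)
  path <- tempfile(fileext = ".csv")
  # write scrambled: taxa (b, a, d, c): split b a | d c == ab|cd stays CF1
  writeLines(c("taxon1,taxon2,taxon3,taxon4,CF12_34,CF13_24,CF14_23,ngenes",
               "b,a,d,c,0.6666667,0.3333333,0,3"), path)
  rt <- read_cf_table(path)
  expect_equal(as.numeric(rt[1, 5:7]), as.numeric(tab[1, 5:7]),
               tolerance = 1e-6)
  # taxa (a, c, b, d): split ac|bd is the new 12|34, so CF1 <-> CF2 swap
  writeLines(c("taxon1,taxon2,taxon3,taxon4,CF12_34,CF13_24,CF14_23,ngenes",
               "a,c,b,d,0.3333333,0.6666667,0,3"), path)
  rt2 <- read_cf_table(path)
  expect_equal(as.numeric(rt2[1, 5:7]), as.numeric(tab[1, 5:7]),
               tolerance = 1e-6)
})

test_that("quartet subsampling is exact, seeded, and pure", {
  net <- sim_net_retry(10, 0, seed = 15)
  gt <- simulate_gene_trees(net, 20, seed = 16)
  tab <- observed_cf(gt)
  sub <- subsample_quartets(tab, 0.5, seed = 42)
  expect_equal(nrow(sub), 105L)               # ceiling(210 * 0.5)
  expect_equal(nrow(subsample_quartets(tab, 0.999, seed = 1)), 210L)
  expect_identical(subsample_quartets(tab, 1.0, seed = 99), tab)

  sub2 <- subsample_quartets(tab, 0.5, seed = 42)
  expect_identical(sub, sub2)
  sub3 <- subsample_quartets(tab, 0.5, seed = 43)
  expect_false(identical(as.data.frame(sub), as.data.frame(sub3)))

  # the caller's RNG stream is untouched
  set.seed(7); r1 <- runif(3)
  set.seed(7); invisible(subsample_quartets(tab, 0.3, seed = 5)); r2 <- runif(3)
  expect_identical(r1, r2)

  expect_error(subsample_quartets(tab, 0, seed = 1), "prop")
  expect_error(subsample_quartets(tab, 1.5, seed = 1), "prop")
})

test_that("misfit weights follow W = sum |X - CF|", {
  tab <- one_quartet_table(c(1, 0, 0))
  expect_equal(quartet_weights(tab, matrix(c(1/3, 1/3, 1/3), 1)), 4 / 3)
  expect_equal(quartet_weights(tab, matrix(c(1, 0, 0), 1)), 0)
  tab2 <- one_quartet_table(c(0, 1, 0))
  expect_equal(quartet_weights(tab2, matrix(c(1, 0, 0), 1)), 2)  # the maximum
  # weights live in [0, 2] on random simplex points
  set.seed(8)
  for (i in 1:20) {
    x <- rexp(3); x <- x / sum(x)
    p <- rexp(3); p <- p / sum(p)
    w <- quartet_weights(one_quartet_table(x), matrix(p, 1))
    expect_gte(w, 0); expect_lte(w, 2)
  }
  expect_error(quartet_weights(tab, matrix(0.5, 2, 3)), "aligned")
})
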