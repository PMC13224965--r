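# Fixture builders shared across the test files.  Everything is generated in
# code; seeds are fixed so the suite is deterministic.

# A quartet species tree ((a,b),(c,d)) with internal length t (split across
# the two root edges) and pendant lengths 1.
quartet_tree_net <- function(t, taxa = c("a", "b", "c", "d")) {
  parse_enewick(sprintf("((%s:1,%s:1):%g,(%s:1,%s:1):%g);",
                        taxa[1], taxa[2], t / 2, taxa[3], taxa[4], t / 2))
}

# A 4-cycle quarnet with hybrid leaf a; displayed trees ab|cd
# (internal 1.0, weight gamma) and ac|bd (internal 0.5, weight 1 - gamma).
cycle_quarnet <- function(gamma = 0.3) {
  parse_enewick(sprintf(
    "(((a)#H1:0::%g,b:1):1,((#H1:0::%g,c:1):0.5,d:1):0);",
    gamma, 1 - gamma))
}

# Simulate a level-1 network, retrying seeds when reticulation placement is
# infeasible for the drawn tree shape.
sim_net_retry <- function(n, h, mean_bl = 1.5, gamma = 0.5, seed = 1) {
  for (s in seed + (0:25) * 1009) {
    net <- tryCatch({
      tr <- yule_tree(n, seed = qcfnet:::mix_seed(s, 11L))
      if (h > 0) tr <- add_reticulations(tr, h, gamma = gamma,
                                         seed = qcfnet:::mix_seed(s, 22L),
                                         max_tries = 300L)
      scale_branch_lengths(tr, mean_bl)
    }, error = function(e) NULL)
    if (!is.null(net)) return(net)
  }
  stop("could not simulate a network with n=", n, ", h=", h)
}

# Noiseless CF table: the exact expected CFs of `net` presented as data.
noiseless_table <- function(net, ngenes = 1000L) {
  qs <- enumerate_quartets(net$taxa)
  ex <- expected_cf_network(net, qs)
  qcfnet:::new_cf_table(data.frame(
    taxon1 = qs[, 1], taxon2 = qs[, 2], taxon3 = qs[, 3], taxon4 = qs[, 4],
    CF12_34 = ex[, 1], CF13_24 = ex[, 2], CF14_23 = ex[, 3],
    ngenes = ngenes, stringsAsFactors = FALSE), net$taxa)
}

# One-row CF table on {a,b,c,d} with a given observed triple.
one_quartet_table <- function(x, taxa = c("a", "b", "c", "d"), ngenes = 100L) {
  qcfnet:::new_cf_table(data.frame(
    taxon1 = taxa[1], taxon2 = taxa[2], taxon3 = taxa[3], taxon4 = taxa[4],
    CF12_34 = x[1], CF13_24 = x[2], CF14_23 = x[3], ngenes = ngenes,
    stringsAsFactors = FALSE), taxa)
}

expect_valid <- function(net) expect_length(validate_network(net), 0)
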