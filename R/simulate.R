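# Fixture generation: Yule species trees, level-1 reticulation insertion,
# branch-length scaling to a target mean (the knob controlling incomplete
# lineage sorting), and exact MSNC gene-tree simulation.

#' Simulate a Yule species tree
#'
#' Pure-birth tree with `n` extant taxa (birth rate 1; the rate is
#' irrelevant once branch lengths are rescaled with
#' [scale_branch_lengths()]).  Deterministic given `seed`.
#'
#' @param n Number of taxa (`>= 4`).
#' @param seed Integer seed.
#' @return A `qcf_network` with `h = 0` and taxa `t1..tn`.
#' @export
yule_tree <- function(n, seed) {
  if (n < 4L) stop("need at least 4 taxa")
  phy <- with_local_seed(seed, ape::rphylo(n, birth = 1, death = 0))
  phylo_to_net(phy)
}

# the minor hybrid edge of each hybrid node (smaller gamma; ties broken by
# shorter length, then first)
minor_edges <- function(net) {
  net <- net_refresh(net)
  out <- integer(0)
  for (hn in which(net$indeg == 2L)) {
    es <- which(net$child == hn)
    g <- net$gamma[es]
    l <- ifelse(is.na(net$length[es]), Inf, net$length[es])
    o <- order(g, l)
    out <- c(out, es[o[1L]])
  }
  out
}

#' Add level-1 reticulations at arbitrary positions
#'
#' Inserts `h` reticulations one at a time by sampling an ordered pair of
#' distinct edges (origin, target) uniformly at random, subdividing both and
#' connecting them with a new minor hybrid edge of length 0 and inheritance
#' probability `gamma`; placements violating the level-1 / no-2-cycle /
#' no-3-cycle rules are rejected and resampled (up to `max_tries` attempts
#' per reticulation).
#'
#' @param tree A valid `qcf_network` (typically from [yule_tree()]).
#' @param h Number of reticulations to add (`>= 1`).
#' @param gamma Inheritance probability of each new minor hybrid edge.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling bound per reticulation.
#' @return A valid `qcf_network` with `tree$h + h` hybrid nodes.
#' @export
add_reticulations <- function(tree, h, gamma = 0.5, seed = 1L,
                              max_tries = 10000L) {
  stopifnot(h >= 1, gamma > 0, gamma < 1)
  net <- tree
  with_local_seed(seed, {
    for (i in seq_len(h)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- net_refresh(net)
        E <- n_edges(cand)
        eo <- sample.int(E, 1L)
        et <- sample.int(E, 1L)
        if (et == eo) next
        s1 <- subdivide_edge(cand, et, frac = runif(1L))
        cand <- s1$net; tnode <- s1$node
        s2 <- subdivide_edge(cand, eo, frac = runif(1L))
        cand <- s2$net; onode <- s2$node
        cand$parent <- c(cand$parent, onode)
        cand$child <- c(cand$child, tnode)
        cand$length <- c(cand$length, 0)
        cand$gamma <- c(cand$gamma, gamma)
        cand$gamma[s1$upper] <- 1 - gamma
        cand <- tryCatch(clean_network(net_refresh(cand)),
                         error = function(e) NULL)
        if (is.null(cand) || length(validate_network(cand))) next
        net <- cand; placed <- TRUE; break
      }
      if (!placed)
        stop("could not place reticulation ", i, " after ", max_tries,
             " attempts; try a smaller h")
    }
  })
  net_refresh(net)
}

#' Scale branch lengths to a target mean
#'
#' Multiplies all branch lengths except minor hybrid edges (which stay at 0)
#' by one constant so that their mean equals `target_mean`.  Smaller means
#' produce more incomplete lineage sorting (2.0 / 1.0 / 0.5 = low / medium /
#' high).
#'
#' @param net A `qcf_network` with positive lengths on non-minor edges.
#' @param target_mean Target mean branch length in coalescent units.
#' @return The rescaled network.  Idempotent at a fixed target.
#' @export
scale_branch_lengths <- function(net, target_mean) {
  stopifnot(target_mean > 0)
  minor <- minor_edges(net)
  sel <- setdiff(seq_len(n_edges(net)), minor)
  m <- mean(net$length[sel], na.rm = TRUE)
  if (!is.finite(m) || m <= 0) stop("cannot scale: non-positive mean branch length")
  net$length[sel] <- net$length[sel] * (target_mean / m)
  net
}

#' Simulate gene trees under the multispecies network coalescent
#'
#' One lineage is sampled per taxon; within every edge (population) of
#' duration `l` coalescent units each lineage pair coalesces at rate 1; at a
#' hybrid node every lineage independently follows a parent edge with
#' probability equal to that edge's inheritance probability; remaining
#' lineages coalesce in an unbounded population above the root.
#' Deterministic given `seed`.
#'
#' @param net A valid `qcf_network` with branch lengths (a missing length is
#'   an error if the edge can carry more than one lineage).
#' @param g Number of gene trees.
#' @param seed Integer seed.
#' @return A list (`multiPhylo`) of `g` gene trees on the network's taxa.
#' @export
simulate_gene_trees <- function(net, g, seed) {
  if (g == 0L) return(structure(list(), class = "multiPhylo"))
  net <- net_refresh(net)
  recs <- with_local_seed(seed,
    cpp_msnc_genetrees(net$parent, net$child, net$length, net$gamma,
                       length(net$labels), net$root, net$leaves,
                       as.integer(g)))
  taxa <- net$taxa
  out <- lapply(recs, merges_to_phylo, taxa = taxa)
  class(out) <- "multiPhylo"
  out
}

# Build an ape phylo from a coalescent merge record: rows (a, b, new id,
# height), lineages 1..n being the taxa in sorted order.
merges_to_phylo <- function(m, taxa) {
  n <- length(taxa)
  stopifnot(nrow(m) == n - 1L)
  heights <- c(rep(0, n), m[, 4L])
  # internal id n+j -> ape id 2n-j (so the root, j = n-1, becomes n+1)
  ape_id <- function(id) ifelse(id <= n, id, 2L * n - (id - n))
  parent <- ape_id(rep(m[, 3L], each = 2L))
  child_raw <- as.vector(t(m[, 1:2]))
  child <- ape_id(child_raw)
  elen <- heights[rep(m[, 3L], each = 2L)] - heights[child_raw]
  phy <- structure(list(edge = cbind(as.integer(parent), as.integer(child)),
                        edge.length = pmax(elen, 0),
                        tip.label = taxa, Nnode = n - 1L),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Simulate a level-1 species network
#'
#' The full fixture pipeline: a Yule tree on `n` taxa, `h` level-1
#' reticulations at arbitrary positions (minor hybrid edges of length 0,
#' inheritance probability `gamma`), and branch lengths rescaled so that the
#' mean over non-minor edges equals `mean_branch_length`.
#'
#' @param n Number of taxa (`>= 4`).
#' @param h Number of reticulations (`>= 0`).
#' @param mean_branch_length Target mean branch length (2.0 / 1.0 / 0.5 =
#'   low / medium / high incomplete lineage sorting).
#' @param gamma Inheritance probability of the minor hybrid edges.
#' @param seed Integer seed.
#' @return A valid `qcf_network`.
#' @export
simulate_network <- function(n, h = 1L, mean_branch_length = 2.0,
                             gamma = 0.5, seed = 1L) {
  net <- yule_tree(n, seed = mix_seed(seed, 11L))
  if (h > 0L)
    net <- add_reticulations(net, h, gamma = gamma, seed = mix_seed(seed, 22L))
  scale_branch_lengths(net, mean_branch_length)
}
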