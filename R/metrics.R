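# Topological accuracy: hardwired cluster dissimilarity (HWCD).

#' Hardwired clusters of a network
#'
#' Roots the semi-directed network at the edge incident to `root_taxon`
#' (orienting all tree edges away from that leaf while hybrid edges keep
#' their direction) and returns, for every edge, the set of leaves reachable
#' through its child.  Duplicate clusters collapse into a set.
#'
#' @param net A valid `qcf_network` (or [ape::phylo]).
#' @param root_taxon A leaf label at which to root.  Must be a feasible root
#'   position (a leaf hanging below a hybrid node is not).
#' @return A character vector of clusters, each a comma-joined sorted taxon
#'   list.
#' @export
hardwired_clusters <- function(net, root_taxon) {
  if (inherits(net, "phylo")) net <- phylo_to_net(net)
  net <- net_refresh(net)
  ori <- orient_from_leaf(net, root_taxon)
  N <- length(net$labels)
  E <- n_edges(net)
  kids <- split(seq_len(E), factor(ori$parent, levels = seq_len(N)))
  memo <- vector("list", N)
  desc <- function(v) {
    if (!is.null(memo[[v]])) return(memo[[v]])
    out <- if (!is.na(net$labels[v])) net$labels[v] else character(0)
    for (e in kids[[v]]) out <- c(out, desc(ori$child[e]))
    out <- sort(unique(out))
    memo[[v]] <<- out
    out
  }
  cl <- vapply(seq_len(E), function(e) paste(desc(ori$child[e]), collapse = ","),
               "")
  sort(unique(cl[nzchar(cl)]))
}

#' Hardwired cluster dissimilarity
#'
#' Size of the symmetric difference between the hardwired cluster sets of
#' two networks on the same taxa, both rooted at `root_taxon`.  Symmetric,
#' nonnegative, and 0 for isomorphic networks; for unrooted binary trees it
#' equals twice the Robinson-Foulds split distance, with maximum `2(n-3)`.
#'
#' @param net1,net2 `qcf_network` (or [ape::phylo]) objects on identical
#'   taxon sets.
#' @param root_taxon Leaf at which both are rooted (for trees the value does
#'   not depend on the choice).  Defaults to the first taxon.
#' @return Integer dissimilarity.
#' @export
hwcd <- function(net1, net2, root_taxon = NULL) {
  if (inherits(net1, "phylo")) net1 <- phylo_to_net(net1)
  if (inherits(net2, "phylo")) net2 <- phylo_to_net(net2)
  if (!identical(net1$taxa, net2$taxa))
    stop("networks are on different taxon sets")
  if (is.null(root_taxon)) root_taxon <- net1$taxa[1L]
  c1 <- hardwired_clusters(net1, root_taxon)
  c2 <- hardwired_clusters(net2, root_taxon)
  length(setdiff(c1, c2)) + length(setdiff(c2, c1))
}

#' Normalized tree dissimilarity
#'
#' HWCD between two trees divided by its maximum possible value `2(n-3)`;
#' 0 iff the trees are topologically identical, 1 when they share no
#' nontrivial split.
#'
#' @param tree1,tree2 Trees (`qcf_network` with `h = 0` or [ape::phylo]) on
#'   the same `n >= 4` taxa.
#' @return A value in `[0, 1]`.
#' @export
normalized_hwcd <- function(tree1, tree2) {
  if (inherits(tree1, "phylo")) tree1 <- phylo_to_net(tree1)
  if (inherits(tree2, "phylo")) tree2 <- phylo_to_net(tree2)
  if (tree1$h > 0L || tree2$h > 0L)
    stop("normalized HWCD is defined for trees")
  n <- length(tree1$taxa)
  if (n < 4L) stop("need at least 4 taxa")
  hwcd(tree1, tree2) / (2 * (n - 3))
}

# Root taxon usable for both networks (first leaf that is a feasible root
# position in both); used when comparing an estimated and a true network.
common_root_taxon <- function(net1, net2) {
  for (tx in net1$taxa) {
    ok <- !inherits(try(orient_from_leaf(net1, tx), silent = TRUE), "try-error") &&
          !inherits(try(orient_from_leaf(net2, tx), silent = TRUE), "try-error")
    if (ok) return(tx)
  }
  stop("no common feasible root taxon")
}
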