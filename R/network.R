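# Semi-directed level-1 phylogenetic networks.
#
# Internal representation: a rooted edge list over nodes 1..N.
#   parent, child : integer vectors (one entry per edge, parent -> child)
#   length        : branch lengths in coalescent units (NA = missing)
#   gamma         : inheritance probability of the edge (NA on tree edges);
#                   the two edges entering a hybrid node carry gamma and
#                   1 - gamma
#   labels        : character vector over nodes; NA for internal nodes
#   root          : the (unique) node with in-degree 0
# Semantics are semi-directed: all scores and distances are invariant to the
# root position; the rooted form is kept because the coalescent process and
# hybrid-edge directions need one.

#' Construct a phylogenetic network object
#'
#' Builds a semi-directed level-1 network from a rooted edge list.  Most users
#' will create networks with [parse_enewick()] or [simulate_network()] rather
#' than calling this constructor directly.
#'
#' @param parent,child Integer vectors of node ids (one entry per edge,
#'   directed parent to child).
#' @param length Numeric branch lengths in coalescent units (`NA` = missing).
#' @param gamma Numeric inheritance probabilities; `NA` on tree edges.  The
#'   two edges entering a hybrid node must carry `gamma` and `1 - gamma`.
#' @param labels Character vector of node labels; `NA` for internal nodes.
#' @param check If `TRUE`, basic structural sanity is asserted.
#' @return An object of class `qcf_network`.
#' @seealso [validate_network()], [parse_enewick()], [write_enewick()]
#' @export
qcf_network <- function(parent, child, length = NULL, gamma = NULL,
                        labels, check = TRUE) {
  E <- length(parent)
  if (is.null(length)) length <- rep(NA_real_, E)
  if (is.null(gamma)) gamma <- rep(NA_real_, E)
  net <- structure(
    list(parent = as.integer(parent), child = as.integer(child),
         length = as.double(length), gamma = as.double(gamma),
         labels = as.character(labels)),
    class = "qcf_network")
  net <- net_refresh(net)
  if (check) {
    if (anyNA(net$parent) || anyNA(net$child))
      stop("edge endpoints must be non-missing integers")
    if (length(net$root) != 1L)
      stop("network must have exactly one root (node with in-degree 0)")
    if (anyDuplicated(stats::na.omit(net$labels)))
      stop("duplicate taxon labels")
  }
  net
}

# Recompute derived fields (degrees, hybrid flags, h, taxa, root).
net_refresh <- function(net) {
  N <- length(net$labels)
  indeg <- tabulate(net$child, N)
  outdeg <- tabulate(net$parent, N)
  net$indeg <- indeg
  net$outdeg <- outdeg
  net$hybrid <- indeg[net$child] == 2L
  net$h <- sum(indeg == 2L)
  roots <- which(indeg == 0L & outdeg > 0L)
  if (length(roots) == 0L) roots <- which(indeg == 0L)
  net$root <- roots
  leaves <- which(outdeg == 0L & !is.na(net$labels))
  net$leaves <- leaves[order(net$labels[leaves])]
  net$taxa <- net$labels[net$leaves]
  net
}

n_edges <- function(net) length(net$parent)
n_nodes <- function(net) length(net$labels)

#' @export
print.qcf_network <- function(x, ...) {
  cat(sprintf("Semi-directed level-1 network: %d taxa, %d reticulation%s, %d edges\n",
              length(x$taxa), x$h, if (x$h == 1L) "" else "s", n_edges(x)))
  enw <- tryCatch(write_enewick(x), error = function(e) NULL)
  if (!is.null(enw)) cat(" ", enw, "\n", sep = "")
  invisible(x)
}

# Renumber nodes 1..N' after deletions marked by `keep_edge` (logical over
# edges) and implicit node removal (nodes with no incident kept edge and not
# the designated root).
net_compact <- function(net, keep_edge) {
  p <- net$parent[keep_edge]; c <- net$child[keep_edge]
  used <- sort(unique(c(p, c)))
  map <- integer(length(net$labels)); map[used] <- seq_along(used)
  out <- structure(
    list(parent = map[p], child = map[c],
         length = net$length[keep_edge], gamma = net$gamma[keep_edge],
         labels = net$labels[used]),
    class = "qcf_network")
  if (!is.null(net$comp)) out$comp <- net$comp[keep_edge]
  net_refresh(out)
}

# Iteratively prune unsampled pendant material, suppress in-1/out-1 nodes
# (edge lengths add; provenance concatenates), and drop a dangling root.
# `keep` are the taxon labels to retain.  With provenance=TRUE each edge
# carries `comp`, the integer ids of the original edges it is made of.
clean_network <- function(net, keep = net$taxa, provenance = FALSE) {
  if (provenance && is.null(net$comp)) net$comp <- as.list(seq_len(n_edges(net)))
  repeat {
    net <- net_refresh(net)
    N <- length(net$labels)
    keep_node <- rep(TRUE, N)
    sampled <- !is.na(net$labels) & net$labels %in% keep
    # hybrid flags from current in-degrees: an edge into an in-degree-1 node
    # is a tree edge even if it used to be a hybrid edge
    single_in <- net$indeg[net$child] == 1L
    if (any(single_in & !is.na(net$gamma))) net$gamma[single_in] <- NA_real_

    # 1. drop childless nodes that are not sampled leaves (and their in-edges)
    dead <- which(net$outdeg == 0L & !sampled)
    if (length(dead)) {
      keep_edge <- !(net$child %in% dead)
      net <- net_compact(net, keep_edge)
      next
    }
    # 2. drop a root with a single child (dangling stub in unrooted terms)
    rt <- net$root
    if (length(rt) == 1L && net$outdeg[rt] == 1L) {
      keep_edge <- net$parent != rt
      net <- net_compact(net, keep_edge)
      next
    }
    # 3. suppress one in-1/out-1 node
    mid <- which(net$indeg == 1L & net$outdeg == 1L & is.na(net$labels))
    if (length(mid)) {
      v <- mid[1L]
      ei <- which(net$child == v)
      eo <- which(net$parent == v)
      net$parent[eo] <- net$parent[ei]
      net$length[eo] <- net$length[eo] + net$length[ei]
      # gamma: the merged edge inherits whichever half carried one (the
      # in-half cannot, since v has in-degree 1 => tree edge)
      if (!is.na(net$gamma[ei]) && is.na(net$gamma[eo]))
        net$gamma[eo] <- net$gamma[ei]
      if (!is.null(net$comp)) net$comp[[eo]] <- c(net$comp[[ei]], net$comp[[eo]])
      net <- net_compact(net, seq_len(n_edges(net)) != ei)
      next
    }
    break
  }
  net_refresh(net)
}

# Topological order of nodes (parents before children); NULL if cyclic.
topo_order <- function(net) {
  N <- length(net$labels)
  indeg <- tabulate(net$child, N)
  present <- tabulate(net$child, N) + tabulate(net$parent, N) > 0L
  if (length(net$root) == 1L) present[net$root] <- TRUE
  out_list <- split(net$child, factor(net$parent, levels = seq_len(N)))
  queue <- which(indeg == 0L & present)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (w in out_list[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(ord) != sum(present)) return(NULL)
  ord
}

#' Validate a network against the level-1 model assumptions
#'
#' Checks the structural rules under which quartet concordance factors are
#' computed: node degrees (leaves 1; internal tree nodes 3; hybrid nodes
#' in-degree 2, out-degree 1), acyclicity of the rooted form, the level-1
#' condition (at most one hybrid node per biconnected component), the absence
#' of 2-cycles and 3-cycles, inheritance probabilities in (0,1) summing to 1
#' at every hybrid node.
#'
#' @param net A `qcf_network`.
#' @return A character vector of violation codes; empty when the network is
#'   valid.  Codes: `"degree"`, `"cyclic"`, `"not_level_one"`, `"two_cycle"`,
#'   `"three_cycle"`, `"gamma_sum"`, `"gamma_range"`, `"unlabeled_leaf"`.
#' @examples
#' net <- parse_enewick("((a,(b)#H1:::0.3),(#H1,(c,d)));")
#' validate_network(net)  # character(0)
#' @export
validate_network <- function(net) {
  v <- character(0)
  net <- net_refresh(net)
  N <- length(net$labels)
  indeg <- net$indeg; outdeg <- net$outdeg
  present <- indeg + outdeg > 0L

  if (any(outdeg == 0L & present & is.na(net$labels))) v <- c(v, "unlabeled_leaf")
  rt <- which(indeg == 0L & present)
  ok_deg <- TRUE
  if (length(rt) != 1L) ok_deg <- FALSE else {
    if (outdeg[rt] != 2L && !(outdeg[rt] == 1L && N == 2L)) ok_deg <- FALSE
    others <- setdiff(which(present), rt)
    io <- cbind(indeg[others], outdeg[others])
    ok <- (io[, 1] == 1L & io[, 2] == 0L) |  # leaf
          (io[, 1] == 1L & io[, 2] == 2L) |  # internal tree node
          (io[, 1] == 2L & io[, 2] == 1L)    # hybrid
    if (!all(ok)) ok_deg <- FALSE
  }
  if (!ok_deg) v <- c(v, "degree")

  if (is.null(topo_order(net))) v <- c(v, "cyclic")

  # gammas at hybrid nodes
  hyb <- which(indeg == 2L)
  for (hn in hyb) {
    g <- net$gamma[net$child == hn]
    if (anyNA(g) || length(g) != 2L) { v <- c(v, "gamma_sum"); next }
    if (abs(sum(g) - 1) > 1e-9) v <- c(v, "gamma_sum")
    if (any(g <= 0 | g >= 1)) v <- c(v, "gamma_range")
  }

  # 2-cycles: parallel edges between the same unordered node pair
  key <- paste(pmin(net$parent, net$child), pmax(net$parent, net$child))
  if (anyDuplicated(key)) v <- c(v, "two_cycle")

  # level-1 and 3-cycles via biconnected components of the undirected graph
  # (skipped for trees: without a hybrid node an acyclic rooted graph has no
  # undirected cycle)
  if (net$h > 0L && n_edges(net) > 0L && !("degree" %in% v)) {
    g <- igraph::graph_from_edgelist(cbind(net$parent, net$child), directed = FALSE)
    bc <- igraph::biconnected_components(g)
    for (comp in bc$components) {
      ids <- as.integer(comp)
      if (length(ids) <= 2L) next      # a single edge
      nh <- sum(indeg[ids] == 2L)
      if (nh > 1L) v <- c(v, "not_level_one")
      if (length(ids) == 3L) v <- c(v, "three_cycle")
    }
  }
  unique(v)
}

# Convert a tree-shaped network (h = 0) to an ape "phylo".
net_to_phylo <- function(net) {
  net <- clean_network(net)
  if (net$h > 0L) stop("net_to_phylo requires a network without reticulations")
  leaves <- net$leaves
  N <- length(net$labels)
  ntip <- length(leaves)
  map <- integer(N)
  map[leaves] <- seq_len(ntip)
  internal <- setdiff(which(net$indeg + net$outdeg > 0L), leaves)
  internal <- c(net$root, setdiff(internal, net$root))
  map[internal] <- ntip + seq_along(internal)
  phy <- structure(list(
    edge = cbind(map[net$parent], map[net$child]),
    edge.length = net$length,
    tip.label = net$labels[leaves],
    Nnode = length(internal)), class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

# Convert an ape "phylo" (rooted, binary) to a qcf_network.
phylo_to_net <- function(phy) {
  phy <- ape::reorder.phylo(phy, "cladewise")
  if (!ape::is.rooted(phy)) phy <- ape::root(phy, outgroup = phy$tip.label[1L],
                                             resolve.root = TRUE)
  if (!ape::is.binary(phy)) phy <- ape::multi2di(phy)
  ntip <- length(phy$tip.label)
  N <- ntip + phy$Nnode
  labels <- c(phy$tip.label, rep(NA_character_, phy$Nnode))
  len <- phy$edge.length
  if (is.null(len)) len <- rep(NA_real_, nrow(phy$edge))
  qcf_network(phy$edge[, 1], phy$edge[, 2], len, NULL, labels)
}

#' Trees displayed by a network
#'
#' Enumerates the `2^h` trees obtained by keeping exactly one parent edge per
#' hybrid node, pruning the dropped edges and suppressing the resulting
#' degree-2 nodes (branch lengths of merged edges are summed).  The
#' probability of each displayed tree is the product of the inheritance
#' probabilities of the kept hybrid edges; the probabilities sum to 1.
#'
#' @param net A valid `qcf_network`.
#' @return A list with one element per displayed tree, each a list with
#'   components `tree` (an [ape::phylo] object) and `prob`.
#' @examples
#' net <- parse_enewick("((a,(b)#H1:::0.3),(#H1,(c,d)));")
#' dt <- displayed_trees(net)
#' sapply(dt, `[[`, "prob")  # 0.7 0.3
#' @export
displayed_trees <- function(net) {
  net <- net_refresh(net)
  hyb_nodes <- which(net$indeg == 2L)
  if (length(hyb_nodes) == 0L)
    return(list(list(tree = net_to_phylo(net), prob = 1.0)))
  in_edges <- lapply(hyb_nodes, function(hn) which(net$child == hn))
  choices <- expand.grid(rep(list(1:2), length(hyb_nodes)))
  out <- vector("list", nrow(choices))
  for (i in seq_len(nrow(choices))) {
    drop <- integer(0); prob <- 1.0
    for (j in seq_along(hyb_nodes)) {
      es <- in_edges[[j]]
      kept <- es[choices[i, j]]
      drop <- c(drop, setdiff(es, kept))
      prob <- prob * net$gamma[kept]
    }
    sub <- net_compact(net, !(seq_len(n_edges(net)) %in% drop))
    sub$gamma[] <- NA_real_
    sub <- clean_network(sub)
    out[[i]] <- list(tree = net_to_phylo(sub), prob = prob)
  }
  out
}

# Orient every edge away from the leaf `taxon` (hybrid edges keep their fixed
# direction).  Returns a list(parent, child) of the reoriented edge list, or
# stops if the leaf is not a feasible root position (e.g. it hangs below a
# hybrid node, which would force a hybrid edge to reverse).
orient_from_leaf <- function(net, taxon) {
  net <- net_refresh(net)
  leaf <- net$leaves[match(taxon, net$taxa)]
  if (is.na(leaf)) stop(sprintf("taxon '%s' is not a leaf of the network", taxon))
  E <- n_edges(net)
  N <- length(net$labels)
  hyb_edge <- net$hybrid
  np <- net$parent; nc <- net$child
  dir_p <- integer(E); dir_c <- integer(E)  # new orientation
  fixed <- hyb_edge                          # hybrid edges keep direction
  dir_p[fixed] <- np[fixed]; dir_c[fixed] <- nc[fixed]
  oriented <- fixed
  # BFS from the leaf: tree edges orient away from it; hybrid edges are
  # traversable only parent -> child.
  inc <- vector("list", N)
  for (e in seq_len(E)) {
    inc[[np[e]]] <- c(inc[[np[e]]], e)
    inc[[nc[e]]] <- c(inc[[nc[e]]], e)
  }
  visited <- rep(FALSE, N); visited[leaf] <- TRUE
  queue <- leaf
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (e in inc[[v]]) {
      w <- if (np[e] == v) nc[e] else np[e]
      if (hyb_edge[e]) {
        if (nc[e] == v) next      # cannot travel up a hybrid edge
      } else if (!oriented[e]) {
        if (net$indeg[w] == 2L)
          stop("invalid root position: a tree edge would enter a hybrid node")
        dir_p[e] <- v; dir_c[e] <- w; oriented[e] <- TRUE
      } else if (dir_c[e] == v) next
      if (!visited[w]) { visited[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  if (!all(visited[net$indeg + net$outdeg > 0L]))
    stop("invalid root position: network not fully reachable from that leaf")
  if (!all(oriented)) stop("invalid root position: orientation incomplete")
  list(parent = dir_p, child = dir_c)
}
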