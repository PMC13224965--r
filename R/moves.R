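# The five topological moves of the network search: nearest-neighbour
# interchange, addition of a reticulation, flipping the direction of a
# reticulation edge, and moving the origin or the target of a reticulation
# edge.  Every proposal is gated by validate_network(): candidates that
# violate the level-1 / no-2-cycle / no-3-cycle / degree rules are rejected
# (returned as NULL) and count as failed attempts in the search.

move_types <- c("NNI", "add_reticulation", "flip_direction",
                "move_origin", "move_target")

# Split edge `e` at an interior point, returning the updated network and the
# id of the new degree-2 node.  The lower half keeps the hybrid annotation.
subdivide_edge <- function(net, e, frac = 0.5) {
  N <- length(net$labels)
  newn <- N + 1L
  net$labels <- c(net$labels, NA_character_)
  l <- net$length[e]
  lower <- if (is.na(l)) NA_real_ else l * (1 - frac)
  upper <- if (is.na(l)) NA_real_ else l * frac
  net$parent <- c(net$parent, newn)
  net$child <- c(net$child, net$child[e])
  net$length <- c(net$length, lower)
  net$gamma <- c(net$gamma, net$gamma[e])
  net$child[e] <- newn
  net$length[e] <- upper
  net$gamma[e] <- NA_real_
  list(net = net, node = newn, upper = e, lower = length(net$parent))
}

finish_move <- function(net, taxa0) {
  net <- tryCatch(clean_network(net_refresh(net)), error = function(e) NULL)
  if (is.null(net)) return(NULL)
  if (!identical(net$taxa, taxa0)) return(NULL)
  if (length(validate_network(net))) return(NULL)
  net
}

move_nni <- function(net, e) {
  u <- net$parent[e]; v <- net$child[e]
  if (net$hybrid[e] || net$outdeg[v] != 2L || net$outdeg[u] < 2L) return(NULL)
  kids <- which(net$parent == v)
  sib <- setdiff(which(net$parent == u), e)
  if (length(sib) == 0L) return(NULL)
  c_edge <- kids[sample.int(2L, 1L)]
  if (net$indeg[u] == 0L) {
    # u is the root: the unrooted edge runs v -- u -- z, so the swap partner
    # must be a child subtree of z (swapping the whole z side is a no-op)
    z <- net$child[sib[1L]]
    if (net$outdeg[z] != 2L) return(NULL)  # pendant edge in unrooted terms
    zkids <- which(net$parent == z)
    w_edge <- zkids[sample.int(2L, 1L)]
    net$parent[c_edge] <- z
    net$parent[w_edge] <- v
  } else {
    w_edge <- sib[1L]
    net$parent[c_edge] <- u
    net$parent[w_edge] <- v
  }
  net
}

move_add_reticulation <- function(net, e_origin, gamma0 = 0.5) {
  E <- n_edges(net)
  e_target <- sample.int(E, 1L)
  if (e_target == e_origin) return(NULL)
  s1 <- subdivide_edge(net, e_target)
  net <- s1$net; tnode <- s1$node
  s2 <- subdivide_edge(net, e_origin)
  net <- s2$net; onode <- s2$node
  net$parent <- c(net$parent, onode)
  net$child <- c(net$child, tnode)
  net$length <- c(net$length, 0)
  net$gamma <- c(net$gamma, gamma0)
  # the other parent edge of the new hybrid carries 1 - gamma
  net$gamma[s1$upper] <- 1 - gamma0
  net
}

move_flip_direction <- function(net, e) {
  if (!net$hybrid[e]) return(NULL)
  o <- net$parent[e]; t <- net$child[e]
  if (net$indeg[o] != 1L) return(NULL)  # origin must be a non-root tree node
  ep <- which(net$child == o)           # o's parent edge
  e2 <- setdiff(which(net$child == t), e)
  g <- net$gamma[e]
  net$parent[e] <- t; net$child[e] <- o
  net$gamma[e] <- g
  net$gamma[ep] <- 1 - g
  net$gamma[e2] <- NA_real_
  net
}

move_origin <- function(net, e) {
  if (!net$hybrid[e]) return(NULL)
  o <- net$parent[e]
  nbr <- setdiff(which(net$parent == o | net$child == o), e)
  if (length(nbr) == 0L) return(NULL)
  f <- nbr[sample.int(length(nbr), 1L)]
  s <- subdivide_edge(net, f)
  net <- s$net
  net$parent[e] <- s$node
  net
}

move_target <- function(net, e) {
  if (!net$hybrid[e]) return(NULL)
  t <- net$child[e]
  g <- net$gamma[e]
  nbr <- setdiff(which(net$parent == t | net$child == t), e)
  if (length(nbr) == 0L) return(NULL)
  f <- nbr[sample.int(length(nbr), 1L)]
  e2 <- setdiff(which(net$child == t), e)
  s <- subdivide_edge(net, f)
  net <- s$net
  net$child[e] <- s$node
  net$gamma[e] <- g
  net$gamma[s$upper] <- 1 - g
  net$gamma[e2] <- NA_real_
  net
}

#' Propose one topological rearrangement
#'
#' Applies one of the five search moves at the given focus edge and returns
#' the candidate network, or `NULL` when the focus admits no legal
#' rearrangement (including any candidate failing [validate_network()], e.g.
#' a 2-cycle or 3-cycle, which the search never proposes).  Destination
#' edges for `add_reticulation` (the target) and for `move_origin` /
#' `move_target` (the neighbour edge the attachment moves to) are drawn from
#' the current RNG stream.
#'
#' @param net A valid `qcf_network`.
#' @param move One of `"NNI"`, `"add_reticulation"`, `"flip_direction"`,
#'   `"move_origin"`, `"move_target"`.
#' @param focus Edge id acting as the focus of the move: the NNI edge, the
#'   origin edge for a new reticulation, or the reticulation (hybrid) edge
#'   for the last three moves.
#' @param gamma0 Inheritance probability assigned to a newly added
#'   reticulation edge.
#' @return A valid candidate `qcf_network`, or `NULL`.
#' @export
propose_move <- function(net, move, focus, gamma0 = 0.5) {
  move <- match.arg(move, move_types)
  if (!is.numeric(focus) || length(focus) != 1L || focus < 1L ||
      focus > n_edges(net))
    return(NULL)
  net <- net_refresh(net)
  taxa0 <- net$taxa
  cand <- switch(move,
    NNI = move_nni(net, focus),
    add_reticulation = move_add_reticulation(net, focus),
    flip_direction = move_flip_direction(net, focus),
    move_origin = move_origin(net, focus),
    move_target = move_target(net, focus))
  if (is.null(cand)) return(NULL)
  finish_move(cand, taxa0)
}

# Edge ids that are legal foci for a move type.
legal_foci <- function(net, move) {
  net <- net_refresh(net)
  if (move == "NNI") {
    ok <- !net$hybrid & net$outdeg[net$child] == 2L & net$outdeg[net$parent] >= 2L
    # at the root, the unrooted edge continues into the sibling subtree,
    # which must itself be internal
    at_root <- net$indeg[net$parent] == 0L
    if (any(ok & at_root)) {
      for (e in which(ok & at_root)) {
        sib <- setdiff(which(net$parent == net$parent[e]), e)
        z <- net$child[sib[1L]]
        if (net$outdeg[z] != 2L) ok[e] <- FALSE
      }
    }
    which(ok)
  } else if (move == "add_reticulation") {
    seq_len(n_edges(net))
  } else {
    which(net$hybrid)
  }
}

# Net edge ids spanned by the quarnet of table row `qi` in a compiled map.
map_spanned_ids <- function(map, qi) {
  if (map$qtype[qi] == 0L) {
    ids <- map$tcomp_id[seq.int(map$tcomp_ptr[qi] + 1L, length.out =
                                  map$tcomp_ptr[qi + 1L] - map$tcomp_ptr[qi])]
  } else {
    g <- map$gindex[qi]
    es <- seq.int(map$ge_ptr[g + 1L] + 1L, map$ge_ptr[g + 2L])
    lo <- map$ge_comp_ptr[es[1L]] + 1L
    hi <- map$ge_comp_ptr[es[length(es)] + 1L]
    ids <- map$ge_comp_id[lo:hi]
  }
  unique(ids)
}

#' Select the focus edge of a topological move
#'
#' With probability `prob_qr`, uses weighted random selection: a 4-taxon set
#' is drawn with probability proportional to its misfit weight
#' `W = sum_i |Xq_i - CFq_i|` against the current network, and the focus is
#' drawn uniformly among the network edges spanned by that set's quarnet
#' that are legal for the pending move.  Otherwise (and whenever all weights
#' are zero or no spanned edge is legal) the focus is drawn uniformly among
#' all legal foci.
#'
#' @param net Current `qcf_network`.
#' @param table Observed `cf_table` (the table in use by the run).
#' @param expected Expected CFs of `net` aligned with `table` (from
#'   [expected_cf_network()]), required when `prob_qr > 0`.
#' @param prob_qr Probability in `[0, 1]` of weighted selection.
#' @param move The pending move type.
#' @param map Optional compiled quartet map of `net` (for spanned edges).
#' @return An edge id, or `NA` when the move has no legal focus.
#' @export
select_focus <- function(net, table, expected = NULL, prob_qr = 0,
                         move = "NNI", map = NULL) {
  move <- match.arg(move, move_types)
  legal <- legal_foci(net, move)
  if (length(legal) == 0L) return(NA_integer_)
  use_weighted <- prob_qr > 0 && !is.null(expected) && runif(1L) < prob_qr
  if (use_weighted) {
    W <- quartet_weights(table, expected)
    if (sum(W) > 0) {
      qi <- sample.int(length(W), 1L, prob = W)
      if (is.null(map)) map <- compile_cf_map(net, cf_matrix(table)$quartets)
      spanned <- intersect(map_spanned_ids(map, qi), legal)
      if (length(spanned) > 0L)
        return(spanned[sample.int(length(spanned), 1L)])
    }
    # all-zero weights or no legal spanned edge: fall back to uniform
  }
  legal[sample.int(length(legal), 1L)]
}
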