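# Quarnet extraction and the compiled quartet map used by the likelihood.

#' Induced 4-taxon subnetwork (quarnet)
#'
#' Restricts a network to four leaves: all other leaves are pruned, dead
#' branches removed, and degree-2 nodes suppressed with branch lengths of
#' merged edges summed.  Reticulation cycles that do not separate the four
#' sampled taxa degenerate and are removed; degenerate parallel hybrid edges
#' (2-cycles in the quarnet) are kept as parallel edges, whose expected CFs
#' the evaluator handles exactly.
#'
#' @param net A valid `qcf_network`.
#' @param taxa Character vector of four distinct taxon labels.
#' @return A `qcf_network` on the four taxa with at most `h` hybrid nodes.
#' @export
extract_quarnet <- function(net, taxa) {
  taxa <- as.character(taxa)
  if (length(taxa) != 4L || anyDuplicated(taxa))
    stop("'taxa' must name four distinct leaves")
  missing <- setdiff(taxa, net$taxa)
  if (length(missing))
    stop("taxa not found in the network: ", paste(missing, collapse = ", "))
  clean_network(net, keep = taxa, provenance = TRUE)
}

# taxon set below each edge, as bitmasks over `taxa` (sorted); network must
# be acyclic.
edge_clusters_mask <- function(net, taxa = net$taxa) {
  N <- length(net$labels)
  bit <- integer(N)
  ix <- match(net$labels, taxa)
  bit[!is.na(ix)] <- bitwShiftL(1L, ix[!is.na(ix)] - 1L)
  ord <- topo_order(net)
  node_mask <- integer(N)
  for (v in rev(ord)) {
    m <- bit[v]
    for (e in which(net$parent == v)) m <- bitwOr(m, node_mask[net$child[e]])
    node_mask[v] <- m
  }
  node_mask[net$child]
}

popcount4 <- function(x) {
  ((x %/% 1L) %% 2L) + ((x %/% 2L) %% 2L) + ((x %/% 4L) %% 2L) + ((x %/% 8L) %% 2L)
}

# Enumerate the directed leaf-to-root paths of `node`: list of integer
# vectors of edge indices.
paths_to_root <- function(net, node) {
  res <- list()
  walk <- function(v, acc) {
    ins <- which(net$child == v)
    if (length(ins) == 0L) { res[[length(res) + 1L]] <<- acc; return(invisible()) }
    for (e in ins) walk(net$parent[e], c(acc, e))
  }
  walk(node, integer(0))
  res
}

# Compile the expected-CF evaluator structure for `net` over the 4-taxon
# sets in `quartets` (k x 4 character matrix).  The returned list feeds
# cpp_map_expected_cf / cpp_map_logcl together with the network's per-edge
# length and gamma vectors; `free_len_ids` are the net edge ids whose
# lengths enter some quarnet's internal structure (the identifiable
# lengths).  The compilation itself runs in C++; compile_cf_map_r is the
# plain-R reference implementation against which it is cross-checked.
compile_cf_map <- function(net, quartets) {
  if (is.vector(quartets)) quartets <- matrix(quartets, nrow = 1L)
  quartets <- t(apply(quartets, 1L, sort))
  net <- net_refresh(net)
  qix <- matrix(match(quartets, net$taxa), ncol = 4L)
  if (anyNA(qix)) stop("quartet taxa not found in the network")
  map <- cpp_compile_map(net$parent, net$child, !is.na(net$gamma),
                         length(net$labels), net$leaves, qix)
  map$quartets <- quartets
  map
}

compile_cf_map_r <- function(net, quartets) {
  if (is.vector(quartets)) quartets <- matrix(quartets, nrow = 1L)
  k <- nrow(quartets)
  qtype <- integer(k); t_topo <- integer(k); gindex <- rep(-1L, k)
  tcomp_ptr <- integer(k + 1L); tcomp_id <- integer(0)
  ge_ptr <- integer(0); ge_comp_ptr <- 0L; ge_comp_id <- integer(0)
  ge_gid <- integer(0)
  gp_ptr <- 0L; gp_cover <- integer(0); gp_gam_ptr <- 0L; gp_gam_edge <- integer(0)
  G <- 0L
  free_ids <- integer(0)

  for (qi in seq_len(k)) {
    qt <- sort(quartets[qi, ])
    qn <- extract_quarnet(net, qt)
    if (qn$h == 0L) {
      qtype[qi] <- 0L
      cl <- edge_clusters_mask(qn, qt)
      two <- which(popcount4(cl) == 2L)
      if (length(two) == 0L) stop("internal error: quartet tree without a 2|2 edge")
      # all 2|2 clusters are complementary pairs describing the same split
      m <- cl[two[1L]]
      t_topo[qi] <- if (m %in% c(3L, 12L)) 1L else if (m %in% c(5L, 10L)) 2L else 3L
      ids <- unique(unlist(qn$comp[two]))
      tcomp_id <- c(tcomp_id, ids)
      tcomp_ptr[qi + 1L] <- tcomp_ptr[qi] + length(ids)
      free_ids <- c(free_ids, ids)
    } else {
      qtype[qi] <- 1L
      G <- G + 1L
      gindex[qi] <- G - 1L
      tcomp_ptr[qi + 1L] <- tcomp_ptr[qi]
      # edges in processing order: by position of the child node in a
      # children-first traversal
      ordN <- topo_order(qn)
      pos <- integer(length(qn$labels)); pos[rev(ordN)] <- seq_along(ordN)
      eord <- order(pos[qn$child])
      ne <- length(eord)
      if (ne > 31L) stop("quarnet too large to compile")
      local_of <- integer(n_edges(qn)); local_of[eord] <- seq_len(ne)
      ge_ptr <- c(ge_ptr, ne)
      for (e in eord) {
        ids <- qn$comp[[e]]
        ge_comp_id <- c(ge_comp_id, ids)
        ge_comp_ptr <- c(ge_comp_ptr, ge_comp_ptr[length(ge_comp_ptr)] + length(ids))
        if (!is.na(qn$gamma[e])) {
          gsrc <- ids[!is.na(net$gamma[ids])]
          if (length(gsrc) != 1L)
            stop("internal error: ambiguous gamma provenance in quarnet edge")
          ge_gid <- c(ge_gid, gsrc)
        } else ge_gid <- c(ge_gid, 0L)
        # pendant quarnet edges never carry >1 lineage: their lengths are
        # unidentifiable from CFs and are not free parameters
        if (qn$outdeg[qn$child[e]] != 0L) free_ids <- c(free_ids, ids)
      }
      # leaf-to-root paths per lineage, in sorted taxon order
      for (l in 1:4) {
        leaf <- which(qn$labels == qt[l])
        pl <- paths_to_root(qn, leaf)
        gp_ptr <- c(gp_ptr, gp_ptr[length(gp_ptr)] + length(pl))
        for (p in pl) {
          loc <- local_of[p]
          gp_cover <- c(gp_cover, sum(bitwShiftL(1L, loc - 1L)))
          hyb <- loc[!is.na(qn$gamma[p])]
          gp_gam_edge <- c(gp_gam_edge, hyb - 1L)
          gp_gam_ptr <- c(gp_gam_ptr, gp_gam_ptr[length(gp_gam_ptr)] + length(hyb))
        }
      }
    }
  }
  # gp_ptr currently holds cumulative path counts per (general quartet,
  # lineage); prefix with 0 layout expected by the C++ side
  list(k = k, G = G, qtype = qtype, t_topo = t_topo, gindex = gindex,
       tcomp_ptr = tcomp_ptr, tcomp_id = tcomp_id,
       ge_ptr = c(0L, cumsum(ge_ptr)),
       ge_comp_ptr = ge_comp_ptr, ge_comp_id = ge_comp_id, ge_gid = ge_gid,
       gp_ptr = gp_ptr, gp_cover = gp_cover,
       gp_gam_ptr = gp_gam_ptr, gp_gam_edge = gp_gam_edge,
       free_len_ids = sort(unique(free_ids)),
       quartets = quartets)
}
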