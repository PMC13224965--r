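# Expected quartet concordance factors under the multispecies network
# coalescent (MSNC), plus the Monte-Carlo oracle used to validate them.

#' Expected CFs for a quartet species tree
#'
#' The classical coalescent result for one internal branch of length `t`
#' (coalescent units): the quartet matching the species tree has probability
#' `1 - (2/3) exp(-t)` and each minor quartet `(1/3) exp(-t)`.
#'
#' @param t Internal branch length in coalescent units, `>= 0` (may be `Inf`).
#' @return Numeric CF triple `(major, minor, minor)`.
#' @examples
#' expected_cf_tree(0)    # 1/3 1/3 1/3
#' expected_cf_tree(Inf)  # 1 0 0
#' @export
expected_cf_tree <- function(t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("'t' must be a single non-negative number")
  minor <- exp(-t) / 3
  c((3 - 2 * exp(-t)) / 3, minor, minor)
}

#' Exact expected CFs for a level-1 quarnet
#'
#' Computes the MSNC quartet-topology probabilities for a network on (at
#' most) four taxa by conditioning on the routing of every sampled lineage
#' at every hybrid node (probability the product of inheritance
#' probabilities), with coalescence of co-located lineages accumulated edge
#' by edge; lineages that coalesce below a hybrid node route as one.  When a
#' single sampled lineage can reach each hybrid node this reduces to the
#' displayed-tree mixture `sum_T P(T) CF(T)`.
#'
#' @param qnet A level-1 `qcf_network` with four leaves.
#' @return Numeric CF triple in canonical split order for the sorted taxa
#'   (`t1t2|t3t4`, `t1t3|t2t4`, `t1t4|t2t3`).
#' @export
expected_cf_quarnet <- function(qnet) {
  if (length(qnet$taxa) != 4L) stop("'qnet' must have exactly four leaves")
  bad <- setdiff(validate_network(qnet), "gamma_range")
  bad <- setdiff(bad, c("two_cycle", "three_cycle"))  # degenerate cycles allowed
  if (length(bad)) stop("invalid quarnet: ", paste(bad, collapse = ", "))
  map <- compile_cf_map(qnet, matrix(sort(qnet$taxa), nrow = 1L))
  drop(cpp_map_expected_cf(map, qnet$length, qnet$gamma))
}

#' Expected CFs of a network for a set of 4-taxon sets
#'
#' Extracts the quarnet induced by each 4-taxon set and computes its exact
#' expected CFs.  The result is identical for any number of workers: quartet
#' tasks are independent and results are assembled in canonical quartet
#' order.
#'
#' @param net A valid `qcf_network`.
#' @param quartets 4-column character matrix of 4-taxon sets (defaults to all
#'   sets on the network's taxa), or a `cf_table` whose sets are used.
#' @param workers Number of parallel workers for the per-quartet map
#'   (forked processes; 1 = serial).
#' @return Numeric `k x 3` matrix of expected CFs, rows aligned with
#'   `quartets`.
#' @export
expected_cf_network <- function(net, quartets = NULL, workers = 1L) {
  if (inherits(quartets, "cf_table")) quartets <- cf_matrix(quartets)$quartets
  if (is.null(quartets)) quartets <- enumerate_quartets(net$taxa)
  if (is.vector(quartets)) quartets <- matrix(quartets, nrow = 1L)
  quartets <- t(apply(quartets, 1L, sort))
  k <- nrow(quartets)
  workers <- max(1L, as.integer(workers))
  chunk_cf <- function(rows) {
    map <- compile_cf_map(net, quartets[rows, , drop = FALSE])
    cpp_map_expected_cf(map, net$length, net$gamma)
  }
  if (workers == 1L || k < 2L) {
    out <- chunk_cf(seq_len(k))
  } else {
    chunks <- split(seq_len(k), sort(rep_len(seq_len(workers), k)))
    parts <- parallel::mclapply(chunks, chunk_cf, mc.cores = workers)
    out <- do.call(rbind, parts)  # chunks are contiguous, canonical order kept
  }
  dimnames(out) <- list(NULL, c("CF12_34", "CF13_24", "CF14_23"))
  out
}

#' Monte-Carlo concordance-factor oracle
#'
#' Simulates `ngenes` gene trees on the supplied network under the MSNC
#' generative process (the same engine as [simulate_gene_trees()], in a code
#' path fully independent of the analytic CF computation) and tabulates the
#' observed frequency of the three quartet topologies for one 4-taxon set.
#'
#' @param net A valid `qcf_network` (a quarnet or a larger network).
#' @param quartet Character vector of four taxon labels.
#' @param ngenes Number of gene trees to simulate.
#' @param seed Integer seed (dedicated stream; reproducible).
#' @return Numeric frequency triple in canonical split order for the sorted
#'   quartet.
#' @export
mc_cf_oracle <- function(net, quartet, ngenes, seed) {
  quartet <- sort(as.character(quartet))
  if (length(quartet) != 4L) stop("'quartet' must name four taxa")
  pos <- match(quartet, net$taxa)
  if (anyNA(pos)) stop("quartet taxa not in the network")
  net <- net_refresh(net)
  counts <- with_local_seed(seed,
    cpp_msnc_quartet_counts(net$parent, net$child, net$length, net$gamma,
                            length(net$labels), net$root,
                            net$leaves, pos, as.integer(ngenes)))
  setNames(counts / ngenes, c("CF12_34", "CF13_24", "CF14_23"))
}
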