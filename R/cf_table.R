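# Observed quartet concordance factors: enumeration, counting from gene
# trees, CSV round-trip, seeded subsampling and misfit weights.

cf_cols <- c("taxon1", "taxon2", "taxon3", "taxon4",
             "CF12_34", "CF13_24", "CF14_23", "ngenes")

new_cf_table <- function(df, taxa) {
  df <- df[order(df$taxon1, df$taxon2, df$taxon3, df$taxon4), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, taxa = sort(taxa), class = c("cf_table", "data.frame"))
}

#' @export
print.cf_table <- function(x, ...) {
  cat(sprintf("Quartet CF table: %d 4-taxon sets on %d taxa\n",
              nrow(x), length(attr(x, "taxa"))))
  print.data.frame(head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Enumerate all 4-taxon sets
#'
#' @param taxa Character vector of at least four taxon labels.
#' @return A `choose(n,4) x 4` character matrix, rows sorted within and
#'   across (deterministic lexicographic order).
#' @examples
#' nrow(enumerate_quartets(letters[1:10]))  # 210
#' @export
enumerate_quartets <- function(taxa) {
  taxa <- sort(unique(as.character(taxa)))
  if (length(taxa) < 4L) stop("need at least 4 taxa")
  t(combn(taxa, 4L))
}

# 32-bit popcount via a 16-bit lookup table
.qcf_env <- new.env(parent = emptyenv())
popcount32 <- function(x) {
  if (is.null(.qcf_env$pc16)) {
    v <- integer(65536L)
    for (b in 0:15) v <- v + bitwAnd(bitwShiftR(0:65535, b), 1L)
    .qcf_env$pc16 <- v
  }
  pc <- .qcf_env$pc16
  pc[bitwAnd(x, 65535L) + 1L] + pc[bitwShiftR(x, 16L) + 1L]
}

# nontrivial splits of a phylo as bitmasks over `taxa` (and the tip mask)
tree_split_masks <- function(phy, taxa) {
  ix <- match(phy$tip.label, taxa)
  if (anyNA(ix)) stop("gene tree contains unknown taxa: ",
                      paste(phy$tip.label[is.na(ix)], collapse = ", "))
  ntip <- length(phy$tip.label)
  N <- ntip + phy$Nnode
  mask <- integer(N)
  mask[seq_len(ntip)] <- bitwShiftL(1L, ix - 1L)
  edge <- phy$edge
  for (e in rev(seq_len(nrow(edge))))  # postorder accumulate (cladewise input)
    mask[edge[e, 1L]] <- bitwOr(mask[edge[e, 1L]], mask[edge[e, 2L]])
  below <- mask[edge[, 2L]]
  list(splits = below[edge[, 2L] > ntip], tipmask = mask[ntip + 1L])
}

#' Observed concordance factors from gene trees
#'
#' Counts, for every 4-taxon set, the frequency of the three unrooted quartet
#' topologies across gene trees.  A gene tree is informative for a 4-taxon
#' set if it contains all four taxa and resolves them (its split set,
#' restricted to the four taxa, contains a 2|2 split); other gene trees are
#' excluded from that set's `ngenes`.  Counting is invariant to gene-tree
#' order and rooting.
#'
#' @param gene_trees A list of [ape::phylo] trees (or a `multiPhylo`).
#' @param quartets Optional 4-column character matrix of 4-taxon sets;
#'   defaults to all sets on the union of tip labels.
#' @param taxa Optional full taxon set (defaults to the union of tip labels).
#' @return A `cf_table`: a data frame with columns `taxon1..4`,
#'   `CF12_34`, `CF13_24`, `CF14_23`, `ngenes`.
#' @export
observed_cf <- function(gene_trees, quartets = NULL, taxa = NULL) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  gene_trees <- unclass(gene_trees)
  if (is.null(taxa))
    taxa <- sort(unique(unlist(lapply(gene_trees, `[[`, "tip.label"))))
  taxa <- sort(taxa)
  if (length(taxa) > 31L) stop("at most 31 taxa supported")
  if (is.null(quartets)) quartets <- enumerate_quartets(taxa)
  if (is.vector(quartets)) quartets <- matrix(quartets, nrow = 1L)
  quartets <- t(apply(quartets, 1L, sort))
  k <- nrow(quartets)
  qix <- matrix(match(quartets, taxa), ncol = 4L)
  if (anyNA(qix)) stop("quartet taxa not in the taxon set")
  qmask <- integer(k)
  bits <- matrix(bitwShiftL(1L, qix - 1L), ncol = 4L)
  for (j in 1:4) qmask <- bitwOr(qmask, bits[, j])
  pair12 <- bitwOr(bits[, 1L], bits[, 2L])
  pair13 <- bitwOr(bits[, 1L], bits[, 3L])

  counts <- matrix(0L, k, 3L)
  ngenes <- integer(k)
  for (phy in gene_trees) {
    sm <- tree_split_masks(ape::reorder.phylo(phy, "cladewise"), taxa)
    has <- bitwAnd(qmask, sm$tipmask) == qmask
    if (!any(has)) next
    for (qi in which(has)) {
      r <- bitwAnd(sm$splits, qmask[qi])
      r2 <- bitwAnd(bitwNot(sm$splits), qmask[qi])
      cand <- c(r[popcount32(r) == 2L], r2[popcount32(r2) == 2L])
      if (length(cand) == 0L) next  # unresolved for this quartet
      pr <- cand[1L]
      topo <- if (pr == pair12[qi] || pr == bitwAnd(qmask[qi], bitwNot(pair12[qi])))
        1L
      else if (pr == pair13[qi] || pr == bitwAnd(qmask[qi], bitwNot(pair13[qi])))
        2L
      else 3L
      counts[qi, topo] <- counts[qi, topo] + 1L
      ngenes[qi] <- ngenes[qi] + 1L
    }
  }
  cf <- counts / ifelse(ngenes > 0L, ngenes, 1L)
  if (any(ngenes == 0L))
    warning(sum(ngenes == 0L),
            " 4-taxon set(s) have no informative gene trees; flagged missing")
  df <- data.frame(taxon1 = quartets[, 1L], taxon2 = quartets[, 2L],
                   taxon3 = quartets[, 3L], taxon4 = quartets[, 4L],
                   CF12_34 = cf[, 1L], CF13_24 = cf[, 2L], CF14_23 = cf[, 3L],
                   ngenes = ngenes, stringsAsFactors = FALSE)
  new_cf_table(df, taxa)
}

#' Read / write a quartet CF table
#'
#' CSV format: header `taxon1,taxon2,taxon3,taxon4,CF12_34,CF13_24,CF14_23,
#' ngenes`.  Rows are canonicalised (taxa sorted within a row, rows sorted);
#' rows whose CFs do not sum to 1 within 1e-6, duplicated 4-taxon sets and
#' missing columns are rejected with the offending row number.
#'
#' @param path File path.
#' @return `read_cf_table` returns a `cf_table`; `write_cf_table` returns
#'   `path` invisibly.
#' @export
read_cf_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cf_cols, names(df))
  if (length(miss)) stop("CF table is missing columns: ", paste(miss, collapse = ", "))
  df <- df[cf_cols]
  for (cc in cf_cols[5:8])
    if (!is.numeric(df[[cc]])) stop("non-numeric values in column ", cc)
  # canonicalise taxon order within rows, permuting the CF columns with them
  for (r in seq_len(nrow(df))) {
    tx <- as.character(df[r, 1:4])
    o <- order(tx)
    if (!identical(o, 1:4)) {
      cf3 <- permute_cf(as.numeric(df[r, 5:7]), o)
      df[r, 1:4] <- tx[o]
      df[r, 5:7] <- cf3
    }
    s <- sum(df[r, 5:7])
    if (df$ngenes[r] > 0 && abs(s - 1) > 1e-6)
      stop(sprintf("row %d: CFs sum to %g, not 1", r, s))
  }
  key <- paste(df$taxon1, df$taxon2, df$taxon3, df$taxon4)
  if (anyDuplicated(key))
    stop("duplicate 4-taxon set at row ", which(duplicated(key))[1L])
  taxa <- sort(unique(c(df$taxon1, df$taxon2, df$taxon3, df$taxon4)))
  new_cf_table(df, taxa)
}

#' @rdname read_cf_table
#' @param table A `cf_table`.
#' @export
write_cf_table <- function(table, path) {
  write.csv(as.data.frame(table)[cf_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Reorder a CF triple when the four taxa are permuted by `o` (the ordering
# that sorts them): the split {1,2}|{3,4} maps to whichever canonical split
# the permuted positions form.
permute_cf <- function(cf3, o) {
  pos <- order(o)  # new position of original taxon i
  split_of <- function(i, j) {
    u <- sort(c(pos[i], pos[j]))
    if (identical(u, c(1L, 2L))) 1L else if (identical(u, c(1L, 3L))) 2L else
      if (identical(u, c(1L, 4L))) 3L else if (identical(u, c(3L, 4L))) 1L else
        if (identical(u, c(2L, 4L))) 2L else 3L
  }
  out <- numeric(3)
  out[split_of(1L, 2L)] <- cf3[1L]
  out[split_of(1L, 3L)] <- cf3[2L]
  out[split_of(1L, 4L)] <- cf3[3L]
  out
}

#' Seeded subsampling of 4-taxon sets
#'
#' Draws exactly `ceiling(k * prop)` records uniformly at random without
#' replacement.  The draw is a pure function of `(table, prop, seed)`:
#' identical inputs give identical subsets, and the caller's RNG state is
#' left untouched.  `prop = 1` returns the table unchanged.
#'
#' @param table A `cf_table` with `k` rows.
#' @param prop Proportion in `(0, 1]` of 4-taxon sets to keep.
#' @param seed Integer seed for the dedicated RNG stream.
#' @return A `cf_table` with `ceiling(k * prop)` rows.
#' @export
subsample_quartets <- function(table, prop, seed) {
  if (!is.numeric(prop) || length(prop) != 1L || prop <= 0 || prop > 1)
    stop("'prop' must be in (0, 1]")
  if (prop == 1) return(table)
  k <- nrow(table)
  m <- ceiling(k * prop)
  keep <- with_local_seed(seed, sort(sample.int(k, m)))
  new_cf_table(as.data.frame(table)[keep, , drop = FALSE], attr(table, "taxa"))
}

#' Misfit weight of each 4-taxon set
#'
#' The weight of a quartet is the L1 distance between its observed and
#' expected CFs, `W = sum_i |Xq_i - CFq_i|`, in `[0, 2]`; `W = 0` iff the
#' network CFs fit that quartet exactly.  Large weights flag the parts of
#' the network that fit the data poorly.
#'
#' @param table A `cf_table`.
#' @param expected A numeric `k x 3` matrix of expected CFs aligned 1:1 with
#'   the table rows (e.g. from [expected_cf_network()]).
#' @return Numeric vector of weights, one per table row.
#' @export
quartet_weights <- function(table, expected) {
  expected <- as.matrix(expected)
  if (nrow(expected) != nrow(table) || ncol(expected) != 3L)
    stop("'expected' must be a ", nrow(table), " x 3 matrix aligned with the table")
  X <- as.matrix(as.data.frame(table)[cf_cols[5:7]])
  unname(rowSums(abs(X - expected)))
}

# observed-CF matrix and usable-row flags from a cf_table
cf_matrix <- function(table) {
  list(X = as.matrix(as.data.frame(table)[cf_cols[5:7]]),
       use = table$ngenes > 0L,
       quartets = as.matrix(as.data.frame(table)[cf_cols[1:4]]))
}
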