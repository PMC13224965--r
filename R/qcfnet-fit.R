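# The user-facing model fit: qcfnet() estimates a level-1 semi-directed
# network from gene trees or a quartet CF table by maximizing the composite
# likelihood, and returns a classed object with the usual accessor methods.

#' Fit a level-1 phylogenetic network to quartet concordance factors
#'
#' Estimates a semi-directed level-1 network with `h` reticulations by
#' strict hill-climbing over topologies (five moves; candidates accepted
#' only on a strict composite-likelihood improvement) with continuous
#' parameters (branch lengths in coalescent units, inheritance
#' probabilities) optimized on every candidate.  Multiple independent runs
#' with varied starting topologies are performed and the best full-table
#' score returned.
#'
#' @param cf Observed data: a `cf_table` (see [observed_cf()],
#'   [read_cf_table()]) or a list of gene trees ([ape::phylo] /
#'   `multiPhylo`), from which CFs are computed.
#' @param h Number of reticulations to estimate (default 0: a species tree).
#' @param start Optional starting topology (or list of topologies, recycled
#'   over runs): `qcf_network`, [ape::phylo], or Newick/extended-Newick
#'   string.  By default starting trees are drawn from the gene trees when
#'   available, otherwise random topologies are used.
#' @param runs Number of independent search runs (default 10).
#' @param prop_quartets Proportion of 4-taxon sets scored during each run
#'   (default 1); the final network is always rescored on the full table.
#' @param prob_qr Probability of misfit-weighted focus selection (default 0).
#' @param seed Master seed (default 1); results are fully reproducible given
#'   the seed and do not depend on `workers`.
#' @param max_failures Consecutive failed proposals that end a run.
#' @param control A [qcf_control()] list of optimizer settings.
#' @param workers Parallel workers for per-quartet computations.
#' @return An object of class `qcfnet` with components `network` (the best
#'   network, a `qcf_network`), `logCL` (its full-table log composite
#'   likelihood), `cf` (the full CF table), `runs` (per-run traces), `h`,
#'   `config`, and `call`.  Methods: [print()], [summary()], [coef()],
#'   [logLik()], [predict()], [fitted()], [residuals()], [simulate()],
#'   [plot()].
#' @examples
#' \donttest{
#' truth <- simulate_network(n = 6, h = 0, mean_branch_length = 2, seed = 7)
#' gt <- simulate_gene_trees(truth, g = 300, seed = 8)
#' fit <- qcfnet(gt, h = 0, runs = 2, seed = 1, max_failures = 20)
#' fit
#' hwcd(fit$network, truth)
#' }
#' @export
qcfnet <- function(cf, h = 0L, start = NULL, runs = 10L, prop_quartets = 1,
                   prob_qr = 0, seed = 1L, max_failures = 100L,
                   control = qcf_control(), workers = 1L) {
  cl <- match.call()
  gene_trees <- NULL
  if (inherits(cf, "cf_table")) {
    table <- cf
  } else if (inherits(cf, "phylo") || inherits(cf, "multiPhylo") ||
             (is.list(cf) && length(cf) && inherits(cf[[1L]], "phylo"))) {
    gene_trees <- if (inherits(cf, "phylo")) list(cf) else cf
    table <- observed_cf(gene_trees)
  } else stop("'cf' must be a cf_table or a list of gene trees")
  taxa <- attr(table, "taxa")

  config <- qcf_search_config(h = h, runs = runs,
                              prop_quartets = prop_quartets,
                              prob_qr = prob_qr, seed = seed,
                              max_failures = max_failures,
                              optimizer = control)
  starts <- resolve_starts(start, gene_trees, taxa, config)
  res <- multi_run_search(starts, table, config, workers = workers)
  structure(list(network = res$best$network, logCL = res$best$logCL,
                 cf = table, runs = res$runs, best_run = res$best_run,
                 h = res$best$network$h, config = config, call = cl),
            class = "qcfnet")
}

# One starting topology per run: user-supplied, sampled from the gene trees
# (those covering all taxa), or random.
resolve_starts <- function(start, gene_trees, taxa, config) {
  as_net <- function(s) {
    if (inherits(s, "qcf_network")) return(s)
    if (inherits(s, "phylo")) return(phylo_to_net(s))
    if (is.character(s)) {
      return(if (grepl("#", s, fixed = TRUE)) parse_enewick(s)
             else phylo_to_net(parse_newick(s)))
    }
    stop("cannot interpret a starting topology of class ", class(s)[1L])
  }
  if (!is.null(start)) {
    if (!is.list(start) || inherits(start, "phylo") ||
        inherits(start, "qcf_network"))
      start <- list(start)
    starts <- lapply(start, as_net)
    for (s in starts)
      if (!setequal(s$taxa, taxa))
        stop("starting topology is not on the data's taxon set")
    return(starts)
  }
  if (!is.null(gene_trees)) {
    full <- Filter(function(p) setequal(p$tip.label, taxa), gene_trees)
    if (length(full)) {
      picks <- with_local_seed(mix_seed(config$seed, 424243L),
                               sample.int(length(full), config$runs,
                                          replace = length(full) < config$runs))
      return(lapply(picks, function(i) phylo_to_net(full[[i]])))
    }
  }
  lapply(seq_len(config$runs), function(r)
    with_local_seed(mix_seed(config$seed, 515151L + r),
                    phylo_to_net(ape::rtree(length(taxa), tip.label = sample(taxa)))))
}

#' @export
print.qcfnet <- function(x, ...) {
  cat("Level-1 network fit by composite likelihood on quartet CFs\n")
  cat(sprintf("  taxa: %d   reticulations (h): %d   4-taxon sets: %d\n",
              length(attr(x$cf, "taxa")), x$h, nrow(x$cf)))
  cat(sprintf("  log composite likelihood (full table): %.6f\n", x$logCL))
  cat(sprintf("  runs: %d (best: run %d)\n", length(x$runs), x$best_run))
  cat("  network: ", write_enewick(x$network), "\n", sep = "")
  invisible(x)
}

#' @export
summary.qcfnet <- function(object, ...) {
  runs <- data.frame(
    run = seq_along(object$runs),
    proposals = vapply(object$runs, function(r) nrow(r$trace), 0L),
    accepted = vapply(object$runs, function(r) r$n_accepted, 0L),
    logCL_run = vapply(object$runs, function(r) r$final$logCL, 0.0),
    logCL_full = vapply(object$runs, function(r) r$full$logCL, 0.0))
  W <- quartet_weights(object$cf, fitted(object))
  structure(list(fit = object, runs = runs,
                 worst = order(W, decreasing = TRUE)[seq_len(min(5L, length(W)))],
                 W = W, coef = coef(object)),
            class = "summary.qcfnet")
}

#' @export
print.summary.qcfnet <- function(x, ...) {
  print(x$fit)
  cat("\nPer-run results:\n")
  print(x$runs, row.names = FALSE)
  cat("\nEstimated parameters:\n")
  print(round(x$coef, 4))
  cat("\nMisfit weights W = sum|X - CF|: mean", round(mean(x$W), 4),
      "max", round(max(x$W), 4), "\n")
  invisible(x)
}

#' @export
coef.qcfnet <- function(object, ...) {
  net <- object$network
  map <- compile_cf_map(net, cf_matrix(object$cf)$quartets)
  par <- free_parameters(net, map)
  out <- net$length[par$len_ids]
  names(out) <- sprintf("t[%d->%d]", net$parent[par$len_ids],
                        net$child[par$len_ids])
  if (length(par$gam_minor)) {
    g <- net$gamma[par$gam_minor]
    names(g) <- sprintf("gamma[%d->%d]", net$parent[par$gam_minor],
                        net$child[par$gam_minor])
    out <- c(out, g)
  }
  out
}

#' @export
logLik.qcfnet <- function(object, ...) {
  map <- compile_cf_map(object$network, cf_matrix(object$cf)$quartets)
  par <- free_parameters(object$network, map)
  structure(object$logCL, df = length(par$len_ids) + length(par$gam_minor),
            nobs = sum(object$cf$ngenes > 0), class = "logLik")
}

#' @export
predict.qcfnet <- function(object, quartets = NULL, workers = 1L, ...) {
  if (is.null(quartets)) quartets <- cf_matrix(object$cf)$quartets
  expected_cf_network(object$network, quartets, workers = workers)
}

#' @export
fitted.qcfnet <- function(object, ...) predict(object)

#' @export
residuals.qcfnet <- function(object, ...) {
  cf_matrix(object$cf)$X - fitted(object)
}

#' @export
simulate.qcfnet <- function(object, nsim = 100L, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$config$seed
  simulate_gene_trees(object$network, g = nsim, seed = seed)
}

#' @export
plot.qcfnet <- function(x, type = c("trace", "residuals"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    ymin <- min(vapply(x$runs, function(r) min(r$trace$logCL), 0.0))
    ymax <- max(vapply(x$runs, function(r) max(r$trace$logCL), 0.0))
    nmax <- max(vapply(x$runs, function(r) nrow(r$trace), 0L))
    plot(NULL, xlim = c(1, nmax), ylim = c(ymin, ymax),
         xlab = "proposal", ylab = "log composite likelihood",
         main = "Hill-climbing trajectories", ...)
    for (i in seq_along(x$runs))
      lines(seq_len(nrow(x$runs[[i]]$trace)), x$runs[[i]]$trace$logCL,
            col = i)
    abline(h = x$logCL, lty = 2)
  } else {
    W <- quartet_weights(x$cf, fitted(x))
    hist(W, breaks = 20, xlab = "misfit weight W = sum|X - CF|",
         main = "Per-quartet misfit", ...)
  }
  invisible(x)
}
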