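# Composite likelihood (product over 4-taxon sets of per-quartet multinomial
# terms) and numerical optimization of branch lengths and inheritance
# probabilities on a fixed topology.

#' Optimizer and numerical-tolerance settings
#'
#' @param reltol Relative convergence tolerance on the log composite
#'   likelihood.
#' @param max_eval Maximum objective evaluations per start.
#' @param starts Number of optimization starts (start 1 = current parameter
#'   values, further starts jittered; deterministic given the seed).
#' @param jitter Standard deviation of the jitter on the unconstrained scale.
#' @param eps Clamp applied to expected CFs before logging, keeping the log
#'   composite likelihood finite when an observed topology has expected
#'   probability ~0.
#' @param eps_gamma Bound keeping inheritance probabilities inside
#'   `[eps_gamma, 1 - eps_gamma]` during optimization.
#' @return A list of class `qcf_control`.
#' @export
qcf_control <- function(reltol = 1e-8, max_eval = 200L, starts = 3L,
                        jitter = 0.5, eps = 1e-12, eps_gamma = 1e-4) {
  stopifnot(eps > 0, eps_gamma > 0, max_eval >= 1, starts >= 1)
  structure(list(reltol = reltol, max_eval = as.integer(max_eval),
                 starts = as.integer(starts), jitter = jitter,
                 eps = eps, eps_gamma = eps_gamma),
            class = "qcf_control")
}

#' Log composite likelihood of expected CFs against observed CFs
#'
#' `logCL = sum_s sum_i Xq_i log(CFq_i)` over the 4-taxon sets `s` of the
#' table (natural log).  Expected CFs are clamped to `[eps, 1 - 2 eps]`
#' before logging; terms with `Xq_i = 0` contribute 0; 4-taxon sets flagged
#' missing (`ngenes = 0`) are excluded.
#'
#' @param table A `cf_table` of observed CFs.
#' @param expected Numeric `k x 3` matrix of expected CFs aligned with the
#'   table rows.
#' @param eps Clamp for expected CFs.
#' @return The log composite likelihood (a single number, `<= 0`).
#' @export
log_composite_likelihood <- function(table, expected, eps = 1e-12) {
  expected <- as.matrix(expected)
  if (nrow(expected) != nrow(table) || ncol(expected) != 3L)
    stop("'expected' must be a ", nrow(table), " x 3 matrix aligned with the table")
  cm <- cf_matrix(table)
  P <- pmin(pmax(expected, eps), 1 - 2 * eps)
  terms <- ifelse(cm$X > 0, cm$X * log(P), 0)
  sum(terms[cm$use, , drop = FALSE])
}

# Free parameters of a topology: identifiable branch lengths (edges entering
# some quarnet's internal structure) and one inheritance probability per
# hybrid node (carried by the minor edge; the major edge gets 1 - gamma).
free_parameters <- function(net, map) {
  len_ids <- map$free_len_ids
  hyb <- which(net_refresh(net)$indeg == 2L)
  gam_minor <- integer(0); gam_major <- integer(0)
  for (hn in hyb) {
    es <- which(net$child == hn)
    g <- net$gamma[es]
    minor <- if (!anyNA(g) && g[2] < g[1]) 2L else 1L
    gam_minor <- c(gam_minor, es[minor])
    gam_major <- c(gam_major, es[-minor])
  }
  list(len_ids = len_ids, gam_minor = gam_minor, gam_major = gam_major)
}

theta_to_net <- function(theta, net, par, ctrl) {
  nl <- length(par$len_ids)
  if (nl) net$length[par$len_ids] <- pmin(exp(theta[seq_len(nl)]), 100)
  if (length(par$gam_minor)) {
    g <- plogis(theta[nl + seq_along(par$gam_minor)])
    g <- pmin(pmax(g, ctrl$eps_gamma), 1 - ctrl$eps_gamma)
    net$gamma[par$gam_minor] <- g
    net$gamma[par$gam_major] <- 1 - g
  }
  net
}

net_to_theta <- function(net, par) {
  len0 <- net$length[par$len_ids]
  len0[is.na(len0)] <- 1.0
  len0[len0 <= 1e-4] <- 1e-4
  g0 <- net$gamma[par$gam_minor]
  g0[is.na(g0)] <- 0.5
  g0 <- pmin(pmax(g0, 1e-3), 1 - 1e-3)
  c(log(len0), qlogis(g0))
}

#' Optimize branch lengths and inheritance probabilities on a topology
#'
#' Maximizes the log composite likelihood over the identifiable continuous
#' parameters of a fixed network topology: internal branch lengths (log
#' transform) and inheritance probabilities (logit transform), by
#' multi-start Nelder-Mead.  The returned score is never below the score at
#' the initial parameter values, and the result is deterministic given
#' `seed`.
#'
#' @param topology A valid `qcf_network`; current lengths/gammas are the
#'   first optimization start (missing internal lengths start at 1).
#' @param table A `cf_table` of observed CFs.
#' @param control A [qcf_control()] list.
#' @param seed Integer seed for the multi-start jitter (dedicated stream).
#' @param map Optional precompiled quartet map for `topology` and the
#'   table's 4-taxon sets.
#' @param scope Label recording which table produced the score
#'   (`"full"` or `"subsample"`).
#' @return A list of class `qcf_score` with elements `network` (topology
#'   with optimized parameters), `logCL`, `scope`, and `evals`.
#' @export
optimize_parameters <- function(topology, table, control = qcf_control(),
                                seed = 1L, map = NULL, scope = "full") {
  if (nrow(table) == 0L) stop("empty CF table")
  cm <- cf_matrix(table)
  if (is.null(map)) map <- compile_cf_map(topology, cm$quartets)
  par <- free_parameters(topology, map)
  len0 <- topology$length; gam0 <- topology$gamma
  nl <- length(par$len_ids); ng <- length(par$gam_minor)
  obj <- function(theta) {
    el <- len0
    # lengths above 100 coalescent units are CF-equivalent to infinity;
    # capping keeps unidentifiable directions from wandering
    if (nl) el[par$len_ids] <- pmin(exp(theta[seq_len(nl)]), 100)
    eg <- gam0
    if (ng) {
      g <- plogis(theta[nl + seq_len(ng)])
      g <- pmin(pmax(g, control$eps_gamma), 1 - control$eps_gamma)
      eg[par$gam_minor] <- g
      eg[par$gam_major] <- 1 - g
    }
    v <- -cpp_map_logcl(map, el, eg, cm$X, cm$use, control$eps)
    if (!is.finite(v)) 1e10 else v  # penalty wall keeps optim() in bounds
  }
  theta0 <- net_to_theta(topology, par)
  f0 <- obj(theta0)
  if (!is.finite(f0) || f0 >= 1e10)
    stop("non-finite composite likelihood at the initial parameters")
  best <- list(theta = theta0, value = f0)
  evals <- 1L
  if (length(theta0) > 0L) {
    starts <- with_local_seed(seed, {
      c(list(theta0),
        lapply(seq_len(control$starts - 1L), function(i)
          theta0 + rnorm(length(theta0), 0, control$jitter)))
    })
    for (th in starts) {
      fit <- tryCatch(
        optim(th, obj, method = "BFGS",
              control = list(maxit = control$max_eval,
                             reltol = control$reltol)),
        error = function(e)
          optim(th, obj, method = "Nelder-Mead",
                control = list(maxit = 10L * control$max_eval,
                               reltol = control$reltol)))
      evals <- evals + fit$counts[1L]
      if (is.finite(fit$value) && fit$value < best$value)
        best <- list(theta = fit$par, value = fit$value)
    }
  }
  net <- theta_to_net(best$theta, topology, par, control)
  structure(list(network = net, logCL = -best$value, scope = scope,
                 evals = evals),
            class = "qcf_score")
}

#' @export
print.qcf_score <- function(x, ...) {
  cat(sprintf("Scored network: logCL = %.6f (%s CF table)\n", x$logCL, x$scope))
  print(x$network)
  invisible(x)
}

#' Final full-table rescoring of a network
#'
#' After a search that used a quartet subsample, one final round of numerical
#' optimization against all `k` CFs gives the network's full-data log
#' composite likelihood.
#'
#' @inheritParams optimize_parameters
#' @param net The network to rescore.
#' @param full_table The complete (unsubsampled) `cf_table`.
#' @return A `qcf_score` with `scope = "full"`.
#' @export
final_full_score <- function(net, full_table, control = qcf_control(),
                             seed = 1L) {
  optimize_parameters(net, full_table, control, seed = seed, scope = "full")
}
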