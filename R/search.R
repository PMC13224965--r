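# Strict hill-climbing over level-1 network space: candidate topologies are
# produced by the five moves, scored by optimizing their continuous
# parameters, and accepted only on a strict improvement of the log composite
# likelihood.  Multiple independent runs (each with its own RNG stream and,
# optionally, its own quartet subsample) guard against local optima;
# reticulation removal is never proposed because under strict hill-climbing
# removing a reticulation can never increase the composite likelihood.

#' Search configuration
#'
#' @param h Target number of reticulations (`h >= 0`); reticulations are
#'   introduced by `add_reticulation` moves during the climb and never
#'   removed.
#' @param runs Number of independent hill-climbing runs (default 10).
#' @param prop_quartets Proportion in `(0, 1]` of 4-taxon sets used during
#'   each run (default 1, i.e. all); a per-run subsample of
#'   `ceiling(k * prop_quartets)` sets is drawn at the start of each run and
#'   the final network is always rescored against the full table.
#' @param prob_qr Probability in `[0, 1]` of using misfit-weighted (rather
#'   than uniform) selection of the focus edge for a move (default 0).
#' @param seed Master integer seed; per-run streams are derived from it.
#' @param max_failures Consecutive rejected or invalid proposals after which
#'   a run stops (default 100).
#' @param accept_tol Numerical tolerance implementing the strict-improvement
#'   acceptance rule under floating point: a candidate is accepted iff its
#'   logCL exceeds the incumbent's by more than `accept_tol` (sub-tolerance
#'   differences are optimizer jitter, not signal, and count as ties, which
#'   are rejected).
#' @param optimizer A [qcf_control()] list for the continuous optimization.
#' @return A list of class `qcf_search_config`.
#' @export
qcf_search_config <- function(h = 0L, runs = 10L, prop_quartets = 1,
                              prob_qr = 0, seed = 1L, max_failures = 100L,
                              accept_tol = 1e-6, optimizer = qcf_control()) {
  stopifnot(h >= 0, runs >= 1, prop_quartets > 0, prop_quartets <= 1,
            prob_qr >= 0, prob_qr <= 1, max_failures >= 1, accept_tol >= 0)
  structure(list(h = as.integer(h), runs = as.integer(runs),
                 prop_quartets = prop_quartets, prob_qr = prob_qr,
                 seed = as.integer(seed),
                 max_failures = as.integer(max_failures),
                 accept_tol = accept_tol,
                 optimizer = optimizer),
            class = "qcf_search_config")
}

#' Expected CFs of the incumbent network for move weighting
#'
#' Recomputed after every accepted move: the misfit weights that drive
#' weighted focus selection always refer to the current network at its
#' current parameter values.
#'
#' @param net The incumbent network (with optimized parameters).
#' @param table The `cf_table` in use by the run.
#' @param workers Parallel workers for the per-quartet computation.
#' @return A `k x 3` expected-CF matrix aligned with the table.
#' @export
assemble_expected_for_weights <- function(net, table, workers = 1L) {
  expected_cf_network(net, cf_matrix(table)$quartets, workers = workers)
}

# Move types applicable to the current state.
applicable_moves <- function(net, h_target) {
  mv <- character(0)
  if (length(legal_foci(net, "NNI"))) mv <- c(mv, "NNI")
  if (net$h < h_target) mv <- c(mv, "add_reticulation")
  if (net$h >= 1L) mv <- c(mv, "flip_direction", "move_origin", "move_target")
  mv
}

#' One strict hill-climbing run
#'
#' Starting from `start`, repeatedly proposes one of the applicable moves at
#' a focus chosen by [select_focus()], optimizes the candidate's continuous
#' parameters, and accepts iff the candidate's log composite likelihood
#' strictly exceeds the incumbent's (`L1 > L0`; ties are rejected).  The run
#' stops after `max_failures` consecutive rejected or invalid proposals.
#'
#' @param start A valid starting `qcf_network` (or tree) with
#'   `h <= config$h`.
#' @param table The `cf_table` scored during this run (possibly a
#'   subsample).
#' @param config A [qcf_search_config()].
#' @param run_seed Integer seed of this run's RNG stream.
#' @param scope Scope label stored on scores (`"full"` or `"subsample"`).
#' @param workers Parallel workers for expected-CF assembly.
#' @return A list of class `qcf_run` with elements `trace` (one row per
#'   proposal: move, accepted, logCL of the incumbent after the proposal),
#'   `final` (the incumbent `qcf_score`), `run_seed`, `n_accepted`.
#' @export
hill_climb_run <- function(start, table, config = qcf_search_config(),
                           run_seed = config$seed, scope = "full",
                           workers = 1L) {
  if (inherits(start, "phylo")) start <- phylo_to_net(start)
  bad <- validate_network(start)
  if (length(bad)) stop("invalid starting topology: ", paste(bad, collapse = ", "))
  if (start$h > config$h)
    stop("starting topology has more reticulations than the target h")
  ctrl <- config$optimizer
  set.seed(run_seed)
  inc <- optimize_parameters(start, table, ctrl,
                             seed = mix_seed(run_seed, 1L), scope = scope)
  inc_map <- NULL
  expected <- NULL
  if (config$prob_qr > 0) {
    inc_map <- compile_cf_map(inc$network, cf_matrix(table)$quartets)
    expected <- assemble_expected_for_weights(inc$network, table, workers)
  }
  inc_topo <- write_enewick(inc$network, canonical = TRUE, annotate = FALSE)
  fail <- 0L; iter <- 0L; n_acc <- 0L
  tr_move <- character(0); tr_acc <- logical(0); tr_logcl <- numeric(0)
  while (fail < config$max_failures) {
    iter <- iter + 1L
    mv <- applicable_moves(inc$network, config$h)
    if (length(mv) == 0L) break
    move <- mv[sample.int(length(mv), 1L)]
    focus <- select_focus(inc$network, table, expected, config$prob_qr,
                          move, map = inc_map)
    cand <- if (is.na(focus)) NULL else propose_move(inc$network, move, focus)
    # a rearrangement that reproduces the incumbent's semi-directed topology
    # is no rearrangement: reject it unscored (rescoring the same topology
    # could only drift upward by optimizer jitter)
    if (!is.null(cand) &&
        write_enewick(cand, canonical = TRUE, annotate = FALSE) == inc_topo)
      cand <- NULL
    accepted <- FALSE
    if (!is.null(cand)) {
      # inherited lengths at the 0 boundary are flat under the log transform
      # and would trap the candidate's optimization; start them slightly off
      cand$length[!is.na(cand$length) & cand$length < 0.01] <- 0.01
      sc <- optimize_parameters(cand, table, ctrl,
                                seed = mix_seed(run_seed, 1000L + iter),
                                scope = scope)
      if (sc$logCL > inc$logCL + config$accept_tol) {
        inc <- sc
        inc_topo <- write_enewick(inc$network, canonical = TRUE, annotate = FALSE)
        accepted <- TRUE
        n_acc <- n_acc + 1L
        fail <- 0L
        if (config$prob_qr > 0) {
          inc_map <- compile_cf_map(inc$network, cf_matrix(table)$quartets)
          expected <- assemble_expected_for_weights(inc$network, table, workers)
        }
      }
    }
    if (!accepted) fail <- fail + 1L
    tr_move <- c(tr_move, move); tr_acc <- c(tr_acc, accepted)
    tr_logcl <- c(tr_logcl, inc$logCL)
  }
  structure(list(trace = data.frame(move = tr_move, accepted = tr_acc,
                                    logCL = tr_logcl),
                 final = inc, run_seed = run_seed, n_accepted = n_acc),
            class = "qcf_run")
}

#' Multi-run network search with final full-table rescoring
#'
#' Runs `config$runs` independent hill-climbs with per-run seeds derived
#' from the master seed and per-run quartet subsamples of size
#' `ceiling(k * prop_quartets)`, rescoring each run's incumbent against the
#' full table, and returns the network with the best full-table log
#' composite likelihood.  Fully reproducible given `config$seed`.
#'
#' @param start_topologies A list of starting networks/trees (recycled
#'   across runs).
#' @param full_table The complete `cf_table`.
#' @param config A [qcf_search_config()].
#' @param workers Parallel workers for expected-CF assembly.
#' @return A list with elements `best` (a full-scope `qcf_score`), `runs`
#'   (per-run `qcf_run` objects, each with `$full` the rescored
#'   `qcf_score`), and `best_run`.
#' @export
multi_run_search <- function(start_topologies, full_table,
                             config = qcf_search_config(), workers = 1L) {
  if (!is.list(start_topologies) || inherits(start_topologies, "phylo") ||
      inherits(start_topologies, "qcf_network"))
    start_topologies <- list(start_topologies)
  runs <- vector("list", config$runs)
  for (r in seq_len(config$runs)) {
    rs <- mix_seed(config$seed, r)
    tab <- if (config$prop_quartets < 1)
      subsample_quartets(full_table, config$prop_quartets,
                         seed = mix_seed(rs, 777L))
    else full_table
    scope <- if (config$prop_quartets < 1) "subsample" else "full"
    start <- start_topologies[[(r - 1L) %% length(start_topologies) + 1L]]
    run <- hill_climb_run(start, tab, config, run_seed = rs, scope = scope,
                          workers = workers)
    run$full <- final_full_score(run$final$network, full_table,
                                 config$optimizer, seed = mix_seed(rs, 999L))
    runs[[r]] <- run
  }
  scores <- vapply(runs, function(r) r$full$logCL, 0.0)
  best_run <- which.max(scores)
  list(best = runs[[best_run]]$full, runs = runs, best_run = best_run)
}
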