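## The stochastic update engine. The elementary semantics: each iteration
## draws a fresh uniformly random permutation of the nodes and updates them in
## that order against the evolving state. A node whose rule is satisfied but
## which is OFF switches ON with probability p_a; a node whose rule is
## unsatisfied but which is ON switches OFF with probability p_d; otherwise
## nothing happens. Ensembles run in compiled code with a counter-seeded
## xoshiro256++ generator so results are reproducible across platforms and
## independent of R's RNG state.

## ---- bytecode compiler ------------------------------------------------------

.emit_postfix <- function(expr, var_index) {
  out <- integer(0)
  rec <- function(e) {
    switch(e$kind,
      const = out <<- c(out, 0L, e$value),
      var = out <<- c(out, 1L, var_index[[e$name]]),
      not = { rec(e$children[[1L]]); out <<- c(out, 2L, 0L) },
      and = { for (c in e$children) rec(c); out <<- c(out, 3L, length(e$children)) },
      or = { for (c in e$children) rec(c); out <<- c(out, 4L, length(e$children)) }
    )
  }
  rec(expr)
  out
}

.compile_model <- function(model) {
  nms <- node_names(model)
  var_index <- stats::setNames(seq_along(nms) - 1L, nms)  # 0-based
  code <- integer(0)
  node_off <- integer(length(nms) + 1L)
  for (i in seq_along(nms)) {
    node_off[i] <- length(code) / 2L
    code <- c(code, .emit_postfix(model$nodes[[i]]$rule, var_index))
  }
  node_off[length(nms) + 1L] <- length(code) / 2L
  list(code = code, node_off = node_off,
       pa = vapply(model$nodes, `[[`, numeric(1), "p_a"),
       pd = vapply(model$nodes, `[[`, numeric(1), "p_d"),
       names = nms)
}

## initial-state spec vector for the compiled engine:
## -1 = independent fair coin, otherwise the fixed bit
.initial_spec <- function(model, scen) {
  nms <- node_names(model)
  init <- stats::setNames(rep(0L, length(nms)), nms)
  if ("LCK" %in% nms) init[["LCK"]] <- 1L  # basal pool of active LCK
  for (nm in intersect(scen$active_inputs, nms)) init[[nm]] <- -1L
  for (p in scen$perturbations) {
    if (!is.null(p$forced_initial)) init[[p$node]] <- p$forced_initial
  }
  init
}

## ---- elementary operations (reference R implementations) -------------------

#' Stochastic single-node update
#'
#' The elementary update applied to one node: with `f` the value of the
#' node's rule under `state` and `x` its current value, returns 1 with
#' probability `p_a` (else 0) when `f = 1, x = 0`; returns 0 with probability
#' `p_d` (else 1) when `f = 0, x = 1`; returns `x` unchanged when `f = x`.
#'
#' @param state complete named 0/1 state vector.
#' @param spec a [node_spec()].
#' @param draw a uniform random number in `[0,1)`; defaults to `runif(1)`.
#' @return bit 0/1.
#' @export
update_node <- function(state, spec, draw = stats::runif(1)) {
  stopifnot(inherits(spec, "node_spec"))
  f <- eval_expression(spec$rule, state)
  x <- as.integer(state[[spec$name]])
  if (f == x) return(x)
  if (f == 1L) return(if (draw < spec$p_a) 1L else 0L)
  if (draw < spec$p_d) 0L else 1L
}

#' One random-order asynchronous iteration
#'
#' Draws a uniformly random permutation of all nodes and applies
#' [update_node()] to each in that order against the evolving state: later
#' nodes in the permutation see earlier nodes' new values. Uses R's RNG
#' (control it with `set.seed()`); ensemble simulation uses its own
#' deterministic generator instead.
#'
#' @param state complete named 0/1 state vector.
#' @param model a validated [logic_model()].
#' @return the updated state vector.
#' @export
step <- function(state, model) {
  stopifnot(inherits(model, "logic_model"))
  for (nm in sample(node_names(model))) {
    state[[nm]] <- update_node(state, model$nodes[[nm]])
  }
  state
}

#' Draw an initial state for a scenario
#'
#' Every node starts at 0 except: perturbed nodes with a forced initial state
#' take that value; the node `LCK` (if present and unperturbed) starts at 1
#' (basal active pool); each active input node is an independent fair coin.
#' Inactive inputs are 0. Uses R's RNG for the coin draws.
#'
#' @param model a validated [logic_model()].
#' @param scen a [scenario()].
#' @return named integer 0/1 vector over all nodes.
#' @export
make_initial_state <- function(model, scen) {
  validate_scenario(model, scen)
  init <- .initial_spec(model, scen)
  coin <- init == -1L
  init[coin] <- as.integer(stats::runif(sum(coin)) < 0.5)
  init
}

## ---- ensemble simulation ----------------------------------------------------

#' Simulate an ensemble of replicates
#'
#' Runs `scen$replicates` independent replicates of `scen$horizon` iterations
#' from freshly drawn initial states and aggregates per-node activity: entry
#' `(t, i)` of the activity matrix is the fraction of replicates in which node
#' `i` is ON at iteration `t` (row `0` is the initial state). Fully
#' reproducible from `(model, scen, scen$seed)`.
#'
#' @param model a validated [logic_model()].
#' @param scen a [scenario()].
#' @param update `"asynchronous"` (random-order, the model's semantics) or
#'   `"synchronous"` (all rules evaluated on the old state; comparison only).
#' @param record_joint_at optional integer iterations at which to record the
#'   joint state distribution (models with <= 20 nodes only); used to compare
#'   against the exact Markov kernel.
#' @return object of class `ensemble_result`: `activity` matrix
#'   `(T+1) x n_nodes` with iteration rownames `0..T`, `nodes`, `scenario`,
#'   `seed`, and when requested `joint` (matrix: recorded iteration x 2^n
#'   state probabilities, states in binary order, first node most significant).
#' @export
simulate_ensemble <- function(model, scen, update = c("asynchronous", "synchronous"),
                              record_joint_at = NULL) {
  stopifnot(inherits(model, "logic_model"), inherits(scen, "scenario"))
  update <- match.arg(update)
  concrete <- apply_scenario(model, scen)
  comp <- .compile_model(concrete)
  init <- .initial_spec(concrete, scen)
  rec <- if (is.null(record_joint_at)) integer(0) else
    sort(unique(as.integer(record_joint_at)))
  if (length(rec) && (min(rec) < 0 || max(rec) > scen$horizon)) {
    stop("record_joint_at iterations must lie in [0, horizon]", call. = FALSE)
  }
  res <- .cpp_simulate(comp$code, comp$node_off, comp$pa, comp$pd,
                       unname(init), scen$horizon, scen$replicates,
                       as.double(scen$seed), update == "synchronous", rec,
                       scen$steady_window)
  activity <- res$activity
  dimnames(activity) <- list(iteration = 0:scen$horizon, node = comp$names)
  repw <- res$replicate_steady
  colnames(repw) <- comp$names
  out <- list(activity = activity, nodes = comp$names, scenario = scen,
              seed = scen$seed, update = update, replicate_steady = repw)
  if (length(rec)) {
    joint <- res$joint
    rownames(joint) <- rec
    out$joint <- joint
  }
  structure(out, class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %d nodes, T=%d, R=%d, seed=%d (%s)\n",
              length(x$nodes), nrow(x$activity) - 1L, x$scenario$replicates,
              x$seed, x$update))
  invisible(x)
}

#' Steady-state summary of an ensemble
#'
#' Per node, the mean activity over the final `window` iterations
#' (`T - W + 1 .. T`). For readout nodes these are the signature fractions
#' reported as `p_cfunc`, `p_cinhib` and `p_tapop`.
#'
#' @param result an [ensemble_result][simulate_ensemble].
#' @param window number of final iterations W; defaults to the scenario's
#'   `steady_window`.
#' @return named numeric vector of steady fractions, one per node.
#' @export
steady_state_summary <- function(result, window = NULL) {
  stopifnot(inherits(result, "ensemble_result"))
  horizon <- nrow(result$activity) - 1L
  if (is.null(window)) window <- result$scenario$steady_window
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be >= 1", call. = FALSE)
  if (window > horizon) stop("window must not exceed the horizon", call. = FALSE)
  rows <- (horizon - window + 2L):(horizon + 1L)  # iterations T-W+1 .. T
  colMeans(result$activity[rows, , drop = FALSE])
}

#' Empirical standard error of the steady fractions
#'
#' The steady fraction is the mean over replicates of each replicate's
#' ON-fraction across the scenario's steady window; its standard error is
#' estimated as `sd(replicate window means) / sqrt(R)`. This is the correct
#' SE of the windowed estimate; the single-iteration binomial form
#' `sqrt(p(1-p)/R)` is an upper bound on it.
#'
#' @param result an [ensemble_result][simulate_ensemble].
#' @return named numeric vector of standard errors, one per node (for the
#'   window fixed by the scenario's `steady_window`).
#' @export
steady_state_se <- function(result) {
  stopifnot(inherits(result, "ensemble_result"))
  repw <- result$replicate_steady
  apply(repw, 2L, stats::sd) / sqrt(nrow(repw))
}
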