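## Scenarios: which input ligands are active, per-node perturbations,
## simulation horizon, replicate count, seed and steady-state window.

#' Define a per-node perturbation
#'
#' A perturbation can force a node's initial state and/or override its
#' propensities for the whole run. [knockout()] forces initial 0 with
#' `p_a = 0` (the node can never switch ON); [overexpression()] forces
#' initial 1 with `p_a = 1`. Overexpression leaves `p_d` untouched by
#' default, so an overexpressed node still degrades transiently when its
#' rule is unsatisfied; `strict_clamp = TRUE` additionally sets `p_d = 0`.
#'
#' @param node node name.
#' @param forced_initial 0, 1 or NULL (leave the default initial state).
#' @param p_a,p_d propensity overrides in `[0,1]`, or NULL to keep the node's own.
#' @param strict_clamp for [overexpression()]: also set `p_d = 0`.
#' @return object of class `perturbation`.
#' @export
perturbation <- function(node, forced_initial = NULL, p_a = NULL, p_d = NULL) {
  stopifnot(is.character(node), length(node) == 1L)
  chk01 <- function(x, what) {
    if (!is.null(x) && (!is.numeric(x) || is.na(x) || x < 0 || x > 1)) {
      stop(what, " override must lie in [0,1]", call. = FALSE)
    }
  }
  if (!is.null(forced_initial) && !forced_initial %in% c(0, 1)) {
    stop("forced_initial must be 0, 1 or NULL", call. = FALSE)
  }
  chk01(p_a, "p_a"); chk01(p_d, "p_d")
  structure(list(node = node,
                 forced_initial = if (is.null(forced_initial)) NULL
                                  else as.integer(forced_initial),
                 p_a = p_a, p_d = p_d),
            class = "perturbation")
}

#' @rdname perturbation
#' @export
knockout <- function(node) perturbation(node, forced_initial = 0, p_a = 0)

#' @rdname perturbation
#' @export
overexpression <- function(node, strict_clamp = FALSE) {
  perturbation(node, forced_initial = 1, p_a = 1,
               p_d = if (strict_clamp) 0 else NULL)
}

#' Define a simulation scenario
#'
#' @param active_inputs names of input nodes supplied with ligand; they start
#'   at an independent fair coin draw and carry a constant-TRUE rule for the
#'   run (continuous engagement). Inactive inputs are held at 0.
#' @param perturbations list of [perturbation()] objects.
#' @param horizon number of update iterations T (>= 1).
#' @param replicates ensemble size R (>= 1).
#' @param seed integer base seed; every random draw of the run derives from it.
#' @param steady_window number of final iterations W (1 <= W <= T) averaged by
#'   [steady_state_summary()]; defaults to `min(20, horizon)`.
#' @param name optional scenario label.
#' @return object of class `scenario`.
#' @export
scenario <- function(active_inputs = character(0), perturbations = list(),
                     horizon = 100, replicates = 10000, seed = 1,
                     steady_window = NULL, name = NULL) {
  if (inherits(perturbations, "perturbation")) perturbations <- list(perturbations)
  stopifnot(is.list(perturbations))
  for (p in perturbations) stopifnot(inherits(p, "perturbation"))
  horizon <- as.integer(horizon); replicates <- as.integer(replicates)
  if (is.null(steady_window)) steady_window <- min(20L, horizon)
  steady_window <- as.integer(steady_window)
  if (horizon < 1L) stop("horizon must be >= 1", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  if (steady_window < 1L) stop("steady_window must be >= 1", call. = FALSE)
  if (steady_window > horizon) {
    stop("steady_window must not exceed the horizon", call. = FALSE)
  }
  structure(list(active_inputs = unique(as.character(active_inputs)),
                 perturbations = perturbations,
                 horizon = horizon, replicates = replicates,
                 seed = as.integer(seed), steady_window = steady_window,
                 name = name),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario>%s active_inputs={%s}, %d perturbation(s), T=%d, R=%d, W=%d, seed=%d\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              paste(x$active_inputs, collapse = ","),
              length(x$perturbations), x$horizon, x$replicates,
              x$steady_window, x$seed))
  invisible(x)
}

#' Check a scenario against a model
#'
#' @param model a [logic_model()].
#' @param scen a [scenario()].
#' @return invisibly TRUE; errors describe every problem found.
#' @export
validate_scenario <- function(model, scen) {
  stopifnot(inherits(model, "logic_model"), inherits(scen, "scenario"))
  problems <- character(0)
  inputs <- input_nodes(model)
  extra <- setdiff(scen$active_inputs, inputs)
  if (length(extra)) {
    problems <- c(problems, paste0("active_inputs not input nodes of the model: ",
                                   paste(extra, collapse = ", ")))
  }
  for (p in scen$perturbations) {
    if (!p$node %in% node_names(model)) {
      problems <- c(problems, paste0("perturbation targets unknown node: ", p$node))
    }
  }
  if (length(problems)) {
    stop("invalid scenario:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Apply a scenario to a model
#'
#' Returns the concrete model actually simulated: active input nodes get a
#' constant-TRUE rule, inactive inputs a constant-FALSE rule, and perturbation
#' propensity overrides are written into the node specifications.
#'
#' @inheritParams validate_scenario
#' @return a [logic_model()].
#' @export
apply_scenario <- function(model, scen) {
  validate_scenario(model, scen)
  for (nm in input_nodes(model)) {
    model$nodes[[nm]]$rule <-
      bool_const(as.integer(nm %in% scen$active_inputs))
  }
  for (p in scen$perturbations) {
    if (!is.null(p$p_a)) model$nodes[[p$node]]$p_a <- p$p_a
    if (!is.null(p$p_d)) model$nodes[[p$node]]$p_d <- p$p_d
  }
  model
}

#' Read / write a scenario configuration file
#'
#' YAML with keys `active_inputs`, `perturbations` (list of mappings with
#' `node` and optional `forced_initial`, `pa`, `pd`), `horizon`, `replicates`,
#' `seed`, `steady_window`, `name`.
#'
#' @param path file path.
#' @param scen a [scenario()] (for writing).
#' @return [read_scenario()] returns a [scenario()].
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  perts <- lapply(cfg$perturbations %||% list(), function(p) {
    perturbation(p$node, forced_initial = p$forced_initial,
                 p_a = p$pa, p_d = p$pd)
  })
  scenario(active_inputs = unlist(cfg$active_inputs) %||% character(0),
           perturbations = perts,
           horizon = cfg$horizon %||% 100,
           replicates = cfg$replicates %||% 10000,
           seed = cfg$seed %||% 1,
           steady_window = cfg$steady_window %||% 20,
           name = cfg$name)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(scen, path) {
  stopifnot(inherits(scen, "scenario"))
  cfg <- list(name = scen$name,
              active_inputs = as.list(scen$active_inputs),
              perturbations = lapply(scen$perturbations, function(p) {
                Filter(Negate(is.null),
                       list(node = p$node, forced_initial = p$forced_initial,
                            pa = p$p_a, pd = p$p_d))
              }),
              horizon = scen$horizon, replicates = scen$replicates,
              seed = scen$seed, steady_window = scen$steady_window)
  yaml::write_yaml(Filter(Negate(is.null), cfg), path)
  invisible(path)
}
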