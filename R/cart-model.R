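## The packaged CAR T-cell / tumor interaction model and its experiments:
## named receptor-ligation scenarios and the knockout/overexpression scan.

#' Node-name aliases accepted when loading CART model files
#'
#' `PERGRZM` (perforin/granzyme B) is canonicalized to `PERGRZB`, and the
#' inhibition readout `CINHI` to `CINHIB`.
#' @return named character vector alias -> canonical name.
#' @export
cart_aliases <- function() c(PERGRZM = "PERGRZB", CINHI = "CINHIB")

#' The curated 59-node CAR T-cell / tumor signaling model
#'
#' Loads the packaged model: 59 nodes covering CAR ligation (scFv, CD28,
#' CD3zeta, LCK, ZAP70), MAPK / PI3K-AKT-MTORC1 / calcium / PKCtheta
#' signaling, IL2 cytokine signaling, cytotoxic granule release, the PD1 and
#' CTLA4 inhibitory axes, and the downstream transcription factors, with four
#' ligand-expression inputs (`TAex`, `IL2ex`, `PDL1L2ex`, `CD8086ex`) and
#' three readout nodes (`CFUNC`, `CINHIB`, `TAPOP`). All nodes carry the
#' default propensities `p_a = 0.5`, `p_d = 0.05`.
#'
#' Three curation corrections relative to the printed rule table are applied
#' and recorded in the model metadata: the LCK rule's unbalanced parentheses
#' are minimally balanced, the node names PERGRZB/CINHIB are canonicalized
#' (aliases PERGRZM/CINHI accepted), and the undefined symbol CDSYF is
#' dropped from the CFUNC rule, which reads `AP1 & NFAT & MTORC1`.
#'
#' @return a validated [logic_model()].
#' @export
build_cart_model <- function() {
  path <- system.file("extdata", "cart_table1.model", package = "cartlogic",
                      mustWork = TRUE)
  m <- load_model(path, aliases = cart_aliases())
  m$metadata$corrections <- c(
    LCK = "unbalanced parentheses minimally balanced, preserving the printed token sequence",
    PERGRZB = "node canonically named PERGRZB; PERGRZM accepted as an alias",
    CINHIB = "readout canonically named CINHIB; CINHI accepted as an alias",
    CFUNC = "undefined symbol CDSYF dropped; rule is AP1 & NFAT & MTORC1")
  m
}

#' Named receptor-ligation scenarios
#'
#' The five ligation scenarios over the four input ligands: `A` CAR ligation
#' only (`TAex`); `B` adds IL2; `C` additionally engages both inhibitory
#' ligands (`PDL1L2ex`, `CD8086ex`); `D` blocks PDL1L2 (CD8086 still
#' engaged); `E` blocks CD8086 (PDL1L2 still engaged).
#'
#' @return named list: scenario id -> character vector of active inputs.
#' @export
cart_scenarios <- function() {
  list(A = "TAex",
       B = c("TAex", "IL2ex"),
       C = c("TAex", "IL2ex", "PDL1L2ex", "CD8086ex"),
       D = c("TAex", "IL2ex", "CD8086ex"),
       E = c("TAex", "IL2ex", "PDL1L2ex"))
}

#' Readout node set of a model
#'
#' Maps the model's readout nodes onto the three signaling signatures:
#' CART-cell function (`cfunc`), CART-cell inhibition (`cinhib`) and tumor
#' apoptosis (`tapop`).
#'
#' @param model a [logic_model()].
#' @return list with fields `cfunc`, `cinhib`, `tapop` (node names).
#' @export
readout_set <- function(model) {
  ro <- readout_nodes(model)
  find <- function(candidates) {
    hit <- intersect(candidates, ro)
    if (length(hit) != 1L) {
      stop("cannot identify readout among {", paste(ro, collapse = ", "),
           "}: expected one of ", paste(candidates, collapse = "/"),
           call. = FALSE)
    }
    hit
  }
  list(cfunc = find("CFUNC"), cinhib = find("CINHIB"), tapop = find("TAPOP"))
}

#' Steady signature fractions of an ensemble
#'
#' @param result an [ensemble_result][simulate_ensemble] of a model with the
#'   three signature readouts.
#' @param model the model the ensemble was run on.
#' @param window steady-state window; defaults to the scenario's.
#' @return named numeric vector `c(p_cfunc, p_cinhib, p_tapop)`.
#' @export
readout_fractions <- function(result, model, window = NULL) {
  rs <- readout_set(model)
  steady <- steady_state_summary(result, window)
  c(p_cfunc = unname(steady[[rs$cfunc]]),
    p_cinhib = unname(steady[[rs$cinhib]]),
    p_tapop = unname(steady[[rs$tapop]]))
}

#' Run a named (or custom) ligation scenario
#'
#' Simulates the packaged CART model (or a user model) under one of the named
#' ligation scenarios `A`-`E`, or under an explicit [scenario()].
#'
#' @param name scenario id in `names(cart_scenarios())`, or a [scenario()].
#' @param model the model to simulate; defaults to [build_cart_model()].
#' @param replicates,horizon,steady_window,seed simulation parameters used
#'   when `name` is an id (ignored for an explicit scenario).
#' @param perturbations optional list of [perturbation()]s added to the named
#'   scenario.
#' @return list with `ensemble` (an [ensemble_result][simulate_ensemble]),
#'   `steady` (per-node steady fractions) and `readouts`
#'   (`p_cfunc`, `p_cinhib`, `p_tapop`).
#' @export
run_scenario <- function(name, model = build_cart_model(),
                         replicates = 10000, horizon = 100,
                         steady_window = 20, seed = 1,
                         perturbations = list()) {
  if (inherits(name, "scenario")) {
    scen <- name
  } else {
    lib <- cart_scenarios()
    if (!is.character(name) || length(name) != 1L || !name %in% names(lib)) {
      stop("unknown scenario: ", deparse(name), " (known: ",
           paste(names(lib), collapse = ", "), ")", call. = FALSE)
    }
    scen <- scenario(active_inputs = lib[[name]], perturbations = perturbations,
                     horizon = horizon, replicates = replicates, seed = seed,
                     steady_window = steady_window, name = name)
  }
  ens <- simulate_ensemble(model, scen)
  steady <- steady_state_summary(ens)
  list(ensemble = ens, steady = steady,
       readouts = readout_fractions(ens, model))
}

#' Long-format trajectory table
#'
#' @param result an [ensemble_result][simulate_ensemble].
#' @param nodes nodes to include; defaults to all.
#' @return data.frame with columns `iteration`, `node`, `activity`, ordered by
#'   node then iteration.
#' @export
trajectory_report <- function(result, nodes = NULL) {
  stopifnot(inherits(result, "ensemble_result"))
  if (is.null(nodes)) nodes <- result$nodes
  unknown <- setdiff(nodes, result$nodes)
  if (length(unknown)) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  iters <- as.integer(rownames(result$activity))
  do.call(rbind, lapply(nodes, function(nm) {
    data.frame(iteration = iters, node = nm,
               activity = unname(result$activity[, nm]),
               stringsAsFactors = FALSE)
  }))
}

#' Iteration at which a node's activity first crosses half its maximum
#'
#' Convenience for checking signal-propagation ordering along a cascade.
#'
#' @param result an [ensemble_result][simulate_ensemble].
#' @param node node name.
#' @return iteration index (0-based), or NA if the node never activates.
#' @export
half_max_crossing <- function(result, node) {
  y <- result$activity[, node]
  m <- max(y)
  if (m <= 0) return(NA_integer_)
  as.integer(which(y >= m / 2)[1L]) - 1L
}

.derive_seed <- function(base, i) {
  (as.double(base) + 40503 * as.double(i)) %% 2147483647
}

#' Default perturbation-scan targets
#'
#' The internal CART-compartment nodes: every node except the four
#' ligand-expression inputs, the tumor-side nodes, interface nodes and the
#' three readouts.
#'
#' @param model a [logic_model()].
#' @return character vector of node names.
#' @export
default_scan_targets <- function(model) {
  roles <- node_roles(model)
  comps <- node_compartments(model)
  names(which(roles == "internal" & comps == "cart"))
}

#' Knockout / overexpression perturbation scan
#'
#' For every target node, runs a knockout ensemble (initial 0, `p_a = 0`) and
#' an overexpression ensemble (initial 1, `p_a = 1`) under the control
#' scenario's ligation conditions, and reports the percent change of the
#' steady signature fractions (`p_cfunc`, `p_cinhib`, `p_tapop`) relative to
#' the unperturbed control. Percent change is `100 * (p - p_ctrl) / p_ctrl`,
#' reported unclipped and set to `NA` (undefined) where the control fraction
#' is 0. Raw fractions and binomial standard errors
#' (`sqrt(p * (1 - p) / R)`) accompany every percentage. Control and
#' perturbed runs use independent seeds derived deterministically from the
#' control scenario's seed.
#'
#' @param model the model; defaults to [build_cart_model()].
#' @param control the control [scenario()]; defaults to ligation scenario `C`
#'   (all four inputs active).
#' @param targets nodes to perturb; defaults to [default_scan_targets()].
#' @param modes subset of `c("knockout", "overexpression")`.
#' @return object of class `perturbation_scan`: a data.frame with one row per
#'   (node, mode) and columns `p_cfunc`, `p_cinhib`, `p_tapop`, `pct_cfunc`,
#'   `pct_cinhib`, `pct_tapop`, `se_cfunc`, `se_cinhib`, `se_tapop`, plus a
#'   `control` attribute (named control fractions and their SEs).
#' @export
perturbation_scan <- function(model = build_cart_model(),
                              control = NULL,
                              targets = NULL,
                              modes = c("knockout", "overexpression")) {
  if (is.null(control)) {
    control <- scenario(active_inputs = cart_scenarios()$C, name = "C")
  }
  stopifnot(inherits(control, "scenario"))
  modes <- match.arg(modes, several.ok = TRUE)
  if (is.null(targets)) targets <- default_scan_targets(model)
  unknown <- setdiff(targets, node_names(model))
  if (length(unknown)) {
    stop("scan target(s) not in model: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  ctrl_ens <- simulate_ensemble(model, control)
  p_ctrl <- readout_fractions(ctrl_ens, model)
  if (all(p_ctrl == 0)) {
    stop("control readout fractions are all zero; scan aborted ",
         "(check the control scenario's active inputs)", call. = FALSE)
  }
  R <- control$replicates
  se <- function(p) sqrt(p * (1 - p) / R)
  pct <- function(p, p0) ifelse(p0 > 0, 100 * (p - p0) / p0, NA_real_)

  rows <- list()
  i <- 0L
  for (target in targets) {
    for (mode in modes) {
      i <- i + 1L
      pert <- if (mode == "knockout") knockout(target) else overexpression(target)
      scen <- scenario(active_inputs = control$active_inputs,
                       perturbations = c(control$perturbations, list(pert)),
                       horizon = control$horizon, replicates = R,
                       seed = .derive_seed(control$seed, i),
                       steady_window = control$steady_window,
                       name = paste0(mode, ":", target))
      p <- readout_fractions(simulate_ensemble(model, scen), model)
      rows[[i]] <- data.frame(
        node = target, mode = mode,
        p_cfunc = p[["p_cfunc"]], p_cinhib = p[["p_cinhib"]],
        p_tapop = p[["p_tapop"]],
        pct_cfunc = pct(p[["p_cfunc"]], p_ctrl[["p_cfunc"]]),
        pct_cinhib = pct(p[["p_cinhib"]], p_ctrl[["p_cinhib"]]),
        pct_tapop = pct(p[["p_tapop"]], p_ctrl[["p_tapop"]]),
        se_cfunc = se(p[["p_cfunc"]]), se_cinhib = se(p[["p_cinhib"]]),
        se_tapop = se(p[["p_tapop"]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "control") <- c(p_ctrl,
                            se_cfunc = se(p_ctrl[["p_cfunc"]]),
                            se_cinhib = se(p_ctrl[["p_cinhib"]]),
                            se_tapop = se(p_ctrl[["p_tapop"]]))
  attr(out, "control_scenario") <- control
  class(out) <- c("perturbation_scan", "data.frame")
  out
}
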