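## Tidy exports of simulation results: trajectory CSV, summary JSON, scan CSV,
## and the reproducibility manifest written by every CLI run.
## CSV dialect: comma separator, header row, '.' decimal, UTF-8, LF endings.

.write_csv <- function(df, path) {
  con <- file(path, open = "wb")  # binary mode forces LF on every platform
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Write a trajectory CSV
#'
#' Long format with columns `iteration`, `node`, `activity`; byte-identical
#' across repeated runs with the same (model, scenario, seed).
#'
#' @param result an [ensemble_result][simulate_ensemble].
#' @param path output file.
#' @param nodes nodes to include; defaults to all.
#' @return the path, invisibly.
#' @export
write_trajectory_csv <- function(result, path, nodes = NULL) {
  .write_csv(trajectory_report(result, nodes), path)
}

#' Write a steady-state summary JSON
#'
#' Per-node steady fractions over the scenario's steady window, the three
#' signature fractions when the model carries the readout set, and an echo of
#' the scenario (active inputs, perturbations, T, R, W, seed).
#'
#' @param result an [ensemble_result][simulate_ensemble].
#' @param model the simulated model (for the readout mapping); optional.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_summary_json <- function(result, path, model = NULL) {
  scen <- result$scenario
  steady <- steady_state_summary(result)
  payload <- list(
    scenario = list(
      name = scen$name,
      active_inputs = as.list(scen$active_inputs),
      perturbations = lapply(scen$perturbations, function(p) {
        Filter(Negate(is.null),
               list(node = p$node, forced_initial = p$forced_initial,
                    pa = p$p_a, pd = p$p_d))
      }),
      horizon = scen$horizon, replicates = scen$replicates,
      steady_window = scen$steady_window, seed = scen$seed),
    steady_fractions = as.list(steady))
  if (!is.null(model)) {
    payload$signatures <- as.list(readout_fractions(result, model))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a perturbation-scan CSV
#'
#' One row per (node, mode) with raw steady fractions, percent changes versus
#' control and binomial standard errors; the control row is prepended with
#' mode `"control"`.
#'
#' @param scan a [perturbation_scan()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  stopifnot(inherits(scan, "perturbation_scan"))
  ctrl <- attr(scan, "control")
  ctrl_row <- data.frame(
    node = "(control)", mode = "control",
    p_cfunc = ctrl[["p_cfunc"]], p_cinhib = ctrl[["p_cinhib"]],
    p_tapop = ctrl[["p_tapop"]],
    pct_cfunc = 0, pct_cinhib = 0, pct_tapop = 0,
    se_cfunc = ctrl[["se_cfunc"]], se_cinhib = ctrl[["se_cinhib"]],
    se_tapop = ctrl[["se_tapop"]], stringsAsFactors = FALSE)
  .write_csv(rbind(ctrl_row, as.data.frame(scan)), path)
}

#' Write a reproducibility manifest
#'
#' JSON record sufficient to reproduce a run exactly: package version, MD5 of
#' the serialized model, the scenario parameters and the seed.
#'
#' @param model the simulated [logic_model()].
#' @param scen the [scenario()].
#' @param path output file.
#' @param extra optional named list merged into the manifest.
#' @return the path, invisibly.
#' @export
write_manifest <- function(model, scen, path, extra = list()) {
  tmp <- tempfile(fileext = ".model")
  on.exit(unlink(tmp))
  save_model(model, tmp)
  manifest <- c(list(
    package = "cartlogic",
    version = as.character(utils::packageVersion("cartlogic")),
    model_name = model$name,
    model_md5 = unname(tools::md5sum(tmp)),
    n_nodes = length(model$nodes),
    scenario = list(
      name = scen$name, active_inputs = as.list(scen$active_inputs),
      perturbations = lapply(scen$perturbations, function(p) {
        Filter(Negate(is.null),
               list(node = p$node, forced_initial = p$forced_initial,
                    pa = p$p_a, pd = p$p_d))
      }),
      horizon = scen$horizon, replicates = scen$replicates,
      steady_window = scen$steady_window, seed = scen$seed)),
    extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
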