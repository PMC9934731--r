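test_that("the packaged CART model matches its published node table", {
  m <- build_cart_model()
  expect_equal(length(m$nodes), 59L)
  expect_setequal(input_nodes(m), c("TAex", "IL2ex", "PDL1L2ex", "CD8086ex"))
  expect_setequal(readout_nodes(m), c("CFUNC", "CINHIB", "TAPOP"))
  # every node at the default propensities
  expect_true(all(vapply(m$nodes, `[[`, numeric(1), "p_a") == 0.5))
  expect_true(all(vapply(m$nodes, `[[`, numeric(1), "p_d") == 0.05))
  # spot-checked rules
  expect_equal(format_expression(m$nodes[["IL2ge"]]$rule), "AP1 & NFKB & NFAT")
  expect_equal(format_expression(m$nodes[["IS"]]$rule), "!CASP3CASP7")
  expect_equal(format_expression(m$nodes[["CFUNC"]]$rule), "AP1 & NFAT & MTORC1")
  expect_equal(format_expression(m$nodes[["CASP3CASP7"]]$rule), "FASL | PERGRZB")
  expect_equal(truth_table(m$nodes[["dNFAT"]]$rule, c("NFAT", "AP1", "STAT5")),
               truth_table("(NFAT & !AP1) | (NFAT & !STAT5)",
                           c("NFAT", "AP1", "STAT5")))
  # the balanced LCK rule is equivalent to !LCK & (!SHP1 | ERK) & (!SHP2 | ERK)
  vars <- c("LCK", "SHP1", "SHP2", "ERK")
  expect_equal(
    truth_table(m$nodes[["LCK"]]$rule, vars),
    truth_table("!LCK & (!SHP1 | (SHP1 & ERK)) & (!SHP2 | (SHP2 & ERK))", vars))
  # curation corrections are recorded
  expect_true(all(c("LCK", "PERGRZB", "CINHIB", "CFUNC") %in%
                    names(m$metadata$corrections)))
})

test_that("legacy node names are accepted as aliases", {
  txt <- "PERGRZM = 1\nCASP = PERGRZB\nCINHI = CASP, role=readout\n"
  m <- load_model(txt, aliases = cart_aliases())
  expect_true(all(c("PERGRZB", "CINHIB") %in% node_names(m)))
  expect_false(any(c("PERGRZM", "CINHI") %in% node_names(m)))
})

test_that("the scenario library encodes the five ligation conditions", {
  lib <- cart_scenarios()
  expect_equal(names(lib), c("A", "B", "C", "D", "E"))
  expect_equal(lib$A, "TAex")
  expect_setequal(lib$C, c("TAex", "IL2ex", "PDL1L2ex", "CD8086ex"))
  expect_false("PDL1L2ex" %in% lib$D)
  expect_false("CD8086ex" %in% lib$E)
  m <- build_cart_model()
  for (s in lib) expect_true(all(s %in% input_nodes(m)))
  expect_error(run_scenario("Z", model = m), "unknown scenario")
})

test_that("structural zeros: unreachable nodes are exactly silent", {
  m <- build_cart_model()
  # no active inputs: tumor apoptosis is unreachable (cytotoxic granules
  # need PI3K, which needs CD28 or CTLA4, which need an engaged receptor)
  cl0 <- activatable_closure(m, initially_on = "LCK")
  expect_false("TAPOP" %in% cl0)
  e0 <- simulate_ensemble(m, scenario(horizon = 60, replicates = 1000, seed = 9))
  expect_true(all(e0$activity[, "TAPOP"] == 0))
  expect_true(all(e0$activity[, "CASP3CASP7"] == 0))
  # CAR ligation only: PD1 needs PDL1L2 (held 0), BATF needs PD1
  clA <- activatable_closure(m, initially_on = c("LCK", "TAex"))
  expect_false(any(c("PD1", "BATF") %in% clA))
  eA <- simulate_ensemble(m, scenario(active_inputs = "TAex", horizon = 60,
                                      replicates = 1000, seed = 9))
  expect_true(all(eA$activity[, "PD1"] == 0))
  expect_true(all(eA$activity[, "BATF"] == 0))
  # ZAP70 knockout severs NFAT (needs Calcineurin or P38, both ZAP70-dependent),
  # and CFUNC requires NFAT
  clKO <- activatable_closure(
    m, initially_on = c("LCK", cart_scenarios()$C), knocked_out = "ZAP70")
  expect_false("CFUNC" %in% clKO)
})

test_that("ensembles never activate nodes outside the activatable closure", {
  m <- build_cart_model()
  for (inputs in list(character(0), "TAex", c("TAex", "IL2ex"))) {
    cl <- activatable_closure(m, initially_on = c("LCK", inputs))
    silent <- setdiff(node_names(m), cl)
    e <- simulate_ensemble(m, scenario(active_inputs = inputs, horizon = 40,
                                       replicates = 500, seed = 14))
    expect_true(all(e$activity[, silent] == 0),
                info = paste(inputs, collapse = ","))
  }
})

test_that("trajectory reports are tidy and reject unknown nodes", {
  m <- build_cart_model()
  e <- simulate_ensemble(m, scenario(active_inputs = "TAex", horizon = 20,
                                     replicates = 200, seed = 2))
  rep_all <- trajectory_report(e)
  expect_equal(nrow(rep_all), 21L * 59L)
  expect_equal(names(rep_all), c("iteration", "node", "activity"))
  expect_true(all(trajectory_report(e, "IL2ex")$activity == 0))
  expect_error(trajectory_report(e, "NOPE"), "unknown node")
})

test_that("activation propagates down the CAR cascade in causal order", {
  m <- build_cart_model()
  e <- simulate_ensemble(m, scenario(active_inputs = "TAex", horizon = 60,
                                     replicates = 4000, seed = 33))
  # each node below is driven only through the previous one (no shortcuts)
  chain <- c("SCFV", "ZAP70", "PLCgamma1", "DAG", "RASGRP")
  cross <- vapply(chain, function(nd) half_max_crossing(e, nd), integer(1))
  expect_true(all(diff(cross) >= -2))  # upstream rises no later, MC slack
  expect_gt(cross[length(cross)], cross[1])
  # AP1 rises from 0 to a sustained plateau
  ap1 <- e$activity[, "AP1"]
  expect_equal(unname(ap1[1]), 0)
  late <- mean(ap1[41:61])
  expect_gt(late, 10 * sqrt(late * (1 - late) / 4000))
  sm <- stats::filter(ap1, rep(1 / 5, 5), sides = 1)
  expect_gt(min(diff(sm[seq(5, 30, by = 5)])), -0.02)  # monotone rise, smoothed
})

test_that("perturbation scan reports raw fractions, percent changes and SEs", {
  m <- build_cart_model()
  ctrl <- scenario(active_inputs = cart_scenarios()$C, horizon = 60,
                   replicates = 1500, seed = 4, steady_window = 20, name = "C")
  scan <- perturbation_scan(m, control = ctrl,
                            targets = c("ZAP70", "CASP3CASP7"))
  expect_equal(nrow(scan), 4L)  # 2 nodes x 2 modes
  expect_setequal(scan$mode, c("knockout", "overexpression"))
  ko_zap <- scan[scan$node == "ZAP70" & scan$mode == "knockout", ]
  expect_equal(ko_zap$p_cfunc, 0)
  expect_equal(ko_zap$pct_cfunc, -100)
  # TAPOP's sole regulator removed
  ko_casp <- scan[scan$node == "CASP3CASP7" & scan$mode == "knockout", ]
  expect_equal(ko_casp$p_tapop, 0)
  expect_equal(ko_casp$pct_tapop, -100)
  expect_true(all(scan$se_cfunc >= 0))
  expect_error(perturbation_scan(m, control = ctrl, targets = "NOPE"), "NOPE")
})

test_that("percent change is undefined (NA), not 0, when the control fraction is 0", {
  m <- build_cart_model()
  # with no active inputs nothing activates: all three readouts are 0 and the
  # scan aborts with a diagnostic
  ctrl0 <- scenario(horizon = 30, replicates = 300, seed = 8, name = "none")
  expect_error(perturbation_scan(m, control = ctrl0, targets = "ZAP70"),
               "control readout fractions are all zero")
  # knocking out the cytotoxic granules in the control zeroes p_tapop exactly
  # (CASP3CASP7 needs FASL or PERGRZB, both CYTOGRAN-dependent) while CFUNC
  # and CINHIB stay live: the tapop percent change must be NA, not 0
  ctrlA <- scenario(active_inputs = "TAex",
                    perturbations = list(knockout("CYTOGRAN")),
                    horizon = 60, replicates = 1000, seed = 8, name = "AxCYTO")
  scan <- perturbation_scan(m, control = ctrlA, targets = "SHP1",
                            modes = "knockout")
  expect_true(is.na(scan$pct_tapop))    # control p_tapop is exactly 0
  expect_false(is.na(scan$pct_cfunc))   # control p_cfunc > 0
  expect_equal(scan$p_tapop, 0)         # raw fraction still reported
})

test_that("default scan targets are the internal CART-compartment nodes", {
  m <- build_cart_model()
  targets <- default_scan_targets(m)
  expect_false(any(input_nodes(m) %in% targets))
  expect_false(any(readout_nodes(m) %in% targets))
  expect_false(any(c("TA", "FAS", "CASP3CASP7", "IS") %in% targets))
  expect_true(all(c("ZAP70", "PD1", "LCK", "ERK", "PDL1L2") %in% targets))
  # 59 nodes minus 4 inputs, 3 readouts, 3 internal tumor nodes, 1 interface
  expect_length(targets, 48L)
})
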