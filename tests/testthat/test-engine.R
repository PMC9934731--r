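test_that("update_node implements the propensity-gated switch semantics", {
  spec_a <- node_spec("X", "1", p_a = 0.5, p_d = 0.05)
  # no-event cases are deterministic
  expect_identical(update_node(c(X = 1L), spec_a, draw = 0.99), 1L)
  spec_off <- node_spec("X", "0", p_a = 0.5, p_d = 0.05)
  expect_identical(update_node(c(X = 0L), spec_off, draw = 0.0), 0L)
  # f=1, x=0: switches ON iff draw < p_a
  expect_identical(update_node(c(X = 0L), spec_a, draw = 0.49), 1L)
  expect_identical(update_node(c(X = 0L), spec_a, draw = 0.51), 0L)
  # f=0, x=1: switches OFF iff draw < p_d
  expect_identical(update_node(c(X = 1L), spec_off, draw = 0.04), 0L)
  expect_identical(update_node(c(X = 1L), spec_off, draw = 0.06), 1L)
})

test_that("update draw frequencies match the propensities", {
  n <- 1e5
  # activation: f=1, x=0, p_a=0.5
  on <- .cpp_update_draws(1L, 0L, 0.5, 0.05, n, 17)
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(mean(on) - 0.5), 3 * se)
  # degradation: f=0, x=1, p_d=0.05 -> OFF-switch frequency ~ 0.05
  off <- .cpp_update_draws(0L, 1L, 0.5, 0.05, n, 17)
  se_d <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(mean(1L - off) - 0.05), 3 * se_d)
  # no-event draws never change the state
  expect_true(all(.cpp_update_draws(1L, 1L, 0.5, 0.05, 1000, 3) == 1L))
  expect_true(all(.cpp_update_draws(0L, 0L, 0.5, 0.05, 1000, 3) == 0L))
})

test_that("step applies a random-order pass with within-iteration visibility", {
  m <- chain_model()  # A const TRUE, B = A, p_a = 1, p_d = 0
  # a node with p_a = 0 and value 0 stays 0 through any step
  ko <- logic_model(list(node_spec("A", "1", p_a = 0, p_d = 0.05)))
  set.seed(1)
  expect_identical(step(c(A = 0L), ko)[["A"]], 0L)
  # after one step from (0,0): B=1 iff B updated after A, i.e. half the time
  set.seed(42)
  hits <- replicate(4000, step(c(A = 0L, B = 0L), m)[["B"]])
  se <- sqrt(0.25 / 4000)
  expect_lt(abs(mean(hits) - 0.5), 3 * se)
  # A always switches ON (rule const TRUE, p_a = 1)
  set.seed(7)
  expect_identical(step(c(A = 0L, B = 0L), m)[["A"]], 1L)
})

test_that("initial states follow the scenario conventions", {
  m <- load_model(paste0("TAex = 0, role=input\nLCK = LCK\nZAP70 = LCK\n"))
  # no active inputs, no perturbations: all zero except LCK
  s <- make_initial_state(m, scenario())
  expect_identical(s, c(TAex = 0L, LCK = 1L, ZAP70 = 0L))
  # active input is a fair coin
  set.seed(5)
  draws <- replicate(4000, make_initial_state(
    m, scenario(active_inputs = "TAex"))[["TAex"]])
  expect_lt(abs(mean(draws) - 0.5), 3 * sqrt(0.25 / 4000))
  # forced initial wins over the LCK convention
  s2 <- make_initial_state(m, scenario(perturbations = list(
    perturbation("LCK", forced_initial = 0),
    perturbation("ZAP70", forced_initial = 1))))
  expect_identical(s2, c(TAex = 0L, LCK = 0L, ZAP70 = 1L))
  # unknown node in a perturbation is an error
  expect_error(
    make_initial_state(m, scenario(perturbations = list(knockout("NOPE")))),
    "NOPE")
})

test_that("constantly satisfied rule follows the activation recursion and never degrades", {
  m <- const_true_model(p_a = 0.5, p_d = 0.05)
  sc <- scenario(horizon = 10, replicates = 10000, seed = 99, steady_window = 2)
  e <- simulate_ensemble(m, sc)
  p <- 0
  for (t in 1:10) {
    p <- p + (1 - p) * 0.5
    se <- sqrt(max(p * (1 - p), 1e-12) / sc$replicates) + 1e-9
    expect_lt(abs(e$activity[t + 1L, "A"] - p), 3 * se)
  }
  # monotone no-event property: once ON a CONST-TRUE node never switches OFF,
  # so the ensemble fraction is non-decreasing, exactly
  expect_true(all(diff(e$activity[, "A"]) >= 0))
})

test_that("knockout is absorbing: activity identically zero", {
  m <- const_true_model()
  sc <- scenario(perturbations = list(knockout("A")),
                 horizon = 50, replicates = 2000, seed = 3)
  e <- simulate_ensemble(m, sc)
  expect_true(all(e$activity[, "A"] == 0))
  expect_equal(unname(steady_state_summary(e, 10)[["A"]]), 0)
})

test_that("self-inhibiting toggle reaches the birth-death balance p_a/(p_a+p_d)", {
  e <- simulate_ensemble(toggle_model(0.5, 0.05),
                         scenario(horizon = 200, replicates = 10000,
                                  seed = 21, steady_window = 50))
  p <- unname(steady_state_summary(e)[["A"]])
  expect_lt(abs(p - 10 / 11), 3 * sqrt((10 / 11) * (1 / 11) / 10000))
})

test_that("ensembles are reproducible and node-order invariant in distribution", {
  m <- load_model("A = 1\nB = A\nC = A & !B\n")
  sc <- scenario(horizon = 30, replicates = 3000, seed = 12, steady_window = 10)
  e1 <- simulate_ensemble(m, sc)
  e2 <- simulate_ensemble(m, sc)
  expect_identical(e1$activity, e2$activity)  # byte-identical repeat
  # permuting node declaration order leaves statistics unchanged at 3*SE
  m_perm <- load_model("C = A & !B\nA = 1\nB = A\n")
  e3 <- simulate_ensemble(m_perm, sc)
  for (nd in c("A", "B", "C")) {
    p1 <- steady_state_summary(e1)[[nd]]
    p3 <- steady_state_summary(e3)[[nd]]
    se <- sqrt(2 * max(p1 * (1 - p1), 1e-4) / 3000)
    expect_lt(abs(p1 - p3), 3 * se)
  }
})

test_that("steady_state_summary averages the last W iterations and validates W", {
  m <- const_true_model(p_a = 1, p_d = 0)  # activity 0 then all 1
  e <- simulate_ensemble(m, scenario(horizon = 5, replicates = 100, seed = 1,
                                     steady_window = 3))
  expect_equal(unname(steady_state_summary(e, 3)[["A"]]), 1)
  expect_equal(unname(steady_state_summary(e, 5)[["A"]]), 1)
  expect_error(steady_state_summary(e, 0), "window")
  expect_error(steady_state_summary(e, 6), "horizon")
})

test_that("replicate window means are consistent with the aggregate summary", {
  m <- generate_random_model(4, seed = 19)
  sc <- scenario(horizon = 40, replicates = 2000, seed = 6, steady_window = 10)
  e <- simulate_ensemble(m, sc)
  expect_equal(dim(e$replicate_steady), c(2000L, 4L))
  # the mean of per-replicate window means is exactly the windowed summary
  expect_equal(colMeans(e$replicate_steady), steady_state_summary(e))
  # the empirical SE never exceeds the single-iteration binomial bound
  p <- steady_state_summary(e)
  binom <- sqrt(p * (1 - p) / sc$replicates)
  expect_true(all(steady_state_se(e) <= binom + 1e-4))
})

test_that("activities stay in [0,1] and the synchronous variant is available", {
  m <- generate_random_model(5, seed = 8)
  e <- simulate_ensemble(m, scenario(horizon = 20, replicates = 500, seed = 2))
  expect_true(all(e$activity >= 0 & e$activity <= 1))
  es <- simulate_ensemble(m, scenario(horizon = 20, replicates = 500, seed = 2),
                          update = "synchronous")
  expect_true(all(es$activity >= 0 & es$activity <= 1))
  # synchronous const-true node follows the same activation recursion
  ec <- simulate_ensemble(const_true_model(), scenario(horizon = 5,
                          replicates = 10000, seed = 4), update = "synchronous")
  expect_lt(abs(ec$activity[2, "A"] - 0.5), 3 * sqrt(0.25 / 10000))
})
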