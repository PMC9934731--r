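# Small fixture models and an independent rule evaluator, built in code.

# single node whose rule is constantly TRUE
const_true_model <- function(p_a = 0.5, p_d = 0.05) {
  logic_model(list(node_spec("A", "1", p_a = p_a, p_d = p_d)), name = "const1")
}

# self-inhibiting toggle: A = !A (birth-death chain between 0 and 1)
toggle_model <- function(p_a = 0.5, p_d = 0.05) {
  logic_model(list(node_spec("A", "!A", p_a = p_a, p_d = p_d)), name = "toggle")
}

# two-node chain: A constantly TRUE, B copies A; deterministic propensities
chain_model <- function() {
  logic_model(list(node_spec("A", "1", p_a = 1, p_d = 0),
                   node_spec("B", "A", p_a = 1, p_d = 0)),
              name = "chain")
}

# independent evaluator: R's own parser and logical operators share the
# grammar (!, &, |, same precedence), so parse(text=) is an external oracle
r_eval_rule <- function(text, state) {
  env <- list2env(stats::setNames(as.list(as.logical(state)), names(state)))
  as.integer(eval(parse(text = text), envir = env))
}

# all 0/1 assignments over a variable set, as a data.frame
all_assignments <- function(vars) {
  g <- do.call(expand.grid, stats::setNames(rep(list(0:1), length(vars)), vars))
  as.data.frame(g)
}

# truth table of an expression (or rule text) over given variables
truth_table <- function(expr, vars) {
  if (is.character(expr)) expr <- parse_expression(expr)
  grid <- all_assignments(vars)
  apply(grid, 1L, function(row) eval_expression(expr, row))
}

# random expression text over a variable pool (independent of the package's
# generator internals), reproducible under the caller's set.seed
random_rule_text <- function(vars, depth) {
  if (depth <= 0 || runif(1) < 0.3) {
    if (runif(1) < 0.1) return(sample(c("0", "1"), 1))
    return(sample(vars, 1))
  }
  op <- sample(c("!", "&", "|"), 1)
  if (op == "!") return(paste0("!(", random_rule_text(vars, depth - 1), ")"))
  k <- sample(2:3, 1)
  parts <- vapply(seq_len(k), function(i)
    paste0("(", random_rule_text(vars, depth - 1), ")"), character(1))
  paste(parts, collapse = paste0(" ", op, " "))
}
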