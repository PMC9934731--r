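## Random model generation, used by the property tests that compare the
## Monte-Carlo engine against the exact Markov kernel.

.random_expr <- function(vars, depth) {
  if (depth <= 0L || stats::runif(1) < 0.25) {
    if (stats::runif(1) < 0.15) return(bool_const(sample(0:1, 1L)))
    return(bool_var(sample(vars, 1L)))
  }
  op <- sample(c("not", "and", "or"), 1L)
  if (op == "not") return(bool_not(.random_expr(vars, depth - 1L)))
  k <- sample(2:3, 1L)
  kids <- lapply(seq_len(k), function(i) .random_expr(vars, depth - 1L))
  .flatten_nary(op, kids)
}

#' Generate a random logic model
#'
#' Produces a syntactically valid model whose rules reference only defined
#' nodes, reproducible from the seed. Used for property tests (e.g. checking
#' the simulator against the exact transition kernel on small models).
#'
#' @param n node count (>= 1).
#' @param max_depth maximum rule depth (>= 1).
#' @param p_a_range,p_d_range ranges the propensities are drawn from.
#' @param seed integer seed.
#' @return a validated [logic_model()].
#' @export
generate_random_model <- function(n, max_depth = 3L,
                                  p_a_range = c(0.2, 1), p_d_range = c(0, 0.3),
                                  seed = 1) {
  stopifnot(n >= 1L, max_depth >= 1L,
            all(p_a_range >= 0 & p_a_range <= 1),
            all(p_d_range >= 0 & p_d_range <= 1))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nms <- paste0("N", seq_len(n))
  nodes <- lapply(nms, function(nm) {
    node_spec(nm, .random_expr(nms, sample.int(max_depth, 1L)),
              p_a = stats::runif(1, p_a_range[1], p_a_range[2]),
              p_d = stats::runif(1, p_d_range[1], p_d_range[2]))
  })
  logic_model(nodes, name = sprintf("random_n%d_seed%d", n, seed))
}
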