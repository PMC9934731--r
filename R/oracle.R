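## Exact Markov-chain kernel of the random-order asynchronous update process,
## for small models. The process over one iteration is: draw a permutation
## sigma uniformly from the n! orderings, then apply the single-node
## stochastic update kernels in that order. The iteration kernel is therefore
## the permutation average (1/n!) * sum_sigma  M_{sigma(1)} ... M_{sigma(n)}.
## States are indexed in binary order with the first declared node as the most
## significant bit, matching the simulator's joint-state recording.

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

.state_bits <- function(s, n) {
  # s in 0..2^n-1 -> bit vector, first node most significant
  as.integer(bitwAnd(bitwShiftR(s, (n - 1L):0L), 1L))
}

.state_labels <- function(nms) {
  n <- length(nms)
  vapply(0:(2^n - 1L), function(s) paste(.state_bits(s, n), collapse = ""),
         character(1))
}

## single-site kernel for node i (1-based): 2^n x 2^n
.site_kernel <- function(model, i) {
  nms <- node_names(model)
  n <- length(nms)
  spec <- model$nodes[[i]]
  N <- 2L^n
  M <- matrix(0, N, N)
  bitval <- 2L^(n - i)  # contribution of node i's bit to the state index
  for (s in 0:(N - 1L)) {
    bits <- .state_bits(s, n)
    st <- stats::setNames(bits, nms)
    f <- eval_expression(spec$rule, st)
    x <- bits[i]
    if (f == x) {
      M[s + 1L, s + 1L] <- 1
    } else if (f == 1L) {
      M[s + 1L, s + bitval + 1L] <- spec$p_a
      M[s + 1L, s + 1L] <- 1 - spec$p_a
    } else {
      M[s + 1L, s - bitval + 1L] <- spec$p_d
      M[s + 1L, s + 1L] <- 1 - spec$p_d
    }
  }
  M
}

#' Exact one-iteration transition kernel (small models)
#'
#' Builds the exact `2^n x 2^n` row-stochastic transition matrix of one
#' random-order asynchronous iteration by averaging, over all `n!` node
#' orderings, the ordered product of single-node update kernels. Serves as an
#' independent oracle for the Monte-Carlo simulator. Cost grows as
#' `n! * 2^n`, so models with more than `max_nodes` (default 6) nodes are
#' refused.
#'
#' @param model a validated [logic_model()] with at most `max_nodes` nodes;
#'   input rules should already be concrete (see [apply_scenario()]).
#' @param max_nodes refusal threshold.
#' @return object of class `transition_matrix`: `kernel` (row-stochastic
#'   matrix with binary state labels, first declared node most significant)
#'   and `nodes`.
#' @export
exact_transition_matrix <- function(model, max_nodes = 6L) {
  stopifnot(inherits(model, "logic_model"))
  n <- length(model$nodes)
  if (n > max_nodes) {
    stop(sprintf(paste0("exact kernel limited to %d nodes (cost ~ n! * 2^n); ",
                        "model has %d"), max_nodes, n), call. = FALSE)
  }
  sites <- lapply(seq_len(n), function(i) .site_kernel(model, i))
  perms <- .permutations(n)
  N <- 2L^n
  K <- matrix(0, N, N)
  for (r in seq_len(nrow(perms))) {
    P <- sites[[perms[r, 1L]]]
    for (j in seq_len(n)[-1L]) P <- P %*% sites[[perms[r, j]]]
    K <- K + P
  }
  K <- K / nrow(perms)
  labs <- .state_labels(node_names(model))
  dimnames(K) <- list(from = labs, to = labs)
  structure(list(kernel = K, nodes = node_names(model)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d nodes, %d states\n",
              length(x$nodes), nrow(x$kernel)))
  invisible(x)
}

#' Exact initial state distribution of a scenario
#'
#' The product distribution implied by the initial-state rules: all nodes 0,
#' `LCK` 1 (when present and unperturbed), forced initial values, active
#' inputs an independent fair coin.
#'
#' @inheritParams simulate_ensemble
#' @return numeric vector of length `2^n` over states in binary order.
#' @export
exact_initial_distribution <- function(model, scen) {
  init <- .initial_spec(model, scen)
  n <- length(init)
  p_on <- ifelse(init == -1L, 0.5, as.numeric(init))
  N <- 2L^n
  d <- numeric(N)
  for (s in 0:(N - 1L)) {
    bits <- .state_bits(s, n)
    d[s + 1L] <- prod(ifelse(bits == 1L, p_on, 1 - p_on))
  }
  names(d) <- .state_labels(names(init))
  d
}

#' Propagate a distribution through the exact kernel
#'
#' @param tm a [transition_matrix][exact_transition_matrix].
#' @param d0 initial distribution over states.
#' @param t number of iterations.
#' @return the distribution after `t` iterations.
#' @export
exact_distribution_at <- function(tm, d0, t) {
  stopifnot(inherits(tm, "transition_matrix"), t >= 0)
  d <- matrix(d0, nrow = 1L)
  for (k in seq_len(t)) d <- d %*% tm$kernel
  stats::setNames(as.numeric(d), rownames(tm$kernel))
}

#' Per-node ON-marginals of a state distribution
#'
#' @param d distribution over `2^n` states (binary order).
#' @param nodes node names (first is the most significant bit).
#' @return named numeric vector of marginal ON-probabilities.
#' @export
marginal_on_probabilities <- function(d, nodes) {
  n <- length(nodes)
  stopifnot(length(d) == 2^n)
  out <- numeric(n)
  for (s in 0:(2L^n - 1L)) {
    bits <- .state_bits(s, n)
    out <- out + bits * d[s + 1L]
  }
  stats::setNames(out, nodes)
}

#' Stationary distribution of an exact kernel
#'
#' Left eigenvector of the kernel for eigenvalue 1, normalized to sum to 1.
#'
#' @param tm a [transition_matrix][exact_transition_matrix].
#' @return numeric stationary distribution over states.
#' @export
stationary_distribution <- function(tm) {
  stopifnot(inherits(tm, "transition_matrix"))
  e <- eigen(t(tm$kernel))
  k <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, k])
  v <- v / sum(v)
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), rownames(tm$kernel))
}

#' Total variation distance between two distributions
#'
#' @param p,q distributions over the same state space.
#' @return `0.5 * sum(|p - q|)`.
#' @export
total_variation <- function(p, q) {
  stopifnot(length(p) == length(q))
  0.5 * sum(abs(p - q))
}
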