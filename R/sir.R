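## Discrete-time SIR spreading simulator.
##
## Synchronous rounds, infect-then-recover: every currently infected node
## first gets a chance to infect each susceptible neighbor (probability alpha
## per S-I contact), then recovers with probability beta.  An infected node
## therefore transmits for at least one round even at beta = 1, which is the
## regime the capacity experiments run in.  Draw order within a round is
## fixed (infection trials over susceptible nodes in ascending index order,
## then recovery trials over infected nodes in ascending index order), so a
## given seed yields a bit-identical trajectory.

validate_sir <- function(alpha, beta, iterations = 1L) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) stop_usage("`alpha` must lie in [0, 1]")
  if (!is.numeric(beta) || beta <= 0 || beta > 1) stop_usage("`beta` must lie in (0, 1]")
  if (!is.numeric(iterations) || iterations < 1) stop_usage("`iterations` must be >= 1")
  invisible(TRUE)
}

## Integer-index adjacency list in canonical (sorted-name) node order.
sir_adjacency <- function(g) {
  nodes <- node_names(g)
  idx <- match(igraph::V(g)$name, nodes)
  adj <- igraph::as_adj_list(g)
  out <- vector("list", length(nodes))
  for (v in seq_along(adj)) out[[idx[v]]] <- sort(idx[as.integer(adj[[v]])])
  list(nodes = nodes, adj = out)
}

sir_step_core <- function(adj, state, alpha, beta) {
  n <- length(state)
  inf <- which(state == 1L)
  contacts <- unlist(adj[inf], use.names = FALSE)
  counts <- tabulate(contacts, nbins = n)
  sus <- which(state == 0L & counts > 0L)
  newly <- sus[runif(length(sus)) < 1 - (1 - alpha)^counts[sus]]
  recovered <- inf[runif(length(inf)) < beta]
  state[newly] <- 1L
  state[recovered] <- 2L
  state
}

#' Run one SIR trajectory
#'
#' @param g An igraph graph with character vertex names.
#' @param seeds Character vector of initially infected nodes (non-empty).
#' @param alpha Per-contact infection probability in \[0, 1\].
#' @param beta Per-round recovery probability in (0, 1\]; default 1.
#' @param max_rounds Round cap; `0` (default) runs to extinction.
#' @param rng_seed Optional integer seed; identical seeds give bit-identical
#'   trajectories.
#' @return A tibble of class `sir_trajectory` with one row per round
#'   (including round 0): `round`, `n_s`, `n_i`, `n_r`, `cum_infected`
#'   (= `n_i + n_r`, the ever-infected count).  The final outbreak size is
#'   the last `cum_infected`.
#' @examples
#' g <- random_graph("er", n = 20, p = 0.2, seed = 1)
#' sir_run(g, seeds = "1", alpha = 0.3, rng_seed = 7)
#' @export
sir_run <- function(g, seeds, alpha, beta = 1, max_rounds = 0, rng_seed = NULL) {
  assert_graph(g)
  validate_sir(alpha, beta)
  if (length(seeds) == 0L) stop_domain("seed set must be non-empty")
  missing <- setdiff(seeds, igraph::V(g)$name)
  if (length(missing) > 0L) {
    stop_domain(sprintf("unknown seed node(s): %s", paste(missing, collapse = ", ")))
  }
  net <- sir_adjacency(g)
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))

  n <- length(net$nodes)
  state <- integer(n)
  state[match(unique(seeds), net$nodes)] <- 1L

  rows <- list(c(0L, sum(state == 0L), sum(state == 1L), sum(state == 2L)))
  round <- 0L
  while (any(state == 1L) && (max_rounds == 0 || round < max_rounds)) {
    state <- sir_step_core(net$adj, state, alpha, beta)
    round <- round + 1L
    rows[[round + 1L]] <- c(round, sum(state == 0L), sum(state == 1L), sum(state == 2L))
  }
  m <- do.call(rbind, rows)
  out <- tibble(
    round = m[, 1L], n_s = m[, 2L], n_i = m[, 3L], n_r = m[, 4L],
    cum_infected = m[, 3L] + m[, 4L]
  )
  structure(out, class = c("sir_trajectory", class(tibble())),
            alpha = alpha, beta = beta, n_nodes = n)
}

#' Per-node spreading capacity under the SIR oracle
#'
#' For each node, the mean final outbreak size (`|I| + |R|` at termination)
#' over Monte-Carlo replicates with that node as the sole seed — the
#' ground-truth influence measure the centrality rankings are judged
#' against.  Replicate `k` uses RNG seed `rng_seed + k` for every node, so
#' node comparisons are paired at matched seeds and growing `iterations`
#' never perturbs earlier replicates.
#'
#' @inheritParams sir_run
#' @param iterations Monte-Carlo replicates per node (default 1000).
#' @param rng_seed Integer base seed (default 1).
#' @return A tibble of class `sir_capacity`: `node`, `capacity` (mean final
#'   size), `stderr`.
#' @export
spreading_capacity <- function(g, alpha, beta = 1, iterations = 1000,
                               max_rounds = 0, rng_seed = 1) {
  assert_graph(g)
  validate_sir(alpha, beta, iterations)
  net <- sir_adjacency(g)
  n <- length(net$nodes)
  sizes <- matrix(0, nrow = iterations, ncol = n)
  for (k in seq_len(iterations)) {
    for (v in seq_len(n)) {
      set.seed(as.integer(rng_seed) + k)
      state <- integer(n)
      state[v] <- 1L
      round <- 0L
      while (any(state == 1L) && (max_rounds == 0 || round < max_rounds)) {
        state <- sir_step_core(net$adj, state, alpha, beta)
        round <- round + 1L
      }
      sizes[k, v] <- sum(state != 0L)
    }
  }
  out <- tibble(
    node = net$nodes,
    capacity = colMeans(sizes),
    stderr = apply(sizes, 2L, sd) / sqrt(iterations)
  )
  structure(out, class = c("sir_capacity", class(tibble())),
            alpha = alpha, beta = beta, iterations = iterations,
            replicate_sizes = sizes)
}

#' Mean cumulative-infection curve for a seed set
#'
#' `F(t)`: the mean, over Monte-Carlo replicates, of the ever-infected count
#' after `t` rounds when the whole `seed_set` starts infected — the curve
#' used to compare the spreading power of each method's top-N nodes.  After
#' extinction the count stays at its final value, so `F(t)` is
#' non-decreasing with `F(0) = |seed_set|`.
#'
#' @inheritParams sir_run
#' @param seed_set Character vector of seed nodes.
#' @param rounds Number of rounds to track (default 30).
#' @param iterations Monte-Carlo replicates (default 1000).
#' @param rng_seed Integer base seed (default 1); replicate `k` uses
#'   `rng_seed + k`.
#' @return A tibble of class `sir_curve`: `t` (0..rounds), `f_mean`,
#'   `f_stderr`.
#' @export
infection_curve <- function(g, seed_set, alpha, beta = 1, rounds = 30,
                            iterations = 1000, rng_seed = 1) {
  assert_graph(g)
  validate_sir(alpha, beta, iterations)
  if (length(seed_set) == 0L) stop_domain("seed set must be non-empty")
  traj <- matrix(0, nrow = iterations, ncol = rounds + 1L)
  for (k in seq_len(iterations)) {
    run <- sir_run(g, seeds = seed_set, alpha = alpha, beta = beta,
                   max_rounds = rounds, rng_seed = as.integer(rng_seed) + k)
    cum <- run$cum_infected
    traj[k, ] <- c(cum, rep(cum[length(cum)], rounds + 1L - length(cum)))
  }
  out <- tibble(
    t = 0:rounds,
    f_mean = colMeans(traj),
    f_stderr = apply(traj, 2L, sd) / sqrt(iterations)
  )
  structure(out, class = c("sir_curve", class(tibble())),
            alpha = alpha, beta = beta, iterations = iterations,
            seeds = sort_nodes(unique(seed_set)))
}
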