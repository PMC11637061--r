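#' Degree centrality
#'
#' `DC(i) = d(i) / (N - 1)`: the fraction of other nodes a node touches
#' directly.
#'
#' @param g An igraph graph with character vertex names (N >= 2).
#' @return A tibble with columns `node`, `method`, `score`, sorted by node.
#' @export
degree_centrality <- function(g) {
  assert_graph(g)
  n <- igraph::vcount(g)
  if (n < 2L) stop_domain("degree centrality needs at least 2 nodes")
  nodes <- node_names(g)
  d <- igraph::degree(g)[nodes]
  tibble(node = nodes, method = "degree", score = as.numeric(d) / (n - 1))
}

#' K-shell (k-core) decomposition
#'
#' Iteratively strips nodes of degree at most k, for k = 1, 2, ..., assigning
#' each node the index of the deepest core it survives into.  Isolated nodes
#' get shell 0.  Backed by the standard coreness computation.
#'
#' @param g An igraph graph with character vertex names.
#' @return A tibble with columns `node`, `method`, `score`, `shell`
#'   (`score` is the shell as a double, for a uniform interface).
#' @export
k_shell <- function(g) {
  assert_graph(g)
  nodes <- node_names(g)
  ks <- if (length(nodes) == 0L) integer(0) else igraph::coreness(g)[nodes]
  tibble(
    node = nodes, method = "kshell",
    score = as.numeric(ks), shell = as.integer(ks)
  )
}

## K-shell values as a named integer vector (internal fast path).
kshell_values <- function(g) {
  nodes <- node_names(g)
  if (length(nodes) == 0L) return(setNames(integer(0), character(0)))
  ks <- igraph::coreness(g)[nodes]
  setNames(as.integer(ks), nodes)
}

#' Eigenvector centrality by deterministic power iteration
#'
#' Power iteration on the shifted adjacency operator `A + I` with a uniform
#' start vector, normalized to unit Euclidean length each step.  The shift
#' leaves the principal eigenvector unchanged on a connected graph while
#' making the dominant eigenvalue strictly largest in modulus, so iteration
#' converges even on bipartite graphs.  Deterministic: the same graph always
#' yields the same scores.
#'
#' @param g An igraph graph with at least one edge.
#' @param tol Convergence tolerance on the max absolute score change
#'   (default `1e-8`).
#' @param max_iter Iteration cap (default `10000`).
#' @return A tibble with columns `node`, `method`, `score`; scores have unit
#'   Euclidean norm.
#' @export
eigenvector_centrality <- function(g, tol = 1e-8, max_iter = 10000L) {
  assert_graph(g)
  if (igraph::ecount(g) < 1L) stop_domain("eigenvector centrality needs at least one edge")
  nodes <- node_names(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)[nodes, nodes, drop = FALSE]
  n <- length(nodes)
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + x
    y <- y / sqrt(sum(y^2))
    delta <- max(abs(y - x))
    x <- y
    if (delta < tol) {
      return(tibble(node = nodes, method = "eigenvector", score = x))
    }
  }
  stop_convergence(sprintf(
    "eigenvector centrality did not converge in %d iterations (residual %.3g)",
    max_iter, delta
  ))
}

#' PageRank centrality
#'
#' Standard PageRank with uniform teleport on the undirected graph (every
#' edge usable in both directions); scores sum to 1 and isolated nodes
#' receive teleport-only mass.  Backed by igraph's PRPACK solver, which
#' solves the stationary equations directly, so no iteration parameters are
#' needed and results are deterministic.
#'
#' @param g An igraph graph with character vertex names.
#' @param damping Damping factor in (0, 1); default `0.85`.
#' @return A tibble with columns `node`, `method`, `score` summing to 1.
#' @export
pagerank_centrality <- function(g, damping = 0.85) {
  assert_graph(g)
  if (!is.numeric(damping) || damping <= 0 || damping >= 1) {
    stop_usage("`damping` must lie strictly between 0 and 1")
  }
  nodes <- node_names(g)
  pr <- igraph::page_rank(g, damping = damping)$vector[nodes]
  tibble(node = nodes, method = "pagerank", score = as.numeric(pr))
}

#' Compute a centrality ranking by name
#'
#' Dispatches to [kln_rank()], [degree_centrality()], [k_shell()],
#' [eigenvector_centrality()] or [pagerank_centrality()] and returns a
#' uniform ranking tibble (ties broken by ascending node identifier).
#'
#' @param g An igraph graph with character vertex names.
#' @param method One of `"kln"`, `"degree"`, `"kshell"`, `"eigenvector"`,
#'   `"pagerank"`.
#' @param ... Passed to the underlying method.
#' @return A tibble with columns `node`, `method`, `score`, `rank`.
#' @export
rank_nodes <- function(g, method = c("kln", "degree", "kshell", "eigenvector", "pagerank"), ...) {
  method <- tryCatch(match.arg(method), error = function(e) stop_usage(conditionMessage(e)))
  scores <- switch(method,
    kln = {
      r <- kln_rank(g, ...)
      tibble(node = r$node, method = "kln", score = r$kln)
    },
    degree = degree_centrality(g),
    kshell = k_shell(g)[c("node", "method", "score")],
    eigenvector = eigenvector_centrality(g, ...),
    pagerank = pagerank_centrality(g, ...)
  )
  scores <- scores[order(-scores$score, scores$node, method = "radix"), ]
  scores$rank <- seq_len(nrow(scores))
  as_tibble(scores)
}
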