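#' Path change factor
#'
#' After removing a center node, the dissemination weight between two of its
#' former neighbors is the reciprocal of their remaining shortest distance.
#' Disconnected pairs get 1/2 — before the removal they communicated through
#' the center in two hops.  The self term uses factor 1 (distance-1
#' convention for a node "reaching" itself in its own fitting row).
#'
#' @param l Numeric vector of hop counts; `Inf` marks an unreachable pair and
#'   `NA` marks the self term.
#' @return Numeric vector in (0, 1]: `1/l` for finite `l`, `0.5` for `Inf`,
#'   `1` for `NA`.
#' @examples
#' path_change_factor(c(4, Inf, NA)) # 0.25 0.50 1.00
#' @export
path_change_factor <- function(l) {
  if (!is.numeric(l)) stop_usage("`l` must be numeric")
  bad <- !is.na(l) & !is.infinite(l) & l <= 0
  if (any(bad)) stop_domain("hop counts must be positive")
  out <- 1 / l
  out[is.infinite(l)] <- 0.5
  out[is.na(l)] <- 1
  out
}

#' Real information-dissemination distribution of a node
#'
#' The probability that information flowing through node `i` reaches each of
#' its neighbors, taken proportional to the neighbors' degrees in the intact
#' graph: `p_i(j) = d(j) / sum_{j in Gamma(i)} d(j)`.
#'
#' @param g An igraph graph with character vertex names.
#' @param i Node identifier with degree >= 1.
#' @return Named numeric probability vector over `i`'s neighbors in
#'   ascending identifier order; sums to 1.
#' @export
real_distribution <- function(g, i) {
  assert_graph(g)
  assert_node(g, i)
  nbrs <- sort_nodes(igraph::neighbors(g, i)$name)
  if (length(nbrs) == 0L) stop_domain(sprintf("node '%s' is isolated: no real distribution", i))
  d <- as.numeric(igraph::degree(g)[nbrs])
  setNames(d / sum(d), nbrs)
}

#' Neighborhood profile after removing a node
#'
#' Gathers everything the KLN fitting distribution needs about the
#' neighborhood of `i` once `i` is (non-destructively) removed: the
#' neighbors in ascending identifier order, their intact and post-removal
#' degrees, their K-shell values from the intact graph, and the matrix of
#' pairwise shortest distances in the remaining graph (`Inf` = disconnected,
#' diagonal `NA` = self term).
#'
#' @inheritParams real_distribution
#' @param cutoff Optional hop limit; post-removal distances beyond it are
#'   treated as unreachable (approximation flag, default off).
#' @return A `kln_profile` object.
#' @export
post_removal_profile <- function(g, i, cutoff = NULL) {
  assert_graph(g)
  assert_node(g, i)
  nbrs <- sort_nodes(igraph::neighbors(g, i)$name)
  if (length(nbrs) == 0L) stop_domain(sprintf("node '%s' is isolated: empty neighborhood", i))
  gm <- igraph::delete_vertices(g, i)
  D <- igraph::distances(gm, v = nbrs, to = nbrs, algorithm = "unweighted")
  D <- D[nbrs, nbrs, drop = FALSE]
  if (!is.null(cutoff)) {
    if (!is.numeric(cutoff) || cutoff <= 0) stop_usage("`cutoff` must be a positive number")
    D[D > cutoff] <- Inf
  }
  diag(D) <- NA_real_
  new_profile(
    center = i,
    neighbors = nbrs,
    pre_degree = setNames(as.numeric(igraph::degree(g)[nbrs]), nbrs),
    post_degree = setNames(as.numeric(igraph::degree(gm)[nbrs]), nbrs),
    kshell = kshell_values(g)[nbrs],
    post_distance = D
  )
}

new_profile <- function(center, neighbors, pre_degree, post_degree, kshell, post_distance) {
  structure(
    list(
      center = center, neighbors = neighbors,
      pre_degree = pre_degree, post_degree = post_degree,
      kshell = kshell, post_distance = post_distance
    ),
    class = "kln_profile"
  )
}

#' @export
print.kln_profile <- function(x, ...) {
  cat(sprintf(
    "<kln_profile> center '%s', %d neighbor(s): %s\n",
    x$center, length(x$neighbors), paste(x$neighbors, collapse = ", ")
  ))
  invisible(x)
}

#' Real distribution read off a neighborhood profile
#'
#' Same quantity as [real_distribution()] but computed from a
#' [post_removal_profile()] or [neighborhood_from_spec()] object, so printed
#' neighborhood tables can drive the scoring pipeline without a graph.
#'
#' @param profile A `kln_profile`.
#' @return Named probability vector over the profile's neighbors.
#' @export
profile_real_distribution <- function(profile) {
  stopifnot(inherits(profile, "kln_profile"))
  p <- profile$pre_degree
  setNames(as.numeric(p) / sum(p), profile$neighbors)
}

#' Fitting information-dissemination distribution after node removal
#'
#' One row per neighbor `n` of the removed center: the probability that
#' information at `n` reaches each neighbor `j` (including `n` itself) in the
#' remaining graph,
#' `chi_in(j) = sqrt(lambda(n, j)) * d'(j) / sum_j sqrt(lambda(n, j)) * d'(j)`,
#' where `lambda` is the [path_change_factor()] and `d'(j)` the post-removal
#' degree.  A post-removal degree of 0 (the neighbor was a leaf hanging off
#' the center) would zero a whole column and blow the divergence up to
#' infinity; it is replaced by `floor` before normalization, keeping rows
#' valid distributions while preserving the "maximal damage" reading as a
#' large, finite loss.
#'
#' @param profile A `kln_profile`.
#' @param floor Small positive stand-in for zero post-removal degrees
#'   (default `1e-10`).
#' @return Row-stochastic numeric matrix with neighbor identifiers as both
#'   dimnames; rows sum to 1.
#' @export
fitting_distribution <- function(profile, floor = 1e-10) {
  stopifnot(inherits(profile, "kln_profile"))
  if (floor < 0) stop_usage("`floor` must be non-negative")
  d <- profile$post_degree
  d[d == 0] <- floor
  lam <- path_change_factor(profile$post_distance)
  dim(lam) <- dim(profile$post_distance)
  W <- sweep(sqrt(lam), 2L, d, `*`)
  rs <- rowSums(W)
  if (any(rs == 0)) {
    stop_domain("degenerate fitting row: all weights zero (set a positive `floor`)")
  }
  Q <- W / rs
  dimnames(Q) <- list(profile$neighbors, profile$neighbors)
  Q
}

#' Kullback-Leibler divergence of a fitted row from the real distribution
#'
#' `D(P || q) = sum_x P(x) * log(P(x) / q(x))`, logarithm taken in
#' `log_base`; terms with `P(x) = 0` contribute 0 and `q` entries are clamped
#' to at least `floor`.  The default base is 10, the convention under which
#' the per-neighbor divergences of the packaged worked example recompute to
#' their documented values.
#'
#' @param p Real probability vector.
#' @param q_row Fitted probability vector of the same length (one row of
#'   [fitting_distribution()]).
#' @param log_base Logarithm base, > 1 (default 10).
#' @param floor Lower clamp for `q_row` entries (default `1e-10`).
#' @return Non-negative scalar divergence.
#' @export
kl_divergence <- function(p, q_row, log_base = 10, floor = 1e-10) {
  if (length(p) != length(q_row)) {
    stop_domain(sprintf("distribution lengths differ: %d vs %d", length(p), length(q_row)))
  }
  if (!is.numeric(log_base) || log_base <= 1) stop_usage("`log_base` must exceed 1")
  q <- pmax(as.numeric(q_row), floor)
  pp <- as.numeric(p)
  nz <- pp > 0
  sum(pp[nz] * log(pp[nz] / q[nz])) / log(log_base)
}

#' K-shell-weighted neighborhood divergence of a node
#'
#' Sums, over the neighbors `j` of `i`, the intact-graph K-shell of `j` times
#' the KL divergence between the real distribution of `i` and the fitted row
#' of `j` after `i` is removed.  K-shell values always come from the intact
#' graph, computed once — removal never triggers a re-decomposition.
#'
#' @inheritParams real_distribution
#' @param log_base,floor,cutoff See [kl_divergence()],
#'   [fitting_distribution()] and [post_removal_profile()].
#' @return Non-negative scalar `D_i`.
#' @export
node_divergence <- function(g, i, log_base = 10, floor = 1e-10, cutoff = NULL) {
  profile <- post_removal_profile(g, i, cutoff = cutoff)
  divergence_from_profile(profile, log_base = log_base, floor = floor)
}

divergence_from_profile <- function(profile, log_base = 10, floor = 1e-10) {
  p <- profile_real_distribution(profile)
  Q <- fitting_distribution(profile, floor = floor)
  kl <- vapply(
    profile$neighbors,
    function(n) kl_divergence(p, Q[n, ], log_base = log_base, floor = floor),
    0
  )
  sum(as.numeric(profile$kshell) * kl)
}

#' Damage influence of a node
#'
#' `DE(i) = D_i + d(i)`: the K-shell-weighted neighborhood divergence plus
#' the node's own degree.  Isolated nodes inflict no damage: `DE = 0`.
#'
#' @inheritParams node_divergence
#' @return Non-negative scalar; at least `d(i)` for non-isolated nodes.
#' @export
damage_influence <- function(g, i, log_base = 10, floor = 1e-10, cutoff = NULL) {
  assert_graph(g)
  assert_node(g, i)
  d <- as.numeric(igraph::degree(g, i))
  if (d == 0) return(0)
  node_divergence(g, i, log_base = log_base, floor = floor, cutoff = cutoff) + d
}

#' KLN importance score of a node
#'
#' `KLN(i) = DE(i) + sqrt(sum_{j in Gamma(i)} DE(j))`: the node's own damage
#' influence plus the square-rooted damage influence of its one-hop
#' neighborhood.  Isolated nodes score 0.
#'
#' @inheritParams node_divergence
#' @return Non-negative scalar; at least `DE(i)`.
#' @export
kln_score <- function(g, i, log_base = 10, floor = 1e-10, cutoff = NULL) {
  assert_graph(g)
  assert_node(g, i)
  if (igraph::degree(g, i) == 0) return(0)
  nbrs <- igraph::neighbors(g, i)$name
  de_i <- damage_influence(g, i, log_base = log_base, floor = floor, cutoff = cutoff)
  de_nb <- vapply(
    nbrs, function(j) damage_influence(g, j, log_base = log_base, floor = floor, cutoff = cutoff),
    0
  )
  de_i + sqrt(sum(de_nb))
}

#' KLN ranking of every node
#'
#' Runs the full pipeline once per node — real distribution, post-removal
#' fitting distribution, per-neighbor KL divergences, K-shell weighting,
#' damage influence — then aggregates each node's one-hop damage influences
#' into the final KLN score.  Damage influences are computed once and reused
#' across all neighborhood sums.  The ranking is sorted by KLN descending
#' with ties broken by ascending node identifier, so it is deterministic.
#'
#' @inheritParams node_divergence
#' @return A tibble of class `kln_ranking` with columns `node`, `degree`,
#'   `kshell`, `divergence` (`D_i`), `de` (`DE(i)`), `kln`, `rank`.
#' @examples
#' g <- worked_example_graph()
#' kln_rank(g)
#' @export
kln_rank <- function(g, log_base = 10, floor = 1e-10, cutoff = NULL) {
  assert_graph(g)
  nodes <- node_names(g)
  deg <- setNames(as.numeric(igraph::degree(g)[nodes]), nodes)
  ks <- kshell_values(g)

  div <- setNames(numeric(length(nodes)), nodes)
  for (i in nodes[deg > 0]) {
    profile <- post_removal_profile(g, i, cutoff = cutoff)
    div[i] <- divergence_from_profile(profile, log_base = log_base, floor = floor)
  }
  de <- ifelse(deg == 0, 0, div + deg)

  kln <- setNames(numeric(length(nodes)), nodes)
  adj <- igraph::as_adj_list(g)
  names(adj) <- igraph::V(g)$name
  for (i in nodes[deg > 0]) {
    nbrs <- adj[[i]]$name
    kln[i] <- de[i] + sqrt(sum(de[nbrs]))
  }

  out <- tibble(
    node = nodes,
    degree = as.integer(deg),
    kshell = as.integer(ks[nodes]),
    divergence = as.numeric(div),
    de = as.numeric(de),
    kln = as.numeric(kln)
  )
  out <- out[order(-out$kln, out$node, method = "radix"), ]
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("kln_ranking", class(tibble())))
}
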