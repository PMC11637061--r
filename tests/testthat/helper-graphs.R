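# Small graph builders used across tests.

g_from_edges <- function(...) {
  pairs <- list(...)
  f <- tempfile(fileext = ".txt")
  writeLines(vapply(pairs, function(e) paste(e, collapse = " "), ""), f)
  on.exit(unlink(f))
  read_edge_list(f)
}

g_triangle <- function() g_from_edges(c("a", "b"), c("b", "c"), c("c", "a"))

g_path <- function(nodes) {
  do.call(g_from_edges, Map(c, nodes[-length(nodes)], nodes[-1]))
}

g_star <- function(k) {
  do.call(g_from_edges, lapply(paste0("l", seq_len(k)), function(l) c("hub", l)))
}

g_complete <- function(n) {
  nodes <- paste0("v", seq_len(n))
  do.call(g_from_edges, utils::combn(nodes, 2, simplify = FALSE))
}

# Dense named adjacency matrix in canonical node order (for oracles).
adj_matrix <- function(g) {
  nodes <- sort(igraph::V(g)$name, method = "radix")
  igraph::as_adjacency_matrix(g, sparse = FALSE)[nodes, nodes, drop = FALSE]
}

# Write a graph out as a shuffled edge list file.
edge_list_file <- function(g, shuffle_seed = NULL) {
  el <- igraph::as_edgelist(g)
  lines <- paste(el[, 1], el[, 2])
  if (!is.null(shuffle_seed)) {
    flip <- withr::with_seed(shuffle_seed + 1, runif(nrow(el)) < 0.5)
    lines[flip] <- paste(el[flip, 2], el[flip, 1])
    lines <- withr::with_seed(shuffle_seed, sample(lines))
  }
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}
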