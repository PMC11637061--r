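#' Read an undirected network from a plain-text edge list
#'
#' One edge per line, two node identifiers separated by whitespace or a comma;
#' lines starting with `#` and blank lines are ignored.  Node identifiers are
#' kept as opaque strings and never coerced to numbers, so `"01"` and `"1"`
#' remain distinct nodes.  Self-loops and duplicate edges are dropped silently
#' but counted in the load report attached to the graph (see
#' [graph_load_report()]).
#'
#' @param path Path to the edge-list file.
#' @param delimiter Field delimiter.  `NULL` (default) auto-detects: comma if
#'   any data line contains one, otherwise any run of whitespace.
#' @return An undirected simple [igraph][igraph::igraph-package] graph with
#'   character vertex names, carrying graph attributes `nodes_read`,
#'   `edges_read`, `self_loops_dropped`, `duplicates_dropped`.
#' @examples
#' f <- tempfile()
#' writeLines(c("a b", "b c", "c a"), f)
#' g <- read_edge_list(f)
#' igraph::vcount(g) # 3
#' @export
read_edge_list <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop_io(sprintf("cannot read edge list '%s'", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  body <- trimws(lines[keep])

  if (length(body) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(finish_graph(g, 0L, 0L, 0L, 0L))
  }

  if (is.null(delimiter)) delimiter <- if (any(grepl(",", body, fixed = TRUE))) "," else "[[:space:]]+"
  toks <- strsplit(body, delimiter)
  short <- which(vapply(toks, length, 1L) < 2L)
  if (length(short) > 0L) {
    stop_parse(sprintf(
      "line %d of '%s' has fewer than two fields", line_no[short[1L]], path
    ))
  }
  from <- trimws(vapply(toks, `[`, "", 1L))
  to <- trimws(vapply(toks, `[`, "", 2L))

  edges_read <- length(from)
  is_loop <- from == to
  a <- pmin(from[!is_loop], to[!is_loop])
  b <- pmax(from[!is_loop], to[!is_loop])
  dup <- duplicated(paste(a, b, sep = "\r"))

  nodes <- sort_nodes(unique(c(from, to)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[!dup], to = b[!dup], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  finish_graph(g, length(nodes), edges_read, sum(is_loop), sum(dup))
}

finish_graph <- function(g, nodes_read, edges_read, loops, dups) {
  g <- igraph::set_graph_attr(g, "nodes_read", as.integer(nodes_read))
  g <- igraph::set_graph_attr(g, "edges_read", as.integer(edges_read))
  g <- igraph::set_graph_attr(g, "self_loops_dropped", as.integer(loops))
  g <- igraph::set_graph_attr(g, "duplicates_dropped", as.integer(dups))
  g
}

#' Load report of a graph read from disk
#'
#' @param g A graph returned by [read_edge_list()] or [read_gml()].
#' @return A one-row tibble: nodes read, edge lines read, self-loops dropped,
#'   duplicate edges collapsed.
#' @export
graph_load_report <- function(g) {
  assert_graph(g)
  ga <- igraph::graph_attr(g)
  tibble(
    nodes_read = ga$nodes_read %||% igraph::vcount(g),
    edges_read = ga$edges_read %||% igraph::ecount(g),
    self_loops_dropped = ga$self_loops_dropped %||% 0L,
    duplicates_dropped = ga$duplicates_dropped %||% 0L
  )
}

#' Read a network from a GML file
#'
#' Directed edges are symmetrized; self-loops and multi-edges are collapsed as
#' in [read_edge_list()].  Vertex names come from the GML `label` field when
#' present, otherwise from the numeric `id`.
#'
#' @inheritParams read_edge_list
#' @return An undirected simple igraph graph with character vertex names.
#' @export
read_gml <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read GML file '%s'", path))
  g <- tryCatch(
    igraph::read_graph(path, format = "gml"),
    error = function(e) stop_parse(sprintf("malformed GML in '%s': %s", path, conditionMessage(e)))
  )
  va <- igraph::vertex_attr_names(g)
  nm <- if ("label" %in% va) {
    as.character(igraph::V(g)$label)
  } else if ("id" %in% va) {
    as.character(igraph::V(g)$id)
  } else {
    as.character(seq_len(igraph::vcount(g)))
  }
  igraph::V(g)$name <- nm
  edges_read <- igraph::ecount(g)
  g <- igraph::as_undirected(g, mode = "collapse")
  loops <- sum(igraph::which_loop(g))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  finish_graph(
    g, igraph::vcount(g), edges_read, loops,
    max(edges_read - loops - igraph::ecount(g), 0L)
  )
}

#' Write a graph to GML
#'
#' @param g An igraph graph with character vertex names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gml <- function(g, path) {
  assert_graph(g)
  gg <- g
  # graph-level attributes (load reports, sampler parameters) are provenance,
  # not topology, and some are types GML cannot carry
  for (a in igraph::graph_attr_names(gg)) gg <- igraph::delete_graph_attr(gg, a)
  igraph::V(gg)$label <- igraph::V(gg)$name
  igraph::write_graph(gg, path, format = "gml")
  invisible(path)
}

#' Non-destructive node removal
#'
#' Returns a view of `g` with node `i` and all incident edges absent, leaving
#' `g` unchanged.  This is the node-failure scenario the KLN score is built
#' on.
#'
#' @param g An igraph graph with character vertex names.
#' @param i Node identifier (character scalar).
#' @return The graph minus `i`.
#' @export
remove_node_view <- function(g, i) {
  assert_graph(g)
  assert_node(g, i)
  igraph::delete_vertices(g, i)
}

#' Unweighted shortest-path distances from one source
#'
#' Exact BFS hop counts.  Unreachable targets are reported as `Inf`, the
#' package-wide "unreachable" sentinel (never an arbitrary large number).
#' With a `cutoff`, targets farther than `cutoff` hops are also reported as
#' `Inf`; this is the optional neighborhood-truncation approximation used by
#' [kln_rank()].
#'
#' @param g An igraph graph with character vertex names.
#' @param source Source node identifier.
#' @param targets Optional character vector of targets (default: all nodes).
#' @param cutoff Optional positive hop limit.
#' @return Named numeric vector of hop counts (`Inf` = unreachable);
#'   `d[source] == 0`.
#' @export
bfs_distances <- function(g, source, targets = NULL, cutoff = NULL) {
  assert_graph(g)
  assert_node(g, source)
  targets <- targets %||% node_names(g)
  missing <- setdiff(targets, igraph::V(g)$name)
  if (length(missing) > 0L) {
    stop_domain(sprintf("unknown target node(s): %s", paste(missing, collapse = ", ")))
  }
  d <- igraph::distances(g, v = source, to = targets, algorithm = "unweighted")[1L, ]
  if (!is.null(cutoff)) {
    if (!is.numeric(cutoff) || cutoff <= 0) stop_usage("`cutoff` must be a positive number")
    d[d > cutoff] <- Inf
  }
  setNames(as.numeric(d), targets)
}
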