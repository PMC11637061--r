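#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a KLN ranking
#'
#' @param x A `kln_ranking` from [kln_rank()].
#' @param ... Unused.
#' @return A plain tibble with one row per node: `node`, `rank`, `kln`,
#'   `de`, `divergence`, `degree`, `kshell`.
#' @export
tidy.kln_ranking <- function(x, ...) {
  as_tibble(x)[c("node", "rank", "kln", "de", "divergence", "degree", "kshell")]
}

#' One-row summary of a KLN ranking
#'
#' @inheritParams tidy.kln_ranking
#' @return A one-row tibble: node count, top node and score, mean/max KLN.
#' @export
glance.kln_ranking <- function(x, ...) {
  tibble(
    n_nodes = nrow(x),
    top_node = if (nrow(x)) x$node[x$rank == 1L] else NA_character_,
    top_kln = if (nrow(x)) max(x$kln) else NA_real_,
    mean_kln = mean(x$kln),
    mean_de = mean(x$de)
  )
}

#' @export
tidy.kendall_result <- function(x, ...) {
  tibble(tau = x$tau, concordant = x$concordant, discordant = x$discordant,
         n = x$n, variant = x$variant)
}

#' @export
glance.sir_capacity <- function(x, ...) {
  tibble(
    n_nodes = nrow(x),
    alpha = attr(x, "alpha"), beta = attr(x, "beta"),
    iterations = attr(x, "iterations"),
    max_capacity = max(x$capacity), mean_capacity = mean(x$capacity)
  )
}

#' Plot a KLN ranking
#'
#' Lollipop chart of the top `n` nodes by KLN score.
#'
#' @param object A `kln_ranking`.
#' @param n Number of top nodes to show (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kln_ranking <- function(object, n = 15, ...) {
  d <- as_tibble(object)
  d <- d[d$rank <= n, ]
  d$node <- stats::reorder(d$node, d$kln)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$kln, y = .data$node)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$kln, yend = .data$node),
                          linewidth = 0.4, colour = "grey60") +
    ggplot2::geom_point(size = 2.2, colour = "#2c7fb8") +
    ggplot2::labs(x = "KLN importance", y = NULL,
                  title = sprintf("Top %d influential nodes", nrow(d))) +
    ggplot2::theme_minimal()
}

#' Plot an SIR infection curve
#'
#' Mean cumulative-infection curve F(t) with a +/- 2 SE ribbon.
#'
#' @param object A `sir_curve` from [infection_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sir_curve <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$f_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$f_mean - 2 * .data$f_stderr,
                                      ymax = .data$f_mean + 2 * .data$f_stderr),
                         fill = "#a6bddb", alpha = 0.5) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "round t", y = "mean cumulative infections F(t)") +
    ggplot2::theme_minimal()
}

#' Plot per-node spreading capacity against a ranking
#'
#' Capacity-by-rank curve: a smoother downward trend means the ranking
#' better matches the SIR ground truth.
#'
#' @param object A tibble from [capacity_by_rank()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot_capacity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$capacity)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 1, colour = "#d95f0e") +
    ggplot2::labs(x = "rank", y = "SIR spreading capacity",
                  subtitle = sprintf("%d upward violations", rank_roughness(object))) +
    ggplot2::theme_minimal()
}
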