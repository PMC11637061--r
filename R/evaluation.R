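#' Kendall rank correlation between two score mappings
#'
#' Exact pair counts over all unordered key pairs: a pair is concordant when
#' both mappings order it the same strict way and discordant when they order
#' it oppositely; pairs tied in either mapping count toward neither.  The
#' default statistic is `tau = (a - b) / (0.5 * n * (n - 1))` — the tie-
#' excluded numerator over the full pair count (tau-a form).  `variant =
#' "tau_b"` instead divides by the geometric mean of the tie-corrected pair
#' counts.
#'
#' @param x,y Named numeric score vectors over the same key set (n >= 2).
#' @param variant `"tau_a"` (default) or `"tau_b"`.
#' @return A `kendall_result` list: `tau`, `concordant`, `discordant`, `n`,
#'   `variant`.
#' @examples
#' x <- c(a = 1, b = 2, c = 3)
#' kendall_tau(x, c(a = 1, b = 3, c = 2))$tau # 1/3
#' @export
kendall_tau <- function(x, y, variant = c("tau_a", "tau_b")) {
  variant <- tryCatch(match.arg(variant), error = function(e) stop_usage(conditionMessage(e)))
  if (is.null(names(x)) || is.null(names(y))) {
    stop_usage("`x` and `y` must be named score vectors")
  }
  if (!setequal(names(x), names(y)) || anyDuplicated(names(x)) || anyDuplicated(names(y))) {
    stop_domain("`x` and `y` must share the same key set")
  }
  n <- length(x)
  if (n < 2L) stop_domain("need at least 2 keys")
  y <- y[names(x)]

  dx <- sign(outer(x, x, `-`))
  dy <- sign(outer(y, y, `-`))
  up <- upper.tri(dx)
  s <- dx[up] * dy[up]
  a <- sum(s > 0)
  b <- sum(s < 0)

  n0 <- n * (n - 1) / 2
  tau <- switch(variant,
    tau_a = (a - b) / n0,
    tau_b = {
      tx <- sum(dx[up] == 0)
      ty <- sum(dy[up] == 0)
      (a - b) / sqrt((n0 - tx) * (n0 - ty))
    }
  )
  structure(
    list(tau = tau, concordant = a, discordant = b, n = n, variant = variant),
    class = "kendall_result"
  )
}

#' @export
print.kendall_result <- function(x, ...) {
  cat(sprintf(
    "Kendall %s = %.4f  (concordant %d, discordant %d, n = %d)\n",
    if (x$variant == "tau_a") "tau" else "tau-b", x$tau, x$concordant, x$discordant, x$n
  ))
  invisible(x)
}

#' Top-N agreement between two rankings
#'
#' @param rank_a,rank_b Character vectors of nodes in rank order (best
#'   first), each covering at least `n` nodes.
#' @param n Cutoff.
#' @return A one-row tibble: `n`, `shared` (size of the top-n intersection),
#'   `same_position` (indices where the two top-n lists agree exactly).
#' @export
top_n_overlap <- function(rank_a, rank_b, n) {
  if (!is.numeric(n) || n < 1) stop_usage("`n` must be a positive integer")
  if (n > length(rank_a) || n > length(rank_b)) {
    stop_domain(sprintf("`n` = %d exceeds a ranking length (%d, %d)",
                        n, length(rank_a), length(rank_b)))
  }
  a <- rank_a[seq_len(n)]
  b <- rank_b[seq_len(n)]
  tibble(n = as.integer(n),
         shared = length(intersect(a, b)),
         same_position = sum(a == b))
}

#' Spreading capacities in ranking order
#'
#' Maps a method's ranking onto the SIR capacity oracle: element k is the
#' capacity of the node the method ranked k-th.  A good ranking yields a
#' smoothly decreasing sequence; the attached roughness statistic counts the
#' upward violations (positions where capacity rises from one rank to the
#' next).
#'
#' @param ranking Character vector of nodes in rank order.
#' @param capacity Named numeric vector (e.g. from [spreading_capacity()])
#'   covering every ranked node.
#' @return A tibble `rank`, `node`, `capacity` with attribute `violations`;
#'   see also [rank_roughness()].
#' @export
capacity_by_rank <- function(ranking, capacity) {
  if (is.data.frame(capacity)) capacity <- setNames(capacity$capacity, capacity$node)
  missing <- setdiff(ranking, names(capacity))
  if (length(missing) > 0L) {
    stop_domain(sprintf("capacity missing for node(s): %s", paste(missing, collapse = ", ")))
  }
  cap <- as.numeric(capacity[ranking])
  out <- tibble(rank = seq_along(ranking), node = ranking, capacity = cap)
  attr(out, "violations") <- sum(diff(cap) > 0)
  out
}

#' @rdname capacity_by_rank
#' @param x A tibble returned by [capacity_by_rank()].
#' @return `rank_roughness()`: the integer count of upward violations.
#' @export
rank_roughness <- function(x) {
  v <- attr(x, "violations")
  if (is.null(v)) stop_usage("`x` must come from capacity_by_rank()")
  v
}

#' Management-tier classification of a ranking
#'
#' Cuts a ranking into priority tiers at 1-based rank boundaries: tier 1 is
#' ranks 1..b1, tier 2 is b1+1..b2, and so on, with a final tier for all
#' remaining nodes.  The default boundaries (30, 183, 248, 382) are the
#' epidemic-management scheme for the 1204-node contact network case study:
#' primary through quaternary management groups plus ordinary nodes.
#'
#' @param ranking Character vector of nodes in rank order.
#' @param boundaries Strictly increasing positive integers, each at most
#'   `length(ranking)`.
#' @return A tibble `node`, `rank`, `tier` (integer, 1 = highest priority).
#' @export
management_tiers <- function(ranking, boundaries = c(30, 183, 248, 382)) {
  if (length(boundaries) == 0L || any(boundaries < 1)) {
    stop_usage("`boundaries` must be positive rank cut points")
  }
  if (any(diff(boundaries) <= 0)) stop_domain("`boundaries` must be strictly increasing")
  if (any(boundaries > length(ranking))) {
    stop_domain(sprintf("boundary %d exceeds ranking length %d",
                        max(boundaries), length(ranking)))
  }
  rk <- seq_along(ranking)
  tier <- findInterval(rk - 1L, c(0L, boundaries)) # rank <= b1 -> 1, etc.
  tibble(node = ranking, rank = rk, tier = as.integer(tier))
}

#' Pairwise comparison report for several rankings
#'
#' For every pair of named rankings: Kendall tau on the underlying scores and
#' the top-`n` overlap of the orderings.
#'
#' @param rankings Named list of ranking tibbles with columns `node` and a
#'   score column (`score` or `kln`), all over the same node universe.
#' @param n Top-N cutoff for the overlap columns.
#' @return A tibble `method_a`, `method_b`, `n`, `shared`, `same_position`,
#'   `tau`.
#' @export
compare_rankings <- function(rankings, n = 10) {
  if (is.null(names(rankings)) || any(names(rankings) == "")) {
    stop_usage("`rankings` must be a fully named list")
  }
  as_scores <- function(r) {
    col <- if ("score" %in% names(r)) "score" else if ("kln" %in% names(r)) "kln" else
      stop_usage("ranking tibbles need a `score` or `kln` column")
    setNames(r[[col]], r$node)
  }
  scores <- lapply(rankings, as_scores)
  universe <- names(scores[[1L]])
  for (nm in names(scores)) {
    if (!setequal(names(scores[[nm]]), universe)) {
      stop_domain(sprintf(
        "ranking '%s' covers a different node universe (e.g. %s)",
        nm, paste(head(c(setdiff(names(scores[[nm]]), universe),
                         setdiff(universe, names(scores[[nm]]))), 3L), collapse = ", ")
      ))
    }
  }
  orderings <- lapply(scores, function(s) names(s)[order(-s, names(s), method = "radix")])
  pairs <- utils::combn(names(scores), 2L, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    ov <- top_n_overlap(orderings[[pr[1L]]], orderings[[pr[2L]]], n)
    kt <- kendall_tau(scores[[pr[1L]]], scores[[pr[2L]]])
    tibble(method_a = pr[1L], method_b = pr[2L], n = ov$n,
           shared = ov$shared, same_position = ov$same_position, tau = kt$tau)
  })
}
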