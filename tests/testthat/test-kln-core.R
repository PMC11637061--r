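test_that("path change factor maps hops, self and unreachable correctly", {
  expect_equal(path_change_factor(c(4, Inf, NA, 1, 2)), c(0.25, 0.5, 1, 1, 0.5))
  expect_error(path_change_factor(0), class = "klnr_domain_error")
  expect_error(path_change_factor(-2), class = "klnr_domain_error")
})

test_that("real distribution is degree-proportional over the neighborhood", {
  fx <- worked_example_graph()
  p <- real_distribution(fx, "1")
  expect_equal(names(p), c("2", "6", "7", "8"))
  expect_equal(unname(p), c(5, 3, 2, 3) / 13)
  expect_equal(unname(round(p, 3)), c(0.385, 0.231, 0.154, 0.231))

  expect_equal(unname(real_distribution(g_star(3), "l1")), 1.0)

  tri <- g_triangle()
  expect_equal(unname(real_distribution(tri, "a")), c(0.5, 0.5))

  f <- tempfile(); writeLines(c("a b", "z z"), f)
  expect_error(real_distribution(read_edge_list(f), "z"), class = "klnr_domain_error")
})

test_that("post-removal profile carries post degrees, shells and distances", {
  fx <- worked_example_graph()
  pr <- post_removal_profile(fx, "1")
  expect_equal(pr$neighbors, c("2", "6", "7", "8"))
  expect_equal(unname(pr$post_degree), c(4, 2, 1, 2))
  expect_equal(unname(pr$pre_degree - 1), unname(pr$post_degree))
  expect_equal(unname(pr$kshell), c(3, 2, 2, 2))
  expect_equal(unname(pr$post_distance["7", c("2", "6", "8")]), c(4, 3, 2))
  expect_true(is.na(pr$post_distance["7", "7"]))

  st <- post_removal_profile(g_star(4), "hub")
  off <- st$post_distance[upper.tri(st$post_distance)]
  expect_true(all(is.infinite(off)))
  expect_true(all(st$post_degree == 0))

  tr <- post_removal_profile(g_triangle(), "a")
  expect_equal(tr$post_distance["b", "c"], 1)

  # symmetry of the distance matrix off the diagonal
  g <- random_graph("er", n = 20, p = 0.2, seed = 2)
  v <- names(which(igraph::degree(g) >= 2))[1]
  D <- post_removal_profile(g, v)$post_distance
  expect_equal(D[upper.tri(D)], t(D)[upper.tri(D)])
})

test_that("fitting rows reproduce the worked example and normalize to one", {
  fx <- worked_example_graph()
  Q <- fitting_distribution(post_removal_profile(fx, "1"))
  expect_equal(unname(round(Q["7", ], 3)), c(0.359, 0.207, 0.180, 0.254))
  expect_equal(unname(round(Q["2", ], 3)), c(0.533, 0.267, 0.067, 0.133))
  expect_equal(unname(round(Q["6", ], 3)), c(0.517, 0.259, 0.075, 0.149))
  expect_equal(unname(round(Q["8", ], 3)), c(0.341, 0.197, 0.121, 0.341))
  expect_equal(unname(rowSums(Q)), rep(1, 4), tolerance = 1e-12)

  # two neighbors with a symmetric remainder graph: identical rows up to
  # the column swap
  sq <- g_from_edges(c("i", "a"), c("i", "b"), c("a", "x"), c("b", "x"))
  Q2 <- fitting_distribution(post_removal_profile(sq, "i"))
  expect_equal(Q2["a", c("a", "b")], Q2["b", c("b", "a")], ignore_attr = TRUE)

  # row sums stay 1 across random graphs, including leaf neighborhoods
  for (s in 1:4) {
    g <- random_graph("ba", n = 15, m = 1, seed = 70 + s) # m=1 gives leaves
    for (v in igraph::V(g)$name[1:5]) {
      if (igraph::degree(g, v) == 0) next
      Qv <- fitting_distribution(post_removal_profile(g, v))
      expect_equal(unname(rowSums(Qv)), rep(1, nrow(Qv)), tolerance = 1e-12)
      expect_true(all(Qv >= 0))
    }
  }
})

test_that("KL divergence matches the published per-neighbor losses", {
  fx <- worked_example_graph()
  p <- real_distribution(fx, "1")
  Q <- fitting_distribution(post_removal_profile(fx, "1"))

  expect_equal(kl_divergence(p, p), 0)
  expect_equal(round(kl_divergence(p, Q["2", ]), 3), 0.042)
  expect_equal(round(kl_divergence(p, Q["6", ]), 3), 0.031)
  expect_equal(round(kl_divergence(p, Q["7", ]), 3), 0.002)
  expect_equal(round(kl_divergence(p, Q["8", ]), 3), 0.013)

  # the published values only recompute in base 10, not base e
  expect_false(isTRUE(all.equal(
    round(kl_divergence(p, Q["6", ], log_base = exp(1)), 3), 0.031
  )))

  expect_error(kl_divergence(p, Q["6", 1:3]), class = "klnr_domain_error")
  expect_error(kl_divergence(p, Q["6", ], log_base = 1), class = "klnr_usage_error")
})

test_that("divergence, damage influence and KLN compose as defined", {
  fx <- worked_example_graph()
  expect_equal(round(node_divergence(fx, "1"), 3), 0.218)
  expect_equal(round(damage_influence(fx, "1"), 3), 4.218)

  # KLN(i) = DE(i) + sqrt(sum of neighbor DE)
  de <- vapply(c("2", "6", "7", "8"), function(j) damage_influence(fx, j), 0)
  expect_equal(kln_score(fx, "1"), damage_influence(fx, "1") + sqrt(sum(de)))

  # degree-1 node: single-entry distributions, zero divergence, DE = 1
  ba <- random_graph("ba", n = 10, m = 1, seed = 4)
  leaf <- names(which(igraph::degree(ba) == 1))[1]
  expect_equal(damage_influence(ba, leaf), 1.0)

  # isolated node: DE = KLN = 0
  f <- tempfile(); writeLines(c("a b", "z z"), f)
  gz <- read_edge_list(f)
  expect_equal(damage_influence(gz, "z"), 0)
  expect_equal(kln_score(gz, "z"), 0)

  # star center: every leaf has DE 1, so KLN(center) = DE(center) + sqrt(k)
  st <- g_star(5)
  expect_equal(kln_score(st, "hub"), damage_influence(st, "hub") + sqrt(5))
})

test_that("kln_rank is deterministic, complete and handles degenerate graphs", {
  f <- tempfile(); writeLines(c("a a", "c c", "b b"), f)
  r0 <- kln_rank(read_edge_list(f))
  expect_equal(r0$kln, c(0, 0, 0))
  expect_equal(r0$node, c("a", "b", "c")) # identifier order on full tie

  # vertex-transitive graph: all scores equal
  cyc <- g_from_edges(c("a","b"), c("b","c"), c("c","d"), c("d","e"), c("e","a"))
  rc <- kln_rank(cyc)
  expect_equal(diff(range(rc$kln)), 0, tolerance = 1e-12)

  fx <- worked_example_graph()
  r <- kln_rank(fx)
  expect_setequal(r$node, igraph::V(fx)$name)
  expect_equal(r$rank, 1:13)
  expect_equal(r$de[r$node == "1"], damage_influence(fx, "1"))
  expect_equal(r$kln[r$node == "1"], kln_score(fx, "1"))
})

test_that("KLN bounds hold: DE >= degree and KLN >= DE on non-isolated nodes", {
  for (s in 1:3) {
    g <- random_graph("er", n = 20, p = 0.2, seed = 80 + s)
    r <- kln_rank(g)
    live <- r$degree > 0
    expect_true(all(r$divergence >= 0))
    expect_true(all(r$de[live] >= r$degree[live]))
    expect_true(all(r$kln[live] >= r$de[live]))
  }
})

test_that("kln_rank matches the naive brute-force reference implementation", {
  graphs <- list(
    worked_example_graph(),
    random_graph("er", n = 18, p = 0.2, seed = 21),
    random_graph("ba", n = 15, m = 2, seed = 22),
    random_graph("ws", n = 16, nei = 2, p = 0.2, seed = 23)
  )
  for (g in graphs) {
    ref <- kln_naive(adj_matrix(g))
    r <- kln_rank(g)
    expect_equal(setNames(r$de, r$node)[names(ref$de)], ref$de, tolerance = 1e-9)
    expect_equal(setNames(r$kln, r$node)[names(ref$kln)], ref$kln, tolerance = 1e-9)
  }
})

test_that("scores are invariant to edge-file ordering and node relabeling", {
  g <- random_graph("er", n = 15, p = 0.25, seed = 31)
  f1 <- edge_list_file(g)
  f2 <- edge_list_file(g, shuffle_seed = 99)
  r1 <- kln_rank(read_edge_list(f1))
  r2 <- kln_rank(read_edge_list(f2))
  expect_equal(r1$node, r2$node)
  expect_equal(r1$kln, r2$kln)
  unlink(c(f1, f2))

  perm <- withr::with_seed(32, sample(igraph::vcount(g)))
  relab <- setNames(sprintf("n%02d", perm), igraph::V(g)$name)
  g2 <- g
  igraph::V(g2)$name <- unname(relab[igraph::V(g)$name])
  r <- kln_rank(g)
  rr <- kln_rank(g2)
  expect_equal(
    setNames(rr$kln, rr$node)[unname(relab[r$node])],
    setNames(r$kln, unname(relab[r$node])),
    tolerance = 1e-12
  )
})

test_that("automorphically equivalent nodes receive identical KLN scores", {
  fx <- worked_example_graph()
  r <- kln_rank(fx)
  expect_equal(r$kln[r$node == "4"], r$kln[r$node == "5"], tolerance = 1e-12)

  # constructed symmetric pair: u and v share every neighbor
  g <- g_from_edges(c("u", "a"), c("u", "b"), c("v", "a"), c("v", "b"),
                    c("a", "b"), c("a", "c"), c("b", "c"), c("c", "d"))
  rs <- kln_rank(g)
  expect_equal(rs$kln[rs$node == "u"], rs$kln[rs$node == "v"], tolerance = 1e-12)
})

test_that("the distance cutoff only turns far pairs unreachable", {
  fx <- worked_example_graph()
  # cutoff beyond the diameter changes nothing
  expect_equal(kln_rank(fx, cutoff = 50)$kln, kln_rank(fx)$kln)
  # a binding cutoff alters distances for node 1's neighborhood (7 is 4 hops
  # from 2 after removal) but still yields valid distributions
  Q <- fitting_distribution(post_removal_profile(fx, "1", cutoff = 2))
  expect_equal(unname(rowSums(Q)), rep(1, 4), tolerance = 1e-12)
  expect_equal(Q["7", "2"], sqrt(0.5) * 4 / sum(sqrt(c(0.5, 0.5, 1, 0.5)) * c(4, 2, 1, 2)))
})
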