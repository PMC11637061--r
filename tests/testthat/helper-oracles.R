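# Independent brute-force reference implementations.  These deliberately
# avoid the package's code paths (and igraph's algorithms where the package
# relies on them): plain matrices, Floyd-Warshall distances, naive loops.

# All-pairs shortest paths by Floyd-Warshall on a dense adjacency matrix.
fw_distances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  dimnames(D) <- dimnames(A)
  D
}

# K-shell by literal iterative stripping.
kshell_naive <- function(A) {
  nodes <- rownames(A)
  shell <- stats::setNames(integer(length(nodes)), nodes)
  alive <- stats::setNames(rep(TRUE, length(nodes)), nodes)
  k <- 0L
  while (any(alive)) {
    repeat {
      sub <- A[alive, alive, drop = FALSE]
      deg <- rowSums(sub)
      strip <- rownames(sub)[deg <= k]
      if (length(strip) == 0L) break
      shell[strip] <- k
      alive[strip] <- FALSE
      if (!any(alive)) break
    }
    k <- k + 1L
  }
  shell
}

# Full KLN pipeline with naive loops; returns per-node DE and KLN.
kln_naive <- function(A, log_base = 10, floor = 1e-10) {
  nodes <- rownames(A)
  deg <- rowSums(A)
  ks <- kshell_naive(A)
  de <- stats::setNames(numeric(length(nodes)), nodes)
  for (i in nodes) {
    if (deg[i] == 0) next
    nb <- sort(nodes[A[i, ] > 0], method = "radix")
    p <- deg[nb] / sum(deg[nb])
    rest <- setdiff(nodes, i)
    B <- A[rest, rest, drop = FALSE]
    D <- fw_distances(B)
    dpost <- rowSums(B)[nb]
    d_i <- 0
    for (n in nb) {
      w <- numeric(length(nb))
      names(w) <- nb
      for (j in nb) {
        lam <- if (n == j) 1 else if (is.infinite(D[n, j])) 0.5 else 1 / D[n, j]
        dj <- if (dpost[j] == 0) floor else dpost[j]
        w[j] <- sqrt(lam) * dj
      }
      q <- w / sum(w)
      kl <- 0
      for (j in nb) {
        if (p[j] > 0) kl <- kl + p[j] * log(p[j] / max(q[j], floor)) / log(log_base)
      }
      d_i <- d_i + ks[n] * kl
    }
    de[i] <- d_i + deg[i]
  }
  kln <- stats::setNames(numeric(length(nodes)), nodes)
  for (i in nodes) {
    if (deg[i] == 0) next
    nb <- nodes[A[i, ] > 0]
    kln[i] <- de[i] + sqrt(sum(de[nb]))
  }
  list(de = de, kln = kln)
}

# Exact expected final outbreak size of the synchronous SIR process with
# beta = 1, by enumerating every branch of the outcome tree.
sir_expected_size_naive <- function(A, seed_idx, alpha) {
  n <- nrow(A)
  recurse <- function(infected, susceptible, total) {
    if (length(infected) == 0L) return(total)
    m <- vapply(susceptible, function(s) sum(A[s, infected] > 0), 0)
    cand <- susceptible[m > 0]
    p <- 1 - (1 - alpha)^m[m > 0]
    if (length(cand) == 0L) return(total)
    expv <- 0
    for (mask in 0:(2^length(cand) - 1)) {
      pick <- as.logical(bitwAnd(mask, 2^(seq_along(cand) - 1)))
      prob <- prod(ifelse(pick, p, 1 - p))
      if (prob == 0) next
      newly <- cand[pick]
      expv <- expv + prob *
        recurse(newly, setdiff(susceptible, newly), total + length(newly))
    }
    expv
  }
  recurse(seed_idx, setdiff(seq_len(n), seed_idx), length(seed_idx))
}

# Kendall tau by a literal double loop over pairs (Eq.-style tie exclusion).
kendall_naive <- function(x, y) {
  n <- length(x)
  a <- 0L
  b <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) a <- a + 1L else if (s < 0) b <- b + 1L
    }
  }
  list(tau = (a - b) / (0.5 * n * (n - 1)), a = a, b = b)
}

# PageRank by direct solution of the stationary linear system (no dangling
# nodes: use on connected graphs only).
pagerank_solve <- function(A, damping) {
  n <- nrow(A)
  deg <- colSums(A)
  M <- sweep(A, 2, deg, `/`)
  r <- solve(diag(n) - damping * M, rep((1 - damping) / n, n))
  stats::setNames(r / sum(r) * 1, rownames(A)) # solve is already normalized; keep names
}
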