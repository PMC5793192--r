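# Independent brute-force oracles used to cross-check the package kernels.

# Unweighted betweenness by direct shortest-path counting: sigma(s,t) and
# sigma(s,t|v) from BFS distance layers, each unordered pair counted once.
bruteBetweenness <- function(edges) {
  nodes <- sort(unique(c(edges$a, edges$b)))
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    adj[edges$a[i], edges$b[i]] <- TRUE
    adj[edges$b[i], edges$a[i]] <- TRUE
  }
  bfs <- function(s) {
    d <- rep(Inf, n); sig <- rep(0, n)
    d[s] <- 0; sig[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (u in frontier) for (v in which(adj[u, ])) {
        if (is.infinite(d[v])) { d[v] <- d[u] + 1; nxt <- c(nxt, v) }
        if (d[v] == d[u] + 1) sig[v] <- sig[v] + sig[u]
      }
      frontier <- unique(nxt)
    }
    list(d = d, sig = sig)
  }
  sp <- lapply(seq_len(n), bfs)
  btw <- stats::setNames(rep(0, n), nodes)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (is.infinite(sp[[s]]$d[t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (sp[[s]]$d[v] + sp[[t]]$d[v] == sp[[s]]$d[t]) {
        btw[v] <- btw[v] + sp[[s]]$sig[v] * sp[[t]]$sig[v] / sp[[s]]$sig[t]
      }
    }
  }
  btw
}

# R-side canonical triad code, independent of the C++ kernel: minimum over
# all 6 orderings of the base-4 pair-state encoding.
rCanonicalCode <- function(s12, s13, s23) {
  flip <- function(s) ifelse(s == 1, 2, ifelse(s == 2, 1, s))
  st <- matrix(0L, 3, 3)
  st[1, 2] <- s12; st[2, 1] <- flip(s12)
  st[1, 3] <- s13; st[3, 1] <- flip(s13)
  st[2, 3] <- s23; st[3, 2] <- flip(s23)
  perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  min(apply(perms, 1, function(p)
    st[p[1], p[2]] * 16 + st[p[1], p[3]] * 4 + st[p[2], p[3]]))
}

# Pair state of (u, v) from raw edge/arc data frames (names, not indices).
pairState <- function(u, v, ppi, reg) {
  mut <- any((ppi$a == u & ppi$b == v) | (ppi$a == v & ppi$b == u))
  fwd <- any(reg$tf == u & reg$target == v)
  bwd <- any(reg$tf == v & reg$target == u)
  if (mut || (fwd && bwd)) 3L else if (fwd) 1L else if (bwd) 2L else 0L
}

# All-triples census oracle over C(n, 3) node triples.
bruteCensus <- function(network) {
  nodes <- network@nodes
  counts <- integer()
  for (cols in utils::combn(length(nodes), 3, simplify = FALSE)) {
    u <- nodes[cols[1]]; v <- nodes[cols[2]]; w <- nodes[cols[3]]
    s <- c(pairState(u, v, network@ppi, network@reg),
           pairState(u, w, network@ppi, network@reg),
           pairState(v, w, network@ppi, network@reg))
    if (sum(s > 0) < 2) next
    code <- as.character(rCanonicalCode(s[1], s[2], s[3]))
    counts[code] <- (if (is.na(counts[code])) 0L else counts[code]) + 1L
  }
  data.frame(code = as.integer(names(counts)), count = as.integer(counts))
}

# Modularity by direct double summation over the adjacency matrix.
bruteModularity <- function(edges, assignment) {
  nodes <- names(assignment)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    A[edges$a[i], edges$b[i]] <- 1
    A[edges$b[i], edges$a[i]] <- 1
  }
  k <- rowSums(A)
  m2 <- sum(A)
  same <- outer(assignment[nodes], assignment[nodes], "==")
  sum(((A - outer(k, k) / m2) * same)) / m2
}

# Hypergeometric upper tail by exhaustive enumeration of all n-subsets.
bruteHyperP <- function(N, K, n, k) {
  hits <- 0; total <- 0
  members <- seq_len(K)
  for (draw in utils::combn(N, n, simplify = FALSE)) {
    total <- total + 1
    if (sum(draw %in% members) >= k) hits <- hits + 1
  }
  hits / total
}

# A mixed random fixture used across motif tests.
mixedFixture <- function(nNodes = 30, meanDegree = 3, nTfs = 6,
                         nTargets = 3, seed = 1) {
  edges <- generateInteractome(nNodes, meanDegree, seed = seed)
  arcs <- generateRegulon(nTfs, nTargets, sprintf("N%04d", seq_len(nNodes)),
                          seed = seed + 1000)
  integratedNetwork(ppi = edges, reg = arcs)
}
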