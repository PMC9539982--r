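# Independent oracles and fixture builders used across the suite.

# Exhaustive quadruple enumeration of diamond modules: every (mh, auto,
# unordered fungus pair) with all four links present. Deliberately naive.
brute_diamonds <- function(net) {
  nf <- ncol(net$M)
  total <- 0L
  for (m in seq_len(nrow(net$M)))
    for (a in seq_len(nrow(net$A)))
      for (f1 in seq_len(nf - 1L))
        for (f2 in seq((f1 + 1L), nf))
          if (net$M[m, f1] == 1L && net$M[m, f2] == 1L &&
              net$A[a, f1] == 1L && net$A[a, f2] == 1L)
            total <- total + 1L
  total
}

# Random tripartite network with iid Bernoulli(p) cells; rows forced
# non-empty so the tripartite_network invariants hold.
rand_net <- function(nm, na, nf, p = 0.4) {
  draw_block <- function(n, prefix) {
    b <- matrix(rbinom(n * nf, 1L, p), n, nf,
                dimnames = list(paste0(prefix, seq_len(n)),
                                paste0("f", seq_len(nf))))
    for (i in seq_len(n)) if (sum(b[i, ]) == 0L) b[i, sample.int(nf, 1L)] <- 1L
    b
  }
  M <- draw_block(nm, "mh")
  A <- draw_block(na, "auto")
  guild <- stats::setNames(c(rep("mycoheterotroph", nm), rep("autotroph", na)),
                           c(rownames(M), rownames(A)))
  tripartite_network(rbind(M, A), guild)
}

# Tip correlations from root-to-MRCA path lengths, enumerated directly on
# the edge table (no covariance machinery): psv = 1 - mean off-diagonal.
psv_oracle <- function(community, tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    nodes <- integer(0)
    while (node != root) {
      nodes <- c(nodes, node)
      node <- parent[node]
    }
    nodes
  }
  depth <- function(node) sum(elen[path_to_root(node)])
  idx <- match(community, tree$tip.label)
  k <- length(idx)
  C <- matrix(1, k, k)
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    pi <- path_to_root(idx[i]); pj <- path_to_root(idx[j])
    shared <- sum(elen[intersect(pi, pj)])
    C[i, j] <- C[j, i] <- shared / sqrt(depth(idx[i]) * depth(idx[j]))
  }
  1 - mean(C[upper.tri(C)])
}

# Tip-to-tip path lengths by breadth-first search over the undirected edge
# list -- independent of any cophenetic routine.
naive_cophenetic <- function(tree) {
  nv <- max(tree$edge)
  adj <- vector("list", nv)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  n_tip <- length(tree$tip.label)
  D <- matrix(0, n_tip, n_tip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(n_tip)) {
    dist <- rep(NA_real_, nv); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (r in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][r, 1]
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + adj[[v]][r, 2]
          queue <- c(queue, u)
        }
      }
    }
    D[s, ] <- dist[seq_len(n_tip)]
  }
  D
}

# Small species_communities fixture: two guilds, controllable totals.
toy_communities <- function(counts, guild) {
  structure(list(counts = counts, guild = guild,
                 n_samples = stats::setNames(rep(1L, nrow(counts)),
                                             rownames(counts))),
            class = "species_communities")
}

# Random symmetric zero-diagonal distance matrix over shared ids.
rand_dist <- function(n, ids = paste0("t", seq_len(n)), dims = 3L) {
  d <- as.matrix(stats::dist(matrix(stats::rnorm(n * dims), n)))
  dimnames(d) <- list(ids, ids)
  d
}
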