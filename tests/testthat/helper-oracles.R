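# Independent oracles used by the dual-route checks. These deliberately
# avoid igraph / phyper / p.adjust: distances by Floyd-Warshall, shortest
# paths by DP over the shortest-path DAG, hypergeometric tails by explicit
# log-scale summation, BH by the hand step-up rule.

# All-pairs shortest-path distances of a 0/1 adjacency matrix.
oracle_fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    via <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, via)
  }
  d
}

# Number of shortest paths between every ordered pair, given adj and its
# distance matrix. sigma[s, t] = 0 when t is unreachable from s (s != t).
oracle_path_counts <- function(adj, d) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  maxd <- max(d[is.finite(d)])
  if (maxd < 1) return(sigma)
  for (len in 1:maxd) {
    for (s in seq_len(n)) {
      for (t in which(d[s, ] == len)) {
        preds <- which(adj[, t] == 1 & d[s, ] == len - 1)
        sigma[s, t] <- sum(sigma[s, preds])
      }
    }
  }
  sigma
}

# Exact directed unnormalized betweenness by enumeration over the
# shortest-path DAG: b(v) = sum over s != t reachable, v != s, t of
# sigma_sv * sigma_vt / sigma_st when d(s,v) + d(v,t) = d(s,t).
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_fw_distances(adj)
  sigma <- oracle_path_counts(adj, d)
  b <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || !is.finite(d[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t])
        b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  b
}

# Global panel from the Floyd-Warshall distances.
oracle_topology <- function(adj) {
  d <- oracle_fw_distances(adj)
  diag(d) <- Inf
  reach <- is.finite(d)
  list(n_shortest_paths = sum(reach),
       diameter = if (any(reach)) max(d[reach]) else 0,
       characteristic_path_length = if (any(reach)) mean(d[reach]) else NA)
}

# P(X >= k), X ~ Hypergeometric(N, K, n), by explicit log-scale summation.
oracle_hypergeom_tail <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  terms <- vapply(k:hi, function(i)
    exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)), numeric(1))
  min(1, sum(terms))
}

# Hand BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, mapped back.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- ps * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Closed-form simple linear regression on log10 axes.
oracle_loglog_fit <- function(x, y) {
  lx <- log10(x); ly <- log10(y)
  n <- length(lx)
  sxx <- sum((lx - mean(lx))^2)
  sxy <- sum((lx - mean(lx)) * (ly - mean(ly)))
  syy <- sum((ly - mean(ly))^2)
  slope <- sxy / sxx
  r <- sxy / sqrt(sxx * syy)
  list(gamma = slope, R = r, r_squared = r^2)
}

# Random simple directed graph as adjacency + matching gene_network.
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(as.integer(runif(n * n) < p), n, n)
  diag(adj) <- 0L
  nodes <- sprintf("v%02d", seq_len(n))
  idx <- which(adj == 1, arr.ind = TRUE)
  edges <- data.frame(source = nodes[idx[, 1]], interaction = "i",
                      target = nodes[idx[, 2]], stringsAsFactors = FALSE)
  net <- gene_network(edges,
                      node_types = setNames(rep("gene", n), nodes))
  list(adj = adj, net = net, nodes = nodes)
}

# Direct (quadratic-loop) 2-D Gaussian product KDE at the sample points,
# used as the oracle for kde-based local-hub densities.
oracle_kde2 <- function(pts, hx, hy) {
  n <- nrow(pts)
  vapply(seq_len(n), function(i) {
    mean(vapply(seq_len(n), function(j)
      dnorm((pts[i, 1] - pts[j, 1]) / hx) / hx *
        dnorm((pts[i, 2] - pts[j, 2]) / hy) / hy, numeric(1)))
  }, numeric(1))
}
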