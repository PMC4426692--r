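# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: dense matrix algebra, explicit BFS enumeration,
# Floyd-Warshall, and textbook formulas.

# Dense-matrix reference for the communicating-vessels dynamics: one step is
# (I - k L) applied to the energy vector, then clamp-subtract D.
oracle_step <- function(e, A, k, D) {
  deg <- rowSums(A)
  L <- diag(deg, nrow(A)) - A
  e2 <- as.numeric((diag(nrow(A)) - k * L) %*% e)
  list(after_flow = e2, after_dissipation = pmax(e2 - D, 0))
}

oracle_run <- function(e, A, k, D, theta = 1, max_steps = 100000) {
  reached <- e >= theta
  step <- 0L
  while (any(e >= theta) && step < max_steps) {
    step <- step + 1L
    ph <- oracle_step(e, A, k, D)
    reached <- reached | (ph$after_flow >= theta)
    e <- ph$after_dissipation
  }
  list(silencing_time = step, reach = sum(reached), energy = e)
}

# All-pairs BFS with shortest-path counting; returns distance and count
# matrices. Used by the centrality and geodesic-distance oracles.
oracle_bfs_all <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    cnt <- rep(0, n)
    dist[s] <- 0
    cnt[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(A[u, ] == 1)) {
          if (is.infinite(dist[v])) {
            dist[v] <- dist[u] + 1
            nxt <- c(nxt, v)
          }
          if (dist[v] == dist[u] + 1) cnt[v] <- cnt[v] + cnt[u]
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
    S[s, ] <- cnt
  }
  list(dist = D, count = S)
}

# Brute-force degree/closeness/betweenness matching the documented
# conventions: component-scaled closeness, pair-normalised betweenness with
# endpoints excluded.
oracle_centrality <- function(net) {
  A <- as.matrix(igraph::as_adjacency_matrix(net))
  n <- nrow(A)
  bfs <- oracle_bfs_all(A)
  D <- bfs$dist
  S <- bfs$count
  deg <- rowSums(A)
  clo <- numeric(n)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    reach <- which(is.finite(D[v, ]) & seq_len(n) != v)
    r <- length(reach) + 1
    clo[v] <- if (r > 1 && n > 1) {
      ((r - 1) / sum(D[v, reach])) * ((r - 1) / (n - 1))
    } else 0
    if (n > 2) {
      acc <- 0
      for (s in seq_len(n - 1)) {
        for (t in seq(s + 1, n)) {
          if (s == v || t == v || is.infinite(D[s, t])) next
          if (D[s, v] + D[v, t] == D[s, t]) {
            acc <- acc + S[s, v] * S[v, t] / S[s, t]
          }
        }
      }
      btw[v] <- acc / ((n - 1) * (n - 2) / 2)
    }
  }
  data.frame(node = igraph::V(net)$name, degree = unname(deg),
             closeness = clo, betweenness = btw, stringsAsFactors = FALSE)
}

oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# Textbook Welch statistic and Welch-Satterthwaite df.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * length(b) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}

# Simple Erdos-Renyi fixture on named nodes, built without igraph samplers so
# fixtures stay independent of the package's generator.
random_fixture_graph <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  pairs <- utils::combn(n, 2)
  keep <- runif(ncol(pairs)) < p
  interaction_network(ids[pairs[1, keep]], ids[pairs[2, keep]],
                      isolated = ids)
}

path_graph <- function(ids) {
  interaction_network(ids[-length(ids)], ids[-1])
}
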