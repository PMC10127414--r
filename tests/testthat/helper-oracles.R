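# Independent brute-force oracles for graph metrics and exact tests.  These
# deliberately avoid the package's compiled code paths: distances come from
# Floyd-Warshall, betweenness from shortest-path counting over the distance
# matrix, and Fisher p-values from full hypergeometric enumeration.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_lp <- function(adj) {
  d <- oracle_distances(adj)
  v <- d[upper.tri(d)]
  f <- v[is.finite(v)]
  list(lp = if (length(f)) mean(f) else NA_real_,
       unreachable = sum(!is.finite(v)))
}

oracle_eglobal <- function(adj) {
  d <- oracle_distances(adj)
  v <- d[upper.tri(d)]
  if (!length(v)) return(0)
  mean(ifelse(is.finite(v), 1 / v, 0))
}

oracle_nodal_eff <- function(adj) {
  d <- oracle_distances(adj)
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    v <- d[i, -i]
    mean(ifelse(is.finite(v), 1 / v, 0))
  })
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb]) / 2 / (k * (k - 1) / 2)
  })
}

oracle_local_eff <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_eglobal(adj[nb, nb, drop = FALSE])
  })
}

# number of geodesics between every ordered pair, from the distance matrix
oracle_path_counts <- function(adj, d) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  finite_d <- d
  finite_d[!is.finite(d)] <- -1
  maxd <- max(finite_d)
  if (maxd >= 1) {
    for (dist in seq_len(maxd)) {
      for (s in seq_len(n)) {
        for (t in seq_len(n)) {
          if (isTRUE(d[s, t] == dist)) {
            preds <- which(adj[, t] == 1 & d[s, ] == dist - 1)
            sigma[s, t] <- sum(sigma[s, preds])
          }
        }
      }
    }
  }
  sigma
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  if (n < 3) return(rep(0, n))
  d <- oracle_distances(adj)
  sigma <- oracle_path_counts(adj, d)
  bc <- rep(0, n)
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      if (!is.finite(d[s, t]) || sigma[s, t] == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (isTRUE(d[s, v] + d[v, t] == d[s, t])) {
          bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

# exact two-tailed Fisher p by enumerating every table with the observed
# margins and summing the probabilities <= that of the observed table
oracle_fisher <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  lo <- max(0, r1 + c1 - N)
  hi <- min(r1, c1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, c1, N - c1, r1)
  p_obs <- stats::dhyper(a, c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

random_adjacency <- function(n, n_edges = NULL, p_edge = NULL) {
  adj <- matrix(0, n, n)
  pairs <- which(upper.tri(adj))
  if (is.null(n_edges)) {
    if (is.null(p_edge)) p_edge <- stats::runif(1, 0.1, 0.9)
    sel <- pairs[stats::runif(length(pairs)) < p_edge]
  } else {
    sel <- sample(pairs, n_edges)
  }
  adj[sel] <- 1
  adj + t(adj)
}

# small named fixtures used across files
graph_fixtures <- local({
  complete <- function(n) { a <- matrix(1, n, n); diag(a) <- 0; a }
  star <- function(n) {
    a <- matrix(0, n, n); a[1, 2:n] <- 1; a[2:n, 1] <- 1; a
  }
  path <- function(n) {
    a <- matrix(0, n, n)
    for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
    a
  }
  tri_pendant <- {
    a <- matrix(0, 4, 4)
    a[1, 2] <- a[2, 1] <- 1; a[1, 3] <- a[3, 1] <- 1
    a[2, 3] <- a[3, 2] <- 1; a[1, 4] <- a[4, 1] <- 1
    a
  }
  list(complete = complete, star = star, path = path,
       tri_pendant = tri_pendant)
})

# ring lattice: n nodes, each linked to `k` nearest neighbours per side
ring_lattice <- function(n, k = 2) {
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (s in seq_len(k)) {
      j <- ((i - 1 + s) %% n) + 1
      a[i, j] <- a[j, i] <- 1
    }
  }
  a
}
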