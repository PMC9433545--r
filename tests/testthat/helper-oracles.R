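# Independent brute-force graph-measure oracles (base R only, no igraph).
# Deliberately naive: Floyd-Warshall distances, exhaustive shortest-path
# enumeration for betweenness, direct neighbour-pair counts for clustering.

o_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

o_clustering <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    e <- sum(A[nb, nb]) / 2
    e / (k * (k - 1) / 2)
  })
}

o_lp <- function(D) {
  d <- D[upper.tri(D)]
  mean(d[is.finite(d)])
}

o_nodal_path <- function(D) {
  n <- nrow(D)
  sapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0) NA_real_ else mean(d)
  })
}

# enumerate every shortest path between s and t; returns a matrix with one
# row per path (node sequences padded with NA)
o_enum_paths <- function(A, D, s, t) {
  if (!is.finite(D[s, t]) || s == t) return(list())
  paths <- list()
  walk <- function(cur, acc) {
    if (cur == t) {
      paths[[length(paths) + 1]] <<- acc
      return()
    }
    for (u in which(A[cur, ] == 1)) {
      if (is.finite(D[u, t]) && D[u, t] == D[cur, t] - 1) walk(u, c(acc, u))
    }
  }
  walk(s, s)
  paths
}

o_betweenness <- function(A) {
  n <- nrow(A)
  D <- o_distances(A)
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- o_enum_paths(A, D, s, t)
      if (length(paths) == 0) next
      interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(interior) > 0) {
        tab <- table(interior)
        b[as.integer(names(tab))] <- b[as.integer(names(tab))] +
          as.numeric(tab) / length(paths)
      }
    }
  }
  b
}

o_global_eff <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  iv <- 1 / D
  iv[!is.finite(iv)] <- 0
  diag(iv) <- 0
  sum(iv) / (n * (n - 1))
}

o_nodal_eff <- function(D) {
  n <- nrow(D)
  iv <- 1 / D
  iv[!is.finite(iv)] <- 0
  diag(iv) <- 0
  rowSums(iv) / (n - 1)
}

o_local_eff <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    o_global_eff(o_distances(A[nb, nb, drop = FALSE]))
  })
}

o_assortativity <- function(A) {
  deg <- rowSums(A)
  ij <- which(A == 1, arr.ind = TRUE)   # both orientations
  if (stats::sd(deg[ij[, 1]]) == 0 || stats::sd(deg[ij[, 2]]) == 0) {
    return(NA_real_)
  }
  stats::cor(deg[ij[, 1]], deg[ij[, 2]])
}

o_hierarchy <- function(A) {
  k <- rowSums(A)
  ci <- o_clustering(A)
  ok <- k >= 2 & ci > 0
  if (sum(ok) < 2 || length(unique(k[ok])) < 2) return(NA_real_)
  x <- log(k[ok]); y <- log(ci[ok])
  -(sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2))
}

o_synchronization <- function(A) {
  L <- diag(rowSums(A)) - A
  # singular values of a PSD matrix are its eigenvalues; svd is an
  # independent route from the implementation's eigen()
  sv <- sort(svd(L)$d)
  if (sv[length(sv)] <= 1e-12) return(0)
  l2 <- sv[2]
  if (l2 < 1e-8) return(0)
  l2 / sv[length(sv)]
}

# seeded Erdos-Renyi adjacency
o_random_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- as.integer(runif(n * (n - 1) / 2) < p)
  A + t(A)
}

# small named graphs
g_complete <- function(n) { A <- matrix(1, n, n); diag(A) <- 0; A }
g_star <- function(n) { A <- matrix(0, n, n); A[1, 2:n] <- 1; A[2:n, 1] <- 1; A }
g_path <- function(n) { A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  A }
g_cycle <- function(n) { A <- g_path(n); A[1, n] <- A[n, 1] <- 1; A }
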