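# Brute-force oracles, independent of the package's implementation paths.

# adjacency matrix -> tsnet
adj_to_net <- function(A) {
  n <- nrow(A)
  e <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  tsnet(n, e)
}

rand_adj <- function(n, p) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  on <- up[stats::runif(length(up)) < p]
  A[on] <- 1
  A + t(A)
}

# clustering by exhaustive neighbour-pair enumeration
bf_local_clustering <- function(A, i) {
  nb <- which(A[i, ] == 1)
  k <- length(nb)
  if (k < 2) return(0)
  cnt <- 0
  for (a in seq_len(k - 1)) for (b in (a + 1):k)
    cnt <- cnt + A[nb[a], nb[b]]
  cnt / (k * (k - 1) / 2)
}

bf_clustering <- function(A) mean(vapply(seq_len(nrow(A)), function(i)
  bf_local_clustering(A, i), numeric(1)))

# all-pairs shortest paths by plain BFS from every source
bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] == 1)) if (dist[w] > d) { dist[w] <- d; nxt <- c(nxt, w) }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

# average shortest path, finite pairs only, self-pairs included by default
bf_avg_path <- function(A, include_self = TRUE) {
  D <- bf_distances(A)
  up <- D[upper.tri(D)]
  fin <- up[is.finite(up)]
  den <- length(fin) + if (include_self) nrow(A) else 0
  if (den == 0) return(0)
  sum(fin) / den
}

bf_components <- function(A) {
  n <- nrow(A)
  seen <- rep(FALSE, n); k <- 0
  for (s in seq_len(n)) {
    if (seen[s]) next
    k <- k + 1
    frontier <- s; seen[s] <- TRUE
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in which(A[v, ] == 1))
        if (!seen[w]) { seen[w] <- TRUE; nxt <- c(nxt, w) }
      frontier <- nxt
    }
  }
  k
}

# max absolute cross-covariance by direct lag enumeration
# (population-SD normalization, 1/N convention, zero-padded lags)
bf_maxcross <- function(x, y, max_lag) {
  n <- length(x)
  norm <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  x <- norm(x); y <- norm(y)
  vals <- vapply(-max_lag:max_lag, function(tau) {
    if (tau >= 0) {
      t <- seq_len(n - tau)
      abs(sum(x[t + tau] * y[t]) / n)
    } else {
      t <- seq_len(n + tau)
      abs(sum(x[t] * y[t - tau]) / n)
    }
  }, numeric(1))
  max(vals)
}
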