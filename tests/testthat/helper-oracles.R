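# Independent brute-force oracles, deliberately written with different
# algorithms than the package implementation.

# mean local clustering by explicit neighbour-pair enumeration
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  ci <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1L)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0L
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        links <- links + adj[nb[a], nb[b]]
      }
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
  mean(ci)
}

# all-pairs shortest paths by repeated min-plus matrix products
oracle_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj == 1L] <- 1
  diag(D) <- 0
  for (rep in seq_len(n)) {
    Dn <- D
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        Dn[i, j] <- min(D[i, j], min(D[i, ] + D[, j]))
      }
    }
    if (identical(Dn, D)) break
    D <- Dn
  }
  D
}

# finite-only characteristic path length by direct enumeration
oracle_charpath <- function(D) {
  vals <- c()
  n <- nrow(D)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (is.finite(D[i, j])) vals <- c(vals, D[i, j])
    }
  }
  if (length(vals) == 0) NA_real_ else sum(vals) / length(vals)
}

# PLI by the literal three-case sign rule, wrapping with floor arithmetic
# rather than atan2
oracle_pli <- function(phi1, phi2) {
  d <- phi1 - phi2
  d <- d - 2 * pi * floor((d + pi) / (2 * pi))   # [-pi, pi)
  d[d == -pi] <- pi                              # -> (-pi, pi]
  s <- ifelse(d > 0, 1, ifelse(d < 0, -1, 0))
  abs(sum(s) / length(s))
}

# symmetric zero-diagonal random weight matrix
random_weight_matrix <- function(n, seed) {
  set.seed(seed)
  w <- matrix(runif(n * n), n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

# Erdos-Renyi-like binary graph with a fixed edge count
random_binary_graph <- function(n, m, seed) {
  set.seed(seed)
  ut <- which(upper.tri(matrix(0, n, n)))
  pick <- sample(ut, m)
  adj <- matrix(0L, n, n)
  adj[pick] <- 1L
  binary_graph(adj + t(adj))
}

# pure-tone recording at frequency f with an exact phase offset on channel 2
tone_recording <- function(f, offset, fs = 500, dur = 5, extra_channels = 0) {
  t_sec <- (seq_len(round(dur * fs)) - 1) / fs
  rows <- list(cos(2 * pi * f * t_sec), cos(2 * pi * f * t_sec - offset))
  for (k in seq_len(extra_channels)) rows[[2 + k]] <- sin(2 * pi * f * t_sec)
  x <- do.call(rbind, rows)
  plinet:::new_roi_recording(x, fs, paste0("roi", seq_len(nrow(x))), "sub-x", "DR")
}
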