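# Independent brute-force oracles used across tests.

# Floyd-Warshall all-pairs shortest paths on a link-length matrix
# (Inf = absent link).
floyd_warshall <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    via <- d[i, k] + d[k, j]
    if (via < d[i, j]) d[i, j] <- via
  }
  d
}

# Direct triple-sum evaluation of the max-normalized geometric-mean
# clustering coefficient.
cc_triple_sum <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  if (mx == 0) return(numeric(n))
  Wh <- W / mx
  k <- rowSums(W > 0)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h)
        s <- s + (Wh[i, j] * Wh[i, h] * Wh[j, h])^(1 / 3)
    }
    cc[i] <- s / (k[i] * (k[i] - 1))
  }
  cc
}

# Random symmetric nonnegative weight matrix with zero diagonal; density
# controls the fraction of present links.
random_weight_matrix <- function(n, density = 1) {
  W <- matrix(0, n, n)
  up <- upper.tri(W)
  w <- runif(sum(up), 0.05, 1)
  if (density < 1) w[runif(length(w)) > density] <- 0
  W[up] <- w
  W <- W + t(W)
  W
}

# Small forward model stand-in with a fully controlled gain matrix.
stub_forward_model <- function(gain, node_seeds = seq_len(ncol(gain))) {
  structure(list(gain = gain,
                 source_pos = matrix(rnorm(3 * ncol(gain)), ncol = 3),
                 sensor_pos = matrix(rnorm(3 * nrow(gain)), ncol = 3),
                 node_seeds = node_seeds),
            class = "forward_model")
}

# Epoch set wrapped around a single channels x samples matrix.
single_epoch_set <- function(x, fs, epoch_len_s = ncol(x) / fs,
                             labels = sprintf("E%02d", seq_len(nrow(x)))) {
  arr <- array(x, c(1, nrow(x), ncol(x)))
  epoch_set(arr, fs = fs, labels = labels, epoch_len_s = epoch_len_s)
}
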