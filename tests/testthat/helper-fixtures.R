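# Shared fixtures and independent oracles used across the test files.

## small planted-community dataset, cheap enough for repeated use
small_tep <- function(seed = 1, n_sites = 8, n_channels = 12,
                      n_timepoints = 80, n_communities = 2, snr = 5, ...) {
  simulate_tep_dataset(n_sites = n_sites, n_channels = n_channels,
                       n_timepoints = n_timepoints,
                       n_communities = n_communities, snr = snr,
                       seed = seed, ...)
}

## two-pass Pearson correlation, independent of stats::cor
pearson_oracle <- function(a, b) {
  a <- a - sum(a) / length(a)
  b <- b - sum(b) / length(b)
  sum(a * b) / sqrt(sum(a * a) * sum(b * b))
}

## term-by-term signed modularity: evaluates Q+ and Q- by explicit double
## loops and combines them asymmetrically
signed_modularity_oracle <- function(W, labels, gamma = 1) {
  q_part <- function(A) {
    s <- sum(A)
    if (s == 0) return(0)
    k <- rowSums(A)
    q <- 0
    for (i in seq_len(nrow(A))) {
      for (j in seq_len(ncol(A))) {
        if (labels[i] == labels[j]) {
          q <- q + A[i, j] - gamma * k[i] * k[j] / s
        }
      }
    }
    q / s
  }
  W0 <- pmax(W, 0); W1 <- -pmin(W, 0)
  s0 <- sum(W0); s1 <- sum(W1)
  q_part(W0) - if (s1 > 0) s1 / (s0 + s1) * q_part(W1) else 0
}

## all set partitions of 1..n as a list of label vectors
all_partitions <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_partitions(n - 1L)
  out <- list()
  for (p in sub) {
    for (c in seq_len(max(p) + 1L)) {
      out[[length(out) + 1L]] <- c(p, c)
    }
  }
  out
}

## random symmetric signed weight matrix with zero diagonal
random_signed_graph <- function(n, seed) {
  set.seed(seed)
  W <- matrix(stats::runif(n * n, -1, 1), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

## build a unit-variance row with a prescribed Pearson correlation to v,
## using a noise direction orthogonal to v (after centering)
row_with_cor <- function(v, rho, noise) {
  vc <- v - mean(v)
  vc <- vc / sqrt(sum(vc^2))
  u <- noise - mean(noise)
  u <- u - sum(u * vc) * vc
  u <- u / sqrt(sum(u^2))
  rho * vc + sqrt(1 - rho^2) * u
}
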