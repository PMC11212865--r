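#' Prepare a signed graph from a similarity matrix
#'
#' Zeroes the diagonal and keeps every off-diagonal correlation — including
#' negative ones — as a signed edge weight.
#'
#' @param sim symmetric similarity matrix (e.g. from [similarity_matrix()]).
#' @param tol maximum tolerated asymmetry.
#' @return symmetric weight matrix with zero diagonal.
#' @export
prepare_graph <- function(sim, tol = 1e-10) {
  sim <- as.matrix(sim)
  if (nrow(sim) != ncol(sim) || max(abs(sim - t(sim))) > tol) {
    stop("similarity matrix must be symmetric", call. = FALSE)
  }
  W <- (sim + t(sim)) / 2
  diag(W) <- 0
  W
}

## Generalized modularity matrix B such that Q*(labels) equals the sum of
## B over all within-community (i, j) pairs. Combines the positive and
## negative subnetworks with the asymmetric weighting
## Q* = Q+ - (m- / (m+ + m-)) Q-.
## With `null_self_pairs = FALSE` the i = j pairs are dropped from the
## null-model term (the literal reading of the printed formula); the
## default keeps them, the convention of the standard signed-Louvain
## implementation, under which two equal disconnected cliques give Q = 0.5.
modularity_matrix <- function(W, gamma = 1, null_self_pairs = TRUE) {
  W <- as.matrix(W)
  W0 <- pmax(W, 0)
  W1 <- -pmin(W, 0)
  s0 <- sum(W0)
  s1 <- sum(W1)
  if (s0 + s1 == 0) {
    warning("graph has no edges; modularity defined as 0", call. = FALSE)
    return(matrix(0, nrow(W), ncol(W)))
  }
  part <- function(A, s, scale) {
    if (s == 0) return(matrix(0, nrow(A), ncol(A)))
    k <- rowSums(A)
    B <- (A - gamma * outer(k, k) / s) / scale
    if (!null_self_pairs) diag(B) <- diag(A) / scale
    B
  }
  part(W0, s0, s0) - part(W1, s1, s0 + s1)
}

#' Signed modularity of a partition
#'
#' Evaluates the quality of a community assignment on a signed weight
#' matrix: within-community weight minus a strength-based null expectation,
#' computed separately on the positive and negative subnetworks and
#' combined asymmetrically as `Q* = Q+ - (m- / (m+ + m-)) Q-`, so that
#' negative within-community weight is penalized but cannot dominate. With
#' no negative weights this reduces to ordinary Newman modularity.
#'
#' @param W symmetric signed weight matrix with zero diagonal (see
#'   [prepare_graph()]).
#' @param labels community label per node (any atomic type).
#' @param gamma resolution parameter (default 1).
#' @param null_self_pairs keep i = j pairs in the null-model term (the
#'   standard convention; see [modularity_matrix()] internals).
#' @return scalar Q*.
#' @export
signed_modularity <- function(W, labels, gamma = 1,
                              null_self_pairs = TRUE) {
  W <- as.matrix(W)
  if (length(labels) != nrow(W)) {
    stop("`labels` must cover all nodes", call. = FALSE)
  }
  B <- modularity_matrix(W, gamma, null_self_pairs)
  same <- outer(labels, labels, "==")
  sum(B[same])
}

## Q* for many two-group labelings at once. X is an n x p indicator matrix
## (1 = first group). Used by the permutation machinery; agrees with
## signed_modularity() on each column.
two_group_modularity <- function(W, X, gamma = 1, null_self_pairs = TRUE) {
  W <- as.matrix(W)
  X <- as.matrix(X)
  B <- modularity_matrix(W, gamma, null_self_pairs)
  Xc <- 1 - X
  colSums(X * (B %*% X)) + colSums(Xc * (B %*% Xc))
}

#' Louvain community detection for signed graphs (single run)
#'
#' Greedy local-move plus aggregation phases maximizing the asymmetric
#' signed modularity Q* (see [signed_modularity()]). The node visit order
#' is randomized by `seed`; the algorithm terminates when no single-node
#' move improves Q*. The returned partition is never worse than the
#' all-singletons or one-community baselines.
#'
#' @param W symmetric signed weight matrix (diagonal ignored).
#' @param gamma resolution parameter.
#' @param seed integer seed controlling the visit order.
#' @param null_self_pairs see [signed_modularity()].
#' @return object of class `tep_partition`: `labels` (canonical integer
#'   communities, numbered by decreasing size), `q` (Q* of the partition),
#'   `gamma`, `seed`.
#' @export
louvain_signed <- function(W, gamma = 1, seed = NULL,
                           null_self_pairs = TRUE) {
  W <- prepare_graph(W)
  n <- nrow(W)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  B <- modularity_matrix(W, gamma, null_self_pairs)
  B <- (B + t(B)) / 2
  labels <- with_seed(seed, genlouvain(B))
  ## guard: never report a partition below the trivial baselines
  cand <- list(labels, seq_len(n), rep(1L, n))
  qs <- vapply(cand, function(l) sum(B[outer(l, l, "==")]), numeric(1))
  best <- cand[[which.max(qs)]]
  structure(list(labels = canonicalize_labels(best, names = rownames(W)),
                 q = max(qs), gamma = gamma, seed = seed),
            class = "tep_partition")
}

#' @export
print.tep_partition <- function(x, ...) {
  cat(sprintf("tep_partition: %d nodes, %d communities, Q = %.4f%s\n",
              length(x$labels), max(x$labels),
              if (!is.null(x$q_mean)) x$q_mean else x$q,
              if (isTRUE(x$consensus)) " (consensus mean)" else ""))
  print(table(community = x$labels))
  invisible(x)
}

## One Louvain level: repeated sweeps of single-node moves on the
## modularity matrix B, visiting nodes in random order, until stable.
louvain_local_moves <- function(B) {
  nn <- nrow(B)
  ci <- seq_len(nn)
  conn <- B                     # conn[i, c] = sum_j in c of B[i, j]
  repeat {
    moved <- FALSE
    for (i in sample.int(nn)) {
      a <- ci[i]
      links <- conn[i, ]
      links[a] <- links[a] - B[i, i]   # exclude the constant self-pair
      b <- which.max(links)
      if (b != a && links[b] > links[a] + 1e-12) {
        ci[i] <- b
        conn[, a] <- conn[, a] - B[, i]
        conn[, b] <- conn[, b] + B[, i]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  ci
}

## Full generalized Louvain: local moves + community aggregation until no
## further merging is possible.
genlouvain <- function(B) {
  node_comm <- seq_len(nrow(B))
  repeat {
    ci <- louvain_local_moves(B)
    ci <- match(ci, unique(ci))
    node_comm <- ci[node_comm]
    k <- max(ci)
    if (k == nrow(B)) break     # no merges this level: converged
    S <- matrix(0, nrow(B), k)
    S[cbind(seq_len(nrow(B)), ci)] <- 1
    B <- crossprod(S, B %*% S)
    if (k == 1L) break
  }
  node_comm
}

## Renumber communities 1..k by decreasing size; ties broken by the
## smallest member index.
canonicalize_labels <- function(labels, names = NULL) {
  labels <- as.integer(factor(labels, levels = unique(labels)))
  size <- tabulate(labels)
  first <- vapply(seq_len(max(labels)), function(c) {
    which.max(labels == c)
  }, integer(1))
  ord <- order(-size, first)
  out <- match(labels, ord)
  if (!is.null(names)) names(out) <- names
  out
}
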