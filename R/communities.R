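#' Consensus community detection over repeated Louvain runs
#'
#' Runs [louvain_signed()] `n_runs` times with distinct seeds, records the
#' modularity of every run, and derives a consensus partition from the
#' co-assignment (agreement) matrix: entries below the chance agreement
#' expected under permuted run labels are zeroed, the thresholded agreement
#' matrix is re-clustered with the same number of runs, and the procedure
#' iterates until every run returns the same partition.
#'
#' @param W symmetric signed weight matrix.
#' @param n_runs number of Louvain runs (default 1000).
#' @param gamma resolution parameter.
#' @param seed base seed; run r uses `seed + r` unless `run_seeds` is given.
#' @param run_seeds optional explicit per-run seeds (length `n_runs`).
#' @param max_iter maximum consensus iterations before giving up.
#' @param null_self_pairs see [signed_modularity()].
#' @return `tep_partition` with consensus `labels`, `q_mean` and `q_runs`
#'   (mean and per-run modularity of the original runs), `consensus = TRUE`.
#' @export
consensus_communities <- function(W, n_runs = 1000L, gamma = 1, seed = 1L,
                                  run_seeds = NULL, max_iter = 20L,
                                  null_self_pairs = TRUE) {
  if (n_runs < 2L) stop("`n_runs` must be at least 2", call. = FALSE)
  W <- prepare_graph(W)
  n <- nrow(W)
  if (is.null(run_seeds)) run_seeds <- seed + seq_len(n_runs)
  if (length(run_seeds) != n_runs) {
    stop("`run_seeds` must have length `n_runs`", call. = FALSE)
  }
  run_once <- function(mat, seeds) {
    runs <- lapply(seeds, function(s) {
      louvain_signed(mat, gamma = gamma, seed = s,
                     null_self_pairs = null_self_pairs)
    })
    list(labels = vapply(runs, `[[`, integer(n), "labels"),
         q = vapply(runs, `[[`, numeric(1), "q"))
  }
  first <- run_once(W, run_seeds)
  L <- first$labels
  for (iter in seq_len(max_iter)) {
    if (all(L == L[, 1L])) {
      out <- structure(
        list(labels = canonicalize_labels(L[, 1L], names = rownames(W)),
             q_mean = mean(first$q), q_runs = first$q,
             q = mean(first$q), gamma = gamma,
             consensus = TRUE, iterations = iter - 1L),
        class = "tep_partition")
      return(out)
    }
    D <- agreement_matrix(L)
    tau <- chance_agreement(L)
    D[D < tau] <- 0
    diag(D) <- 0
    L <- run_once(D, run_seeds + iter * n_runs)$labels
  }
  stop(paste0("consensus did not converge in ", max_iter, " iterations; ",
              "agreement matrix range [",
              paste(signif(range(agreement_matrix(L)), 3), collapse = ", "),
              "]"), call. = FALSE)
}

## Fraction of runs in which each node pair is co-assigned.
agreement_matrix <- function(L) {
  n <- nrow(L)
  D <- matrix(0, n, n)
  for (r in seq_len(ncol(L))) {
    D <- D + outer(L[, r], L[, r], "==")
  }
  D / ncol(L)
}

## Mean probability that a random node pair is co-assigned when each run's
## labels are permuted — the consensus threshold.
chance_agreement <- function(L) {
  n <- nrow(L)
  mean(apply(L, 2L, function(l) {
    sz <- tabulate(l)
    sum(sz * (sz - 1)) / (n * (n - 1))
  }))
}

#' Assign validation conditions to discovery communities
#'
#' Transfers community labels from a clustered discovery set to new
#' (validation) conditions living in the same feature space, by one of two
#' rules: the label of the Euclidean nearest discovery neighbour, or the
#' most frequent community among the 5 discovery rows with the highest
#' Pearson correlation (frequency ties broken in favour of the tied
#' community with the higher mean correlation among its top-5 members).
#'
#' @param discovery_features,validation_features feature matrices with
#'   identical feature spaces (columns).
#' @param discovery_labels community label per discovery row.
#' @param method `"nearest_neighbor"` or `"top5_correlation"`.
#' @return integer labels, one per validation row, named by its row names.
#' @export
assign_validation <- function(discovery_features, discovery_labels,
                              validation_features,
                              method = c("nearest_neighbor",
                                         "top5_correlation")) {
  method <- match.arg(method)
  D <- as.matrix(discovery_features)
  V <- as.matrix(validation_features)
  if (ncol(D) != ncol(V)) {
    stop("discovery and validation feature spaces differ", call. = FALSE)
  }
  if (length(discovery_labels) != nrow(D)) {
    stop("one discovery label per discovery row required", call. = FALSE)
  }
  k <- 5L
  if (method == "top5_correlation" && nrow(D) < k) {
    warning(sprintf("only %d discovery rows; using all instead of top 5",
                    nrow(D)), call. = FALSE)
    k <- nrow(D)
  }
  out <- vapply(seq_len(nrow(V)), function(i) {
    if (method == "nearest_neighbor") {
      d2 <- rowSums(sweep(D, 2L, V[i, ])^2)
      discovery_labels[which.min(d2)]
    } else {
      r <- as.vector(stats::cor(t(D), V[i, ]))
      top <- order(r, decreasing = TRUE)[seq_len(k)]
      lab <- discovery_labels[top]
      freq <- table(lab)
      cand <- names(freq)[freq == max(freq)]
      if (length(cand) > 1L) {
        meanr <- vapply(cand, function(cc) mean(r[top][lab == cc]),
                        numeric(1))
        cand <- cand[order(-meanr, cand)][1L]
      }
      discovery_labels[match(cand, as.character(discovery_labels))]
    }
  }, discovery_labels[1])
  names(out) <- rownames(V)
  out
}

#' Coil-orientation sensitivity by community agreement
#'
#' A stimulation site whose paired N45 and P45 conditions fall in the same
#' community has low coil-orientation sensitivity (COS); paired conditions
#' in different communities mean high COS.
#'
#' @param labels community label per condition, named by condition id (or
#'   a plain vector indexed by the pair columns).
#' @param pairs data frame from [orientation_pairs()] (columns `site`,
#'   `n45`, `p45`) or a two-column matrix of condition ids/indices.
#' @return list with `per_site` (data frame: site, community of each
#'   orientation, cos = "low"/"high"), `pct_low`, `pct_high`.
#' @export
cos_agreement <- function(labels, pairs) {
  pairs <- as.data.frame(pairs)
  if (!all(c("n45", "p45") %in% names(pairs))) {
    names(pairs)[1:2] <- c("n45", "p45")
  }
  if (!"site" %in% names(pairs)) pairs$site <- seq_len(nrow(pairs))
  idx <- function(ids) {
    if (is.character(ids) || !is.null(names(labels))) {
      match(as.character(ids), names(labels))
    } else as.integer(ids)
  }
  i1 <- idx(pairs$n45)
  i2 <- idx(pairs$p45)
  ok <- !is.na(i1) & !is.na(i2)
  if (any(!ok)) {
    warning(sprintf("excluding %d site(s) with unlabelled members",
                    sum(!ok)), call. = FALSE)
  }
  l1 <- labels[i1[ok]]
  l2 <- labels[i2[ok]]
  agree <- l1 == l2
  list(per_site = data.frame(site = pairs$site[ok],
                             n45_community = l1,
                             p45_community = l2,
                             cos = ifelse(agree, "low", "high"),
                             stringsAsFactors = FALSE),
       pct_low = 100 * mean(agree),
       pct_high = 100 * mean(!agree))
}

#' Community-average TEP
#'
#' Averages the (absolute or signed) channel TEPs across all conditions of
#' each community, the summary used to characterize what each response
#' community looks like in time and space.
#'
#' @param tep a `tep_dataset`.
#' @param labels community label per condition.
#' @param mode `"abs"` (rectified, the default presentation) or `"signed"`.
#' @return communities x channels x timepoints array.
#' @export
community_average_tep <- function(tep, labels, mode = c("abs", "signed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tep, "tep_dataset"))
  if (length(labels) != dim(tep$voltages)[1]) {
    stop("`labels` must align with conditions", call. = FALSE)
  }
  comms <- sort(unique(labels))
  v <- if (mode == "abs") abs(tep$voltages) else tep$voltages
  out <- array(0, dim = c(length(comms), dim(v)[2], dim(v)[3]),
               dimnames = list(as.character(comms),
                               dimnames(v)[[2]], NULL))
  for (ci in seq_along(comms)) {
    rows <- which(labels == comms[ci])
    if (!length(rows)) stop("empty community", call. = FALSE)
    out[ci, , ] <- apply(v[rows, , , drop = FALSE], c(2, 3), mean)
  }
  out
}

#' Per-condition community time series from a channel partition
#'
#' Given a community label per recording channel, summarizes every
#' condition's TEP with one mean signed-voltage trace per channel
#' community.
#'
#' @param tep a `tep_dataset`.
#' @param channel_labels community label per channel.
#' @return conditions x communities x timepoints array.
#' @export
channel_community_timeseries <- function(tep, channel_labels) {
  stopifnot(inherits(tep, "tep_dataset"))
  if (length(channel_labels) != dim(tep$voltages)[2]) {
    stop("`channel_labels` must cover every channel", call. = FALSE)
  }
  comms <- sort(unique(channel_labels))
  out <- array(0, dim = c(dim(tep$voltages)[1], length(comms),
                          dim(tep$voltages)[3]),
               dimnames = list(dimnames(tep$voltages)[[1]],
                               as.character(comms), NULL))
  for (ci in seq_along(comms)) {
    cols <- which(channel_labels == comms[ci])
    if (!length(cols)) stop("empty channel community", call. = FALSE)
    out[, ci, ] <- apply(tep$voltages[, cols, , drop = FALSE], c(1, 3),
                         mean)
  }
  out
}
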