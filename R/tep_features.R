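#' Extract a time window from a TEP dataset
#'
#' Keeps samples with `t_start <= t <= t_end` (both endpoints inclusive, the
#' convention that makes a 20–500 ms window at 1 kHz contain exactly 481
#' samples).
#'
#' @param tep a `tep_dataset`.
#' @param t_start,t_end window limits in ms.
#' @return the `tep_dataset` restricted to the window.
#' @export
extract_window <- function(tep, t_start = 20, t_end = 500) {
  stopifnot(inherits(tep, "tep_dataset"))
  if (t_end < t_start) stop("`t_end` must be >= `t_start`", call. = FALSE)
  if (t_start < min(tep$time) || t_end > max(tep$time)) {
    stop(sprintf("window [%g, %g] ms outside the recorded axis [%g, %g] ms",
                 t_start, t_end, min(tep$time), max(tep$time)),
         call. = FALSE)
  }
  keep <- tep$time >= t_start & tep$time <= t_end
  tep$voltages <- tep$voltages[, , keep, drop = FALSE]
  tep$time <- tep$time[keep]
  tep
}

#' Subset the conditions of a TEP dataset
#'
#' @param tep a `tep_dataset`.
#' @param idx condition indices, condition ids, or a logical mask; or one
#'   of `"discovery"` / `"validation"` to select by set membership.
#' @return the `tep_dataset` restricted to those conditions.
#' @export
subset_conditions <- function(tep, idx) {
  stopifnot(inherits(tep, "tep_dataset"))
  if (is.character(idx) && length(idx) == 1L &&
      idx %in% c("discovery", "validation")) {
    idx <- which(tep$conditions$set == idx)
  } else if (is.character(idx)) {
    idx <- match(idx, tep$conditions$condition_id)
    if (anyNA(idx)) stop("unknown condition id", call. = FALSE)
  } else if (is.logical(idx)) {
    idx <- which(idx)
  }
  tep$voltages <- tep$voltages[idx, , , drop = FALSE]
  tep$conditions <- tep$conditions[idx, , drop = FALSE]
  if (!is.null(tep$truth_labels)) tep$truth_labels <- tep$truth_labels[idx]
  tep
}

#' Channel-by-channel TEP connectivity for one stimulation condition
#'
#' Pearson-correlates the channel TEP timeseries of one condition with each
#' other, giving the channels x channels connectivity matrix that the
#' community analyses are built from.
#'
#' @param x channels x timepoints numeric matrix (one condition's TEP).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
channel_connectivity <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 timepoints", call. = FALSE)
  v <- apply(x, 1L, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    nm <- if (!is.null(rownames(x))) rownames(x)[bad] else bad
    stop(sprintf("zero-variance channel(s): %s",
                 paste(nm, collapse = ", ")), call. = FALSE)
  }
  r <- stats::cor(t(x))
  diag(r) <- 1
  r
}

#' Stimulation-perspective feature matrix
#'
#' For every stimulation condition, computes (or accepts) the channels x
#' channels TEP connectivity matrix and flattens it row-major into one
#' feature row, retaining the diagonal and both triangles, so 95 channels
#' give 9025 features per condition.
#'
#' @param x a `tep_dataset` (connectivity computed per condition) or a list
#'   of equally sized square connectivity matrices with matching dimnames.
#' @return conditions x channels^2 numeric matrix with condition row names.
#' @export
stimulation_feature_matrix <- function(x) {
  mats <- if (inherits(x, "tep_dataset")) {
    n <- dim(x$voltages)[1]
    stats::setNames(lapply(seq_len(n), function(i) {
      channel_connectivity(x$voltages[i, , ])
    }), dimnames(x$voltages)[[1]])
  } else if (is.list(x)) x else {
    stop("`x` must be a tep_dataset or a list of connectivity matrices",
         call. = FALSE)
  }
  d <- dim(mats[[1]])
  dn <- rownames(mats[[1]])
  for (m in mats) {
    if (!identical(dim(m), d) || !identical(rownames(m), dn)) {
      stop("all connectivity matrices must share the channel set and order",
           call. = FALSE)
    }
  }
  out <- t(vapply(mats, function(m) as.vector(t(m)),
                  numeric(prod(d))))
  rownames(out) <- names(mats)
  attr(out, "perspective") <- "stimulation"
  attr(out, "n_channels") <- d[1]
  out
}

#' Reshape one stimulation feature row back into a connectivity matrix
#'
#' @param row one row of a stimulation-perspective feature matrix.
#' @return the channels x channels connectivity matrix.
#' @export
unflatten_connectivity <- function(row) {
  n <- sqrt(length(row))
  if (n != round(n)) stop("feature length is not a perfect square",
                          call. = FALSE)
  ## inverse of the row-major flattening
  t(matrix(row, n, n))
}

#' Recording-channel-perspective feature matrix
#'
#' For every channel, the conditions x timepoints matrix is correlated
#' across timepoints into a conditions x conditions similarity matrix and
#' flattened row-major, so 143 conditions give 20449 features per channel
#' and 42 conditions give 1764.
#'
#' @param tep a `tep_dataset` with at least 2 conditions.
#' @return channels x conditions^2 matrix with channel row names.
#' @export
channel_feature_matrix <- function(tep) {
  stopifnot(inherits(tep, "tep_dataset"))
  n_cond <- dim(tep$voltages)[1]
  if (n_cond < 2L) stop("need at least 2 conditions", call. = FALSE)
  n_chan <- dim(tep$voltages)[2]
  out <- t(vapply(seq_len(n_chan), function(j) {
    as.vector(t(channel_connectivity(tep$voltages[, j, ])))
  }, numeric(n_cond^2)))
  rownames(out) <- dimnames(tep$voltages)[[2]]
  attr(out, "perspective") <- "channel"
  out
}

#' Node-by-node similarity matrix from feature rows
#'
#' Pearson-correlates every pair of feature rows. The result is the signed
#' edge-weight matrix consumed by the modularity analyses.
#'
#' @param features rows x features numeric matrix (from
#'   [stimulation_feature_matrix()] or [channel_feature_matrix()]).
#' @return symmetric n x n correlation matrix with unit diagonal, row/col
#'   names taken from `features`.
#' @export
similarity_matrix <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 rows", call. = FALSE)
  v <- apply(features, 1L, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    nm <- if (!is.null(rownames(features))) rownames(features)[bad] else bad
    stop(sprintf("constant feature row(s): %s",
                 paste(nm, collapse = ", ")), call. = FALSE)
  }
  r <- stats::cor(t(features))
  diag(r) <- 1
  r
}

#' Coil-orientation dissimilarity per stimulation site
#'
#' Computes `1 - Pearson r` between the flattened TEP-connectivity feature
#' rows of the two coil orientations of each site — a continuous measure of
#' coil-orientation sensitivity in \[0, 2\].
#'
#' @param features stimulation-perspective feature matrix with condition
#'   row names.
#' @param pairs two-column data frame or matrix of (N45 row id, P45 row id)
#'   per site; row names (or a `site` column) identify the sites.
#' @return named numeric vector, one dissimilarity per paired site; sites
#'   with a missing member are skipped with a warning.
#' @export
orientation_dissimilarity <- function(features, pairs) {
  pairs <- as.data.frame(pairs)
  if (!all(c("n45", "p45") %in% names(pairs))) {
    idc <- setdiff(names(pairs), "site")[1:2]
    names(pairs)[match(idc, names(pairs))] <- c("n45", "p45")
  }
  sites <- if ("site" %in% names(pairs)) pairs$site else
    paste(pairs$n45, pairs$p45, sep = "|")
  id1 <- as.character(pairs$n45)
  id2 <- as.character(pairs$p45)
  present <- id1 %in% rownames(features) & id2 %in% rownames(features)
  if (any(!present)) {
    warning(sprintf("skipping %d site(s) with unpaired conditions: %s",
                    sum(!present),
                    paste(sites[!present], collapse = ", ")),
            call. = FALSE)
  }
  out <- vapply(which(present), function(i) {
    1 - stats::cor(features[id1[i], ], features[id2[i], ])
  }, numeric(1))
  stats::setNames(out, sites[present])
}

#' Pair the two coil orientations of every site
#'
#' @param conditions condition metadata (data frame with `condition_id`,
#'   `site_label`, `orientation`) or a `tep_dataset`.
#' @return data frame with columns `site`, `n45`, `p45`, one row per site
#'   that has both orientations.
#' @export
orientation_pairs <- function(conditions) {
  if (inherits(conditions, "tep_dataset")) conditions <- conditions$conditions
  n45 <- conditions[conditions$orientation == "N45", ]
  p45 <- conditions[conditions$orientation == "P45", ]
  common <- intersect(n45$site_label, p45$site_label)
  data.frame(site = common,
             n45 = n45$condition_id[match(common, n45$site_label)],
             p45 = p45$condition_id[match(common, p45$site_label)],
             stringsAsFactors = FALSE)
}

#' Regress a per-condition covariate out of the TEP timeseries
#'
#' For every (channel, timepoint) cell, the values across conditions are
#' replaced by the residuals of an ordinary least-squares fit on
#' (intercept, covariate). Used to remove the somatosensory-discomfort
#' (SUDS) confound before building connectivity features.
#'
#' @param tep a `tep_dataset` with at least 3 conditions.
#' @param covariate numeric vector, one value per condition (defaults to
#'   the dataset's SUDS column).
#' @return the `tep_dataset` with residualized voltages.
#' @export
regress_out_covariate <- function(tep, covariate = tep$conditions$suds) {
  stopifnot(inherits(tep, "tep_dataset"))
  n_cond <- dim(tep$voltages)[1]
  if (length(covariate) != n_cond) {
    stop("need exactly one covariate value per condition", call. = FALSE)
  }
  if (n_cond < 3L) stop("need at least 3 conditions", call. = FALSE)
  m <- matrix(tep$voltages, nrow = n_cond)   # conditions x (channel*time)
  tep$voltages[] <- array(residualize(m, covariate), dim = dim(tep$voltages))
  tep
}

## OLS residuals of each column of `m` on (intercept, covariate).
## A constant covariate degenerates to mean-centering (with a warning).
residualize <- function(m, covariate) {
  m <- as.matrix(m)
  if (stats::var(covariate) == 0) {
    warning("constant covariate: residuals are mean-centered values",
            call. = FALSE)
    return(sweep(m, 2L, colMeans(m)))
  }
  X <- cbind(1, covariate)
  m - X %*% solve(crossprod(X), crossprod(X, m))
}
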