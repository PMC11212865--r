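#' Kruskal-Wallis omnibus test across communities
#'
#' Thin wrapper around [stats::kruskal.test()] (rank-based H with tie
#' correction, chi-square reference with k - 1 degrees of freedom) that
#' defines the degenerate all-values-identical case as H = 0, p = 1.
#'
#' @param groups list of numeric vectors, one per community (>= 2 groups
#'   of >= 2 values each).
#' @return list with `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    stop("need at least 2 groups with at least 2 values each",
         call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    return(list(H = 0, p = 1))
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Pairwise rank comparisons with Tukey-style family correction
#'
#' Post-hoc comparisons after a significant Kruskal-Wallis omnibus. The
#' default realizes the usual software behaviour behind "rank-sum test with
#' Tukey correction": communities are compared on their mean joint ranks
#' (with tie correction) and the standardized differences are referred to
#' the studentized-range distribution for the k-group family
#' (Tukey-Kramer, via [stats::ptukey()]). `method = "ranksum_holm"` is the
#' plain alternative: per-pair two-sided Wilcoxon rank-sum tests
#' (normal approximation with tie correction) with Holm adjustment.
#'
#' @param groups list of numeric vectors, one per community.
#' @param method `"tukey"` (mean-rank / studentized-range) or
#'   `"ranksum_holm"`.
#' @return symmetric matrix of corrected two-sided p-values (diagonal NA).
#' @export
pairwise_ranksum_tukey <- function(groups,
                                   method = c("tukey", "ranksum_holm")) {
  method <- match.arg(method)
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  nm <- if (!is.null(names(groups))) names(groups) else
    as.character(seq_len(k))
  P <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  if (method == "tukey") {
    values <- unlist(groups, use.names = FALSE)
    g <- rep(seq_len(k), lengths(groups))
    rk <- rank(values)
    N <- length(values)
    mean_rank <- tapply(rk, g, mean)
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
    s2 <- N * (N + 1) / 12 - tie_term
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        se <- sqrt(s2 * (1 / lengths(groups)[i] + 1 / lengths(groups)[j]))
        p <- if (se == 0) 1 else {
          q <- abs(mean_rank[i] - mean_rank[j]) / se * sqrt(2)
          stats::ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
        }
        P[i, j] <- P[j, i] <- p
      }
    }
  } else {
    raw <- list()
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        w <- suppressWarnings(
          stats::wilcox.test(groups[[i]], groups[[j]], exact = FALSE))
        raw[[paste(i, j)]] <- c(i, j, w$p.value)
      }
    }
    praw <- vapply(raw, `[`, numeric(1), 3L)
    padj <- stats::p.adjust(ifelse(is.nan(praw), 1, praw), method = "holm")
    for (s in seq_along(raw)) {
      i <- raw[[s]][1]; j <- raw[[s]][2]
      P[i, j] <- P[j, i] <- padj[s]
    }
  }
  P
}

#' Compare measures across response communities with a covariate removed
#'
#' For every measure: the per-condition values are residualized on the
#' covariate (ordinary least squares with intercept — the subjective
#' distress confound in the motivating design), compared across communities
#' with the Kruskal-Wallis test, and, only when the omnibus is significant
#' at `alpha`, followed up with pairwise rank comparisons under the chosen
#' family correction.
#'
#' @param metrics data frame in long format (columns `condition_id`,
#'   `measure` — or `modality` + `measure`, which are pasted —, `value`)
#'   or a conditions x measures numeric matrix.
#' @param labels community label per condition (named by condition id for
#'   the long format).
#' @param covariate per-condition covariate (same alignment as `labels`);
#'   `NULL` skips residualization.
#' @param alpha omnibus gate for the pairwise stage.
#' @param method pairwise correction, see [pairwise_ranksum_tukey()].
#' @return data frame with one row per measure (`measure`, `H`,
#'   `p_omnibus`, `n_significant_pairs`) carrying the per-measure pairwise
#'   p-value matrices as attribute `pairwise`.
#' @export
compare_across_communities <- function(metrics, labels, covariate = NULL,
                                       alpha = 0.05,
                                       method = c("tukey", "ranksum_holm")) {
  method <- match.arg(method)
  M <- metrics_to_matrix(metrics, labels)
  labels <- M$labels
  values <- M$values
  if (!is.null(covariate)) {
    if (length(covariate) != nrow(values)) {
      stop("`covariate` must align with conditions", call. = FALSE)
    }
    keep <- stats::complete.cases(values) & !is.na(covariate)
    if (any(!keep)) {
      message(sprintf("dropping %d condition(s) with missing values",
                      sum(!keep)))
      values <- values[keep, , drop = FALSE]
      labels <- labels[keep]
      covariate <- covariate[keep]
    }
    values <- residualize(values, covariate)
  }
  pairwise <- list()
  rows <- lapply(colnames(values), function(ms) {
    groups <- split(values[, ms], labels)
    kw <- kruskal_wallis(groups)
    n_sig <- 0L
    if (kw$p < alpha) {
      P <- pairwise_ranksum_tukey(groups, method = method)
      pairwise[[ms]] <<- P
      n_sig <- sum(P[upper.tri(P)] < alpha)
    }
    data.frame(measure = ms, H = kw$H, p_omnibus = kw$p,
               n_significant_pairs = n_sig, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "pairwise") <- pairwise
  out
}

## Accepts the long table produced by stack_degree_metrics() or a plain
## conditions x measures matrix; returns aligned values and labels.
metrics_to_matrix <- function(metrics, labels) {
  if (is.data.frame(metrics) && "value" %in% names(metrics)) {
    ms <- if ("modality" %in% names(metrics)) {
      paste(metrics$modality, metrics$measure, sep = ".")
    } else metrics$measure
    ids <- unique(metrics$condition_id)
    cols <- unique(ms)
    values <- matrix(NA_real_, length(ids), length(cols),
                     dimnames = list(ids, cols))
    values[cbind(match(metrics$condition_id, ids), match(ms, cols))] <-
      metrics$value
    lab <- if (!is.null(names(labels))) labels[ids] else labels
    if (length(lab) != length(ids) || anyNA(lab)) {
      stop("`labels` must provide a community for every condition",
           call. = FALSE)
    }
    list(values = values, labels = lab)
  } else {
    values <- as.matrix(metrics)
    if (is.null(colnames(values))) {
      colnames(values) <- paste0("measure", seq_len(ncol(values)))
    }
    if (length(labels) != nrow(values)) {
      stop("`labels` must align with rows of `metrics`", call. = FALSE)
    }
    list(values = values, labels = labels)
  }
}
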