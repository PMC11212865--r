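test_that("Kruskal-Wallis H matches a hand-ranked oracle", {
  ## widely separated groups, no ties: H from the textbook rank formula
  groups <- list(c(1, 2, 3), c(101, 102, 103), c(201, 202, 203))
  N <- 9
  rank_sums <- c(sum(1:3), sum(4:6), sum(7:9))
  H_hand <- 12 / (N * (N + 1)) * sum(rank_sums^2 / 3) - 3 * (N + 1)
  res <- kruskal_wallis(groups)
  expect_equal(res$H, H_hand, tolerance = 1e-10)

  ## identical groups: defined degenerate case
  same <- list(rep(2, 4), rep(2, 5))
  expect_equal(kruskal_wallis(same), list(H = 0, p = 1))

  ## random data with ties: independent rank implementation with tie term
  set.seed(13)
  g <- list(round(rnorm(8), 1), round(rnorm(10), 1), round(rnorm(7), 1))
  values <- unlist(g)
  rk <- rank(values)
  n <- lengths(g)
  idx <- rep(seq_along(g), n)
  Ntot <- length(values)
  H_raw <- 12 / (Ntot * (Ntot + 1)) *
    sum(tapply(rk, idx, sum)^2 / n) - 3 * (Ntot + 1)
  ties <- table(values)
  H_tie <- H_raw / (1 - sum(ties^3 - ties) / (Ntot^3 - Ntot))
  expect_equal(kruskal_wallis(g)$H, H_tie, tolerance = 1e-10)

  ## invariance under a strictly monotone transform
  g_exp <- lapply(g, function(v) exp(v))
  expect_equal(kruskal_wallis(g_exp)$H, kruskal_wallis(g)$H,
               tolerance = 1e-10)

  expect_error(kruskal_wallis(list(1:3)), "at least 2 groups")
})

test_that("pairwise rank comparisons detect the shifted group only", {
  set.seed(2)
  base <- rnorm(20)
  groups <- list(a = base, b = rnorm(20), c = rnorm(20) + 100)
  for (method in c("tukey", "ranksum_holm")) {
    P <- pairwise_ranksum_tukey(groups, method = method)
    expect_true(isSymmetric(P))
    expect_lt(P["a", "c"], 0.05)
    expect_lt(P["b", "c"], 0.05)
    expect_gt(P["a", "b"], 0.05)
  }

  same <- list(rep(3, 5), rep(3, 6))
  expect_equal(unique(as.vector(pairwise_ranksum_tukey(same)[1, 2])), 1)
})

test_that("family correction never reduces a pairwise p-value", {
  set.seed(15)
  groups <- list(rnorm(12), rnorm(12, 0.5), rnorm(12, 1))
  ## tukey route vs the same mean-rank z referred to a plain normal
  P <- pairwise_ranksum_tukey(groups, method = "tukey")
  values <- unlist(groups)
  rk <- rank(values)
  idx <- rep(1:3, each = 12)
  mr <- tapply(rk, idx, mean)
  N <- length(values)
  s2 <- N * (N + 1) / 12
  for (i in 1:2) for (j in (i + 1):3) {
    z <- abs(mr[i] - mr[j]) / sqrt(s2 * (2 / 12))
    expect_gte(P[i, j], 2 * stats::pnorm(-z) - 1e-12)
  }
  ## holm route vs raw rank-sum p-values
  Ph <- pairwise_ranksum_tukey(groups, method = "ranksum_holm")
  for (i in 1:2) for (j in (i + 1):3) {
    raw <- suppressWarnings(
      stats::wilcox.test(groups[[i]], groups[[j]], exact = FALSE))$p.value
    expect_gte(Ph[i, j], raw - 1e-12)
  }
})

test_that("covariate orthogonal to the measures leaves the tests unchanged", {
  set.seed(16)
  values <- matrix(rnorm(60 * 2), 60, 2,
                   dimnames = list(NULL, c("m1", "m2")))
  labels <- rep(1:3, each = 20)
  ## construct a covariate orthogonal to the intercept and both measures
  raw <- rnorm(60)
  X <- cbind(1, values)
  cov_orth <- as.vector(raw - X %*% solve(crossprod(X), crossprod(X, raw)))
  with_cov <- compare_across_communities(values, labels, cov_orth)
  without <- compare_across_communities(values, labels, NULL)
  expect_equal(with_cov$H, without$H, tolerance = 1e-10)
  expect_equal(with_cov$p_omnibus, without$p_omnibus, tolerance = 1e-10)
})

test_that("a planted community effect is detected through the full chain", {
  detected <- 0L
  for (s in 1:10) {
    truth <- rep(1:3, each = 20)
    stack <- simulate_connectome_stack(
      60, n_parcels = 30, truth_labels = truth, seed = 1600 + s,
      community_effects = list("2" = c(tracts = 3)))
    metrics <- stack_degree_metrics(stack)
    tab <- metrics[metrics$modality == "tracts" &
                     metrics$measure == "global", ]
    set.seed(1700 + s)
    suds <- runif(60, 0, 100)
    res <- compare_across_communities(
      matrix(tab$value, dimnames = list(NULL, "tracts.global")),
      truth, suds)
    if (res$p_omnibus < 0.05) detected <- detected + 1L
  }
  expect_gte(detected, 9L)
})

test_that("gatekeeping only runs pairwise tests after a significant omnibus", {
  set.seed(18)
  values <- matrix(c(rnorm(30), rnorm(30, 8)), 30, 2,
                   dimnames = list(NULL, c("null_m", "effect_m")))
  values[, 2] <- c(rnorm(10), rnorm(10, 5), rnorm(10, 10))
  labels <- rep(1:3, each = 10)
  res <- compare_across_communities(values, labels)
  pw <- attr(res, "pairwise")
  expect_false("null_m" %in% names(pw))
  expect_true("effect_m" %in% names(pw))
  expect_gt(res$n_significant_pairs[res$measure == "effect_m"], 0)
})
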