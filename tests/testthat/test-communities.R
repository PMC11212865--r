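test_that("consensus on unambiguous structure is exact with q_mean 0.5", {
  W <- matrix(0, 10, 10)
  W[1:5, 1:5] <- 1
  W[6:10, 6:10] <- 1
  diag(W) <- 0
  cons <- consensus_communities(W, n_runs = 10, seed = 4)
  expect_equal(unname(cons$labels), rep(c(1, 2), each = 5))
  expect_equal(cons$q_mean, 0.5, tolerance = 1e-12)
  expect_length(cons$q_runs, 10)
  expect_true(cons$consensus)
})

test_that("degenerate consensus with identical run seeds returns that run", {
  W <- random_signed_graph(8, seed = 77)
  single <- louvain_signed(W, seed = 123)
  cons <- consensus_communities(W, n_runs = 2, run_seeds = c(123, 123))
  expect_equal(unname(cons$labels), unname(single$labels))
  expect_equal(cons$q_mean, single$q, tolerance = 1e-12)
})

test_that("consensus recovers planted structure at least as well as single runs", {
  skip_if_not_installed("mclust")
  aris_single <- numeric(5)
  aris_cons <- numeric(5)
  for (s in 1:5) {
    tep <- simulate_tep_dataset(n_sites = 24, n_channels = 30,
                                n_timepoints = 150, n_communities = 3,
                                snr = 5, seed = 500 + s)
    S <- similarity_matrix(stimulation_feature_matrix(tep))
    runs <- vapply(1:11, function(r) {
      mclust::adjustedRandIndex(
        louvain_signed(S, seed = 1000 * s + r)$labels, tep$truth_labels)
    }, numeric(1))
    aris_single[s] <- stats::median(runs)
    cons <- consensus_communities(S, n_runs = 20, seed = 1000 * s)
    aris_cons[s] <- mclust::adjustedRandIndex(cons$labels,
                                              tep$truth_labels)
  }
  expect_true(all(aris_cons >= aris_single - 1e-12))
})

test_that("validation assignment follows the nearest-neighbour and top-5 rules", {
  set.seed(42)
  D <- matrix(rnorm(8 * 30), 8, 30)
  lab <- c(1, 1, 1, 2, 2, 2, 3, 3)
  ## a validation row identical to a discovery row inherits its label
  V <- D[c(4, 7), ]
  expect_equal(unname(assign_validation(D, lab, V, "nearest_neighbor")),
               c(2, 3))

  ## controlled top-5: correlations to v rank rows with labels 1,1,2,2,2
  v <- rnorm(40)
  noise <- matrix(rnorm(8 * 40), 8, 40)
  rho <- c(0.9, 0.85, 0.8, 0.75, 0.7, 0.1, 0.05, 0.0)
  D2 <- t(vapply(1:8, function(i) row_with_cor(v, rho[i], noise[i, ]),
                 numeric(40)))
  lab2 <- c(1, 1, 2, 2, 2, 3, 3, 3)
  expect_equal(unname(assign_validation(D2, lab2, rbind(v),
                                        "top5_correlation")), 2)

  ## frequency tie (1,1,2,2,3): higher mean correlation wins
  lab3 <- c(1, 1, 2, 2, 3, 3, 3, 3)   # top5 labels: 1,1,2,2,3
  ## community 1 holds the two highest correlations -> mean corr higher
  expect_equal(unname(assign_validation(D2, lab3, rbind(v),
                                        "top5_correlation")), 1)
  ## flip the ranking so community 2 members correlate highest
  rho_flip <- c(0.7, 0.75, 0.9, 0.85, 0.8, 0.1, 0.05, 0.0)
  D3 <- t(vapply(1:8, function(i) row_with_cor(v, rho_flip[i],
                                               noise[i, ]), numeric(40)))
  expect_equal(unname(assign_validation(D3, lab3, rbind(v),
                                        "top5_correlation")), 2)

  expect_warning(
    assign_validation(D[1:3, ], lab[1:3], rbind(v[1:30]),
                      "top5_correlation"),
    "using all")
  expect_error(assign_validation(D, lab, matrix(0, 1, 5)), "differ")
})

test_that("community agreement classifies coil-orientation sensitivity", {
  labels <- c(a_N = 1, a_P = 1, b_N = 2, b_P = 3, c_N = 2, c_P = 2)
  pairs <- data.frame(site = c("a", "b", "c"),
                      n45 = c("a_N", "b_N", "c_N"),
                      p45 = c("a_P", "b_P", "c_P"))
  res <- cos_agreement(labels, pairs)
  expect_equal(res$per_site$cos, c("low", "high", "low"))
  expect_equal(res$pct_low, 100 * 2 / 3)
  expect_equal(res$pct_high, 100 / 3)

  all_same <- cos_agreement(rep(1, 6), cbind(1:3, 4:6))
  expect_equal(all_same$pct_low, 100)

  expect_warning(
    res2 <- cos_agreement(labels, rbind(pairs,
                                        data.frame(site = "d",
                                                   n45 = "d_N",
                                                   p45 = "d_P"))),
    "excluding 1")
  expect_equal(nrow(res2$per_site), 3)
})

test_that("community TEP averages rectify or cancel as requested", {
  tep <- small_tep(seed = 9, n_sites = 3, n_channels = 5,
                   n_timepoints = 40)
  v <- tep$voltages
  ## opposite-sign conditions cancel signed but not rectified
  tep$voltages[2, , ] <- -tep$voltages[1, , ]
  labs <- c(1, 1, 2, 2, 2, 2)
  avg_signed <- community_average_tep(tep, labs, mode = "signed")
  expect_equal(max(abs(avg_signed[1, , ])), 0, tolerance = 1e-12)
  avg_abs <- community_average_tep(tep, labs, mode = "abs")
  expect_equal(avg_abs[1, , ], abs(tep$voltages[1, , ]),
               tolerance = 1e-12)

  ## single-condition community and a direct mean oracle
  labs2 <- c(1, rep(2, 5))
  a <- community_average_tep(tep, labs2, mode = "abs")
  expect_equal(a[1, , ], abs(tep$voltages[1, , ]), tolerance = 1e-12)
  expect_equal(a[2, , ],
               apply(abs(tep$voltages[2:6, , ]), c(2, 3), mean),
               tolerance = 1e-12)
  expect_error(community_average_tep(tep, labs[1:3]), "align")
})

test_that("channel community time series are per-community channel means", {
  tep <- small_tep(seed = 10, n_sites = 3, n_channels = 6,
                   n_timepoints = 30)
  ## all channels in one community: global mean trace per condition
  ts1 <- channel_community_timeseries(tep, rep(1, 6))
  expect_equal(ts1[3, 1, ], colMeans(tep$voltages[3, , ]),
               tolerance = 1e-12)

  ## two opposite channels in one community give a zero trace
  tep$voltages[, 2, ] <- -tep$voltages[, 1, ]
  ts2 <- channel_community_timeseries(tep, c(1, 1, 2, 2, 2, 2))
  expect_equal(max(abs(ts2[, 1, ])), 0, tolerance = 1e-12)

  ts3 <- channel_community_timeseries(tep, c(1, 2, 2, 3, 3, 3))
  expect_equal(ts3[2, 3, ],
               colMeans(tep$voltages[2, 4:6, ]), tolerance = 1e-12)
  expect_error(channel_community_timeseries(tep, 1:3), "every channel")
})
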