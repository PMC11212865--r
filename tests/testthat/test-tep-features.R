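test_that("window extraction uses inclusive endpoints", {
  tep <- small_tep(seed = 1, n_timepoints = 120)  # 20..139 ms at 1 kHz
  expect_equal(dim(extract_window(tep, 30, 30)$voltages)[3], 1)
  expect_equal(dim(extract_window(tep, 20, 21)$voltages)[3], 2)
  expect_equal(dim(extract_window(tep, 20, 139)$voltages)[3], 120)
  expect_error(extract_window(tep, 20, 500), "outside")
})

test_that("channel connectivity matches a brute-force Pearson oracle", {
  x <- matrix(rep(seq_len(50), 4), nrow = 4, byrow = TRUE)
  expect_equal(channel_connectivity(x), matrix(1, 4, 4))

  y <- rbind(sin(1:40), -sin(1:40))
  expect_equal(channel_connectivity(y)[1, 2], -1)

  set.seed(11)
  z <- matrix(rnorm(5 * 50), 5, 50)
  got <- channel_connectivity(z)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(got[i, j], pearson_oracle(z[i, ], z[j, ]),
                 tolerance = 1e-12)
  }
  expect_true(isSymmetric(got))
  expect_equal(diag(got), rep(1, 5), tolerance = 1e-12)

  flat <- rbind(rnorm(30), rep(2, 30), rnorm(30))
  rownames(flat) <- c("a", "bad", "c")
  expect_error(channel_connectivity(flat), "bad")
})

test_that("stimulation features flatten full matrices and round-trip", {
  tep <- small_tep(seed = 2, n_sites = 3, n_channels = 2)
  f <- stimulation_feature_matrix(tep)
  expect_equal(dim(f), c(6, 4))
  r <- channel_connectivity(tep$voltages[1, , ])[1, 2]
  expect_equal(unname(f[1, ]), c(1, r, r, 1), tolerance = 1e-12)

  m <- channel_connectivity(tep$voltages[3, , ])
  expect_equal(unflatten_connectivity(f[3, ]), unname(m),
               ignore_attr = TRUE, tolerance = 1e-12)

  a <- matrix(rnorm(9), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  b <- matrix(rnorm(16), 4, 4)
  expect_error(stimulation_feature_matrix(list(a, b)), "channel set")
})

test_that("channel features have conditions-squared columns", {
  tep <- small_tep(seed = 3, n_sites = 4, n_channels = 6)
  f <- channel_feature_matrix(tep)
  expect_equal(dim(f), c(6, 64))

  ## identical data across channels: every correlation is 1
  tep2 <- small_tep(seed = 4, n_sites = 1, n_channels = 3, snr = Inf,
                    n_communities = 1)
  for (ch in 2:3) tep2$voltages[, ch, ] <- tep2$voltages[, 1, ]
  f2 <- channel_feature_matrix(tep2)
  expect_equal(unname(f2), matrix(1, 3, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("row similarity equals pairwise Pearson and flags constant rows", {
  set.seed(21)
  f <- matrix(rnorm(6 * 20), 6, 20)
  S <- similarity_matrix(f)
  for (i in 1:6) for (j in 1:6) {
    expect_equal(S[i, j], pearson_oracle(f[i, ], f[j, ]),
                 tolerance = 1e-12)
  }
  dup <- rbind(f, f[1, ])
  expect_equal(similarity_matrix(dup)[1, 7], 1, tolerance = 1e-12)
  anti <- rbind(f[1, ], 2 - f[1, ])
  expect_equal(similarity_matrix(anti)[1, 2], -1, tolerance = 1e-12)

  cf <- rbind(f, rep(3, 20))
  rownames(cf) <- c(paste0("r", 1:6), "flatrow")
  expect_error(similarity_matrix(cf), "flatrow")
})

test_that("similarity is invariant to a common channel permutation", {
  tep <- small_tep(seed = 6, n_sites = 5, n_channels = 8)
  S1 <- similarity_matrix(stimulation_feature_matrix(tep))
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  tep2 <- tep
  tep2$voltages <- tep$voltages[, perm, ]
  S2 <- similarity_matrix(stimulation_feature_matrix(tep2))
  expect_equal(S1, S2, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("orientation dissimilarity is 1 minus Pearson with shift invariance", {
  set.seed(31)
  f <- matrix(rnorm(4 * 25), 4, 25,
              dimnames = list(c("a_N45", "a_P45", "b_N45", "b_P45"), NULL))
  pairs <- data.frame(site = c("a", "b"),
                      n45 = c("a_N45", "b_N45"),
                      p45 = c("a_P45", "b_P45"))
  d <- orientation_dissimilarity(f, pairs)
  expect_equal(unname(d["a"]),
               1 - pearson_oracle(f["a_N45", ], f["a_P45", ]),
               tolerance = 1e-12)

  ident <- f; ident["a_P45", ] <- ident["a_N45", ]
  expect_equal(unname(orientation_dissimilarity(ident, pairs)["a"]), 0,
               tolerance = 1e-12)
  anti <- f; anti["a_P45", ] <- -anti["a_N45", ]
  expect_equal(unname(orientation_dissimilarity(anti, pairs)["a"]), 2,
               tolerance = 1e-12)

  shifted <- f + 7
  expect_equal(orientation_dissimilarity(shifted, pairs), d,
               tolerance = 1e-10)

  pairs2 <- rbind(pairs, data.frame(site = "c", n45 = "c_N45",
                                    p45 = "c_P45"))
  expect_warning(d2 <- orientation_dissimilarity(f, pairs2), "c")
  expect_length(d2, 2)
})

test_that("covariate regression matches the closed-form OLS residual", {
  tep <- small_tep(seed = 8, n_sites = 5, n_channels = 4,
                   n_timepoints = 30)
  cov <- tep$conditions$suds
  res <- regress_out_covariate(tep, cov)
  m <- matrix(tep$voltages, nrow = 10)
  X <- cbind(1, cov)
  beta <- solve(t(X) %*% X) %*% t(X) %*% m
  expect_equal(matrix(res$voltages, nrow = 10), m - X %*% beta,
               tolerance = 1e-10)

  ## values exactly linear in the covariate vanish
  lin <- tep
  for (i in 1:10) lin$voltages[i, , ] <- 2 + 3 * cov[i]
  out <- regress_out_covariate(lin, cov)
  expect_equal(max(abs(out$voltages)), 0, tolerance = 1e-10)

  ## constant covariate degenerates to mean-centering, with a warning
  expect_warning(cc <- regress_out_covariate(tep, rep(5, 10)),
                 "constant covariate")
  expect_equal(matrix(cc$voltages, nrow = 10),
               sweep(m, 2, colMeans(m)), tolerance = 1e-12)

  expect_error(regress_out_covariate(tep, 1:3), "per condition")
})
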