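test_that("T2 matches the direct score-variance formula on a small fixture", {
  set.seed(20)
  X <- matrix(rnorm(10 * 6), 10, 6)
  y <- rnorm(10)
  m <- fit_pls(X, y, 3)
  rep_ <- hotelling_q_outliers(m, X)
  tv <- colSums(m$scores^2) / (10 - 1)
  t2_direct <- sapply(1:10, function(i) sum(m$scores[i, ]^2 / tv))
  expect_equal(rep_$t2, t2_direct, tolerance = 1e-10)
  # T2 limit is the F-based leverage bound
  expect_equal(rep_$t2_limit, 3 * 9 / 7 * qf(0.95, 3, 7))
})

test_that("a sample on the model plane at the origin has T2 = Q = 0", {
  set.seed(21)
  X <- matrix(rnorm(20 * 8), 20, 8)
  m <- fit_pls(X, rnorm(20), 2)
  m$x_cal <- X
  # the column-mean spectrum maps to the centered origin
  center <- matrix(colMeans(X), 1)
  rep_ <- hotelling_q_outliers(m, center)
  expect_equal(rep_$t2, 0, tolerance = 1e-20)
  expect_equal(rep_$q, 0, tolerance = 1e-20)
  expect_false(rep_$outlier)
})

test_that("the both-rule spares samples extreme in only one statistic", {
  set.seed(22)
  X <- matrix(rnorm(30 * 10), 30, 10)
  m <- fit_pls(X, rnorm(30), 2)
  m$x_cal <- X
  # displace a probe far along LV1 only: huge T2, tiny Q
  st <- m$preprocess_state
  probe_c <- 50 * sd(m$scores[, 1]) * tcrossprod(1, m$P[, 1])
  probe <- sweep(sweep(probe_c, 2, st$column_pareto_scales, `*`), 2,
                 st$column_means, `+`)
  rep_ <- hotelling_q_outliers(m, probe)
  expect_gt(rep_$t2, rep_$t2_limit)
  expect_false(rep_$outlier)            # Q not extreme -> kept under "both"
  rep_or <- hotelling_q_outliers(m, probe, rule = "either")
  expect_true(rep_or$outlier)
})

test_that("reference screening flags residuals beyond three RMSEC", {
  set.seed(23)
  fx <- low_rank_fixture(n = 50, p = 12, n_factors = 2, noise = 0.05)
  m <- fit_pls(fx$X, fx$y, 2)
  rep_clean <- reference_outliers(m, fx$X, fx$y)
  expect_false(any(rep_clean$outlier))
  # plant one gross reference error and refit
  y_bad <- fx$y
  y_bad[7] <- y_bad[7] + 10 * sd(fx$y)
  m2 <- fit_pls(fx$X, y_bad, 2)
  rep_bad <- reference_outliers(m2, fx$X, y_bad)
  expect_true(rep_bad$outlier[7])
  expect_equal(sum(rep_bad$outlier), 1)
})

test_that("a perfect fit (RMSEC = 0) cannot flag reference outliers", {
  fx <- low_rank_fixture(n = 20, p = 8, n_factors = 1, noise = 0)
  m <- fit_pls(fx$X, fx$y, 1)
  rep_ <- reference_outliers(m, fx$X, fx$y)
  expect_lt(rep_$rmsec, 1e-10)
  expect_false(any(rep_$outlier))
})

test_that("the outlier loop leaves clean data essentially alone", {
  # with dual 5% thresholds an isolated borderline flag is expected noise;
  # what must not happen on clean data is any systematic removal
  set.seed(24)
  fx <- low_rank_fixture(n = 60, p = 15, n_factors = 2, noise = 0.05)
  loop <- outlier_loop(fx$X, fx$y, n_lv = 2)
  expect_lte(loop$n_removed, 1)
  expect_lte(length(loop$history), 3)
})

test_that("planted outliers of both kinds are removed within three passes", {
  set.seed(25)
  fx <- low_rank_fixture(n = 80, p = 20, n_factors = 2, noise = 0.05)
  X <- fx$X; y <- fx$y
  ids <- sprintf("s%02d", 1:80)
  # two spectral outliers: strong off-model structure
  X[3, ] <- X[3, ] * 4 + rnorm(20, sd = 3)
  X[11, ] <- -2 * X[11, ] + rnorm(20, sd = 3)
  # one reference outlier
  y[30] <- y[30] + 12 * sd(y)
  loop <- outlier_loop(X, y, n_lv = 2, sample_ids = ids)
  removed <- unlist(lapply(loop$history, `[[`, "removed_ids"))
  expect_true(all(c("s03", "s11", "s30") %in% removed))
  expect_lte(length(loop$history), 3)
})

test_that("excessive removals trigger the guard-rail warning", {
  set.seed(26)
  fx <- low_rank_fixture(n = 30, p = 10, n_factors = 2, noise = 0.05)
  X <- fx$X; y <- fx$y
  bad <- 1:6
  X[bad, ] <- X[bad, ] * 5 + matrix(rnorm(60, sd = 4), 6, 10)
  y[bad] <- y[bad] + 8 * sd(y)
  expect_warning(outlier_loop(X, y, n_lv = 2, max_fraction = 0.1),
                 "outlier loop removed")
})

test_that("VIP obeys its normalization identity", {
  set.seed(27)
  for (rep in 1:4) {
    X <- matrix(rnorm(30 * (5 + rep * 3)), 30)
    y <- rnorm(30)
    m <- fit_pls(X, y, 1 + rep)
    v <- vip(m)
    expect_equal(sum(v$vip^2), ncol(X), tolerance = 1e-8)
    expect_true(all(v$vip >= 0))
  }
})

test_that("single-wavelength and single-component VIP reduce correctly", {
  set.seed(28)
  # p = 1: normalization forces VIP = 1
  X1 <- matrix(rnorm(20), 20, 1)
  y1 <- X1[, 1] + rnorm(20, sd = 0.2)
  expect_equal(vip(fit_pls(X1, y1, 1))$vip, 1)
  # h = 1: VIP_j = sqrt(p) |w_j| / ||w||
  X <- matrix(rnorm(25 * 6), 25, 6)
  y <- rnorm(25)
  m <- fit_pls(X, y, 1)
  w <- m$W[, 1]
  expect_equal(vip(m)$vip, sqrt(6) * abs(w) / sqrt(sum(w^2)), tolerance = 1e-12)
})

test_that("VIP categories split at 0.8 and 1.0", {
  set.seed(29)
  X <- matrix(rnorm(40 * 20), 40, 20)
  y <- drop(X[, 1:3] %*% c(3, 2, 1)) + rnorm(40, sd = 0.2)
  v <- vip(fit_pls(X, y, 2))
  expect_true(all(v$category[v$vip > 1] == "influential"))
  expect_true(all(v$category[v$vip < 0.8] == "insignificant"))
  expect_true(all(v$category[v$vip >= 0.8 & v$vip <= 1] == "moderate"))
  # the informative columns dominate
  expect_true(all(which(v$vip > 1.5) %in% 1:3))
})

test_that("VIP requires explained variance", {
  set.seed(30)
  X <- matrix(rnorm(20 * 5), 20, 5)
  m <- fit_pls(X, rnorm(20), 2)
  m$explained_y_variance <- c(0, 0)
  expect_error(vip(m), "explains no response variance")
})

test_that("the PLS energy decomposition holds in aggregate", {
  set.seed(31)
  X <- matrix(rnorm(30 * 8), 30, 8)
  m <- fit_pls(X, rnorm(30), 3)
  m$x_cal <- X
  rep_ <- hotelling_q_outliers(m, X)
  Xc <- pareto_apply(X, m$preprocess_state)
  fitted <- m$scores %*% t(m$P)
  expect_equal(sum(Xc^2), sum(fitted^2) + sum(rep_$q),
               tolerance = 1e-10 * sum(Xc^2))
})

test_that("refitting after removing a flagged reference outlier lowers RMSEC", {
  set.seed(32)
  fx <- low_rank_fixture(n = 50, p = 12, n_factors = 2, noise = 0.05)
  y <- fx$y; y[9] <- y[9] + 10 * sd(y)
  m <- fit_pls(fx$X, y, 2)
  r1 <- reference_outliers(m, fx$X, y)
  expect_true(r1$outlier[9])
  keep <- !r1$outlier
  m2 <- fit_pls(fx$X[keep, ], y[keep], 2)
  r2 <- reference_outliers(m2, fx$X[keep, ], y[keep])
  expect_lt(r2$rmsec, r1$rmsec)
})

test_that("PCA overview reports non-increasing variance fractions", {
  set.seed(33)
  wl <- seq(700, 745, by = 5)
  # rank-2 fixture: two PCs explain everything
  base <- matrix(rnorm(2 * 10), 2, 10)
  mix <- matrix(rnorm(12 * 2), 12, 2)
  s <- spectra_set(wl, mix %*% base, sprintf("s%02d", 1:12), "SS")
  pc <- pca_overview(list(s))
  expect_equal(sum(pc$explained_variance[1:2]), 1, tolerance = 1e-10)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  expect_lte(sum(pc$explained_variance), 1 + 1e-10)
})
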