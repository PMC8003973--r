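test_that("Kennard-Stone follows the max-min rule on a hand-worked case", {
  x <- matrix(c(0, 1, 2, 10), ncol = 1)
  ks <- kennard_stone(x, 0.75)
  # seed pair {0, 10}, then 2 (max-min distance 2 beats 1's distance 1)
  expect_equal(ks$calibration, c(1, 4, 3))
  expect_equal(ks$validation, 2)
})

test_that("Kennard-Stone matches an exhaustive max-min oracle for small n", {
  set.seed(14)
  for (rep in 1:8) {
    n <- sample(5:12, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    frac <- runif(1, 0.4, 0.9)
    got <- kennard_stone(x, frac)
    want <- ks_oracle(x, frac)
    expect_setequal(got$calibration, want$calibration)
    expect_equal(got$validation, want$validation)
  }
})

test_that("the 75% split of 302 samples gives 227 calibration and 75 validation", {
  set.seed(1)
  x <- matrix(rnorm(302 * 8), 302, 8)
  ks <- kennard_stone(x, 0.75)
  expect_length(ks$calibration, 227)
  expect_length(ks$validation, 75)
})

test_that("Kennard-Stone boundary and error cases behave", {
  x <- matrix(c(0, 1, 2, 10), ncol = 1)
  ks <- kennard_stone(x, 0.76)          # ceil(3.04) = 4... use n-1 fraction
  x5 <- matrix(c(0, 1, 2, 4, 10), ncol = 1)
  ks <- kennard_stone(x5, 0.8)          # ceil(4) = 4 -> one validation sample
  expect_length(ks$validation, 1)
  xna <- x; xna[2] <- NA
  expect_error(kennard_stone(xna, 0.75), "NaN/NA")
  expect_error(kennard_stone(x, 1.2), "fraction")
  # duplicate rows (zero distances) are allowed
  expect_silent(kennard_stone(rbind(x, x[1, , drop = FALSE]), 0.5))
})

test_that("type concatenation aligns ids and fixes the type order", {
  wl <- seq(700, 745, by = 5)
  mk <- function(ids, type, seed) {
    set.seed(seed)
    spectra_set(wl, matrix(rnorm(length(ids) * 10), length(ids)), ids, type)
  }
  ids <- c("a", "b", "c")
  sets <- list(RJ = mk(ids, "RJ", 1), SS = mk(rev(ids), "SS", 2),
               DF = mk(ids, "DF", 3), CSS = mk(ids, "CSS", 4))
  cc <- concatenate_types(sets)
  expect_equal(dim(cc), c(3, 40))
  expect_equal(rownames(cc), ids)
  # permuted rows realigned by id: SS block row "a" equals its original row
  expect_equal(unname(cc["a", 1:10]),
               sets$SS$absorbance[sets$SS$sample_ids == "a", ])
  # SS block first despite list order
  expect_equal(unname(cc["b", 1:10]),
               sets$SS$absorbance[sets$SS$sample_ids == "b", ])
  sets$DF <- mk(c("a", "b"), "DF", 5)
  expect_error(concatenate_types(sets), "sample ids differ for type DF")
})

test_that("PLS is exact on noiseless single-factor data", {
  fx <- low_rank_fixture(n = 30, p = 20, n_factors = 1, noise = 0)
  m <- fit_pls(fx$X, fx$y, 1)
  expect_equal(cor(fx$y, predict(m, fx$X))^2, 1, tolerance = 1e-8)
  expect_equal(sum(m$explained_y_variance), 1, tolerance = 1e-8)
})

test_that("PLS at full rank equals ordinary least squares", {
  set.seed(11)
  X <- matrix(rnorm(25 * 6), 25, 6)
  y <- rnorm(25)
  m <- fit_pls(X, y, 6)
  ols <- lm(y ~ X)
  expect_equal(predict(m, X), unname(fitted(ols)), tolerance = 1e-6)
})

test_that("PLS scores are orthogonal and Z sums to the calibration R2", {
  set.seed(12)
  X <- matrix(rnorm(40 * 15), 40, 15)
  y <- rnorm(40)
  m <- fit_pls(X, y, 6)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8 * max(abs(G)))
  r2c_ss <- 1 - sum((y - predict(m, X))^2) / sum((y - mean(y))^2)
  expect_equal(sum(m$explained_y_variance), r2c_ss, tolerance = 1e-10)
  expect_true(all(m$explained_y_variance >= 0 & m$explained_y_variance <= 1))
})

test_that("component counts beyond the data rank are rejected", {
  fx <- low_rank_fixture(n = 20, p = 10, n_factors = 2, noise = 0)
  expect_error(fit_pls(fx$X, fx$y, 10), "rank")
  expect_error(fit_pls(fx$X, fx$y, 0), "n_lv")
  expect_error(fit_pls(fx$X, fx$y, 25), "n_lv")
})

test_that("NIPALS agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(13)
  X <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(NULL, paste0("wl", 1:12)))
  y <- drop(X %*% rnorm(12)) + rnorm(30, sd = 0.3)
  m <- fit_pls(X, y, 3, state = structure(
    list(sg_window = 11, sg_polyorder = 2, sg_deriv = 2,
         column_means = colMeans(X),
         column_pareto_scales = rep(1, 12),
         zero_variance = rep(FALSE, 12)), class = "preprocess_state"))
  ref <- mixOmics::pls(X, y, ncomp = 3, scale = FALSE, mode = "regression")
  pref <- predict(ref, X)$predict[, 1, 3]
  expect_equal(unname(predict(m, X)), unname(pref), tolerance = 1e-6)
})

test_that("venetian blinds interleave samples across folds", {
  expect_equal(venetian_blinds_folds(10, 10), 1:10)       # singleton folds
  f <- venetian_blinds_folds(20, 10)
  expect_equal(which(f == 1), c(1, 11))
  expect_equal(which(f == 7), c(7, 17))
  f2 <- venetian_blinds_folds(23, 10)
  expect_true(all(abs(table(f2) - 23 / 10) < 1))
  expect_error(venetian_blinds_folds(10, 1), "splits")
})

test_that("cross-validation finds the true dimension of noiseless data", {
  fx <- low_rank_fixture(n = 40, p = 15, n_factors = 1, noise = 0)
  cv <- cross_validate(fx$X, fx$y, max_lv = 5, splits = 10)
  expect_lt(cv$rmsecv[1], 1e-6 * sd(fx$y))
  expect_true(all(cv$rmsecv >= 0))
  expect_equal(select_lv(cv), 1L)
})

test_that("splits = n reproduces leave-one-out cross-validation", {
  set.seed(17)
  X <- matrix(rnorm(20 * 8), 20, 8)
  y <- drop(X %*% rnorm(8)) + rnorm(20, sd = 0.5)
  cv <- cross_validate(X, y, max_lv = 3, splits = 20)
  # manual LOO oracle
  pred <- matrix(NA_real_, 20, 3)
  for (i in 1:20) {
    fit <- fit_pls(X[-i, ], y[-i], 3)
    for (a in 1:3) pred[i, a] <- predict(fit, X[i, , drop = FALSE], n_lv = a)
  }
  expect_equal(cv$rmsecv, sqrt(colMeans((pred - y)^2)), tolerance = 1e-10)
})

test_that("LV selection returns the most parsimonious adequate model", {
  # flat curve: residuals identical for all LV -> 1
  res <- matrix(rnorm(50), 50, 4)
  cv_flat <- list(rmsecv = rep(1, 4), residuals = res[, c(1, 1, 1, 1)])
  expect_equal(select_lv(cv_flat), 1L)
  # sharp unique minimum, all smaller LVs clearly worse -> argmin
  set.seed(18)
  good <- rnorm(60, sd = 0.1)
  cv_sharp <- list(rmsecv = c(10, 5, 0.1),
                   residuals = cbind(rnorm(60, mean = 10, sd = 0.5),
                                     rnorm(60, mean = 5, sd = 0.5), good))
  expect_equal(select_lv(cv_sharp), 3L)
})

test_that("prediction metrics follow their definitions", {
  y <- c(1, 2, 3, 4, 5)
  # constant error c: RMSE = |c|
  expect_equal(prediction_metrics(y, y + 2)$rmse, 2)
  expect_equal(prediction_metrics(y, y - 2)$rmse, 2)
  # perfect prediction: RMSE 0, R2 1, RPIQ undefined at zero error
  m <- prediction_metrics(y, y)
  expect_equal(m$rmse, 0)
  expect_equal(m$r2, 1)
  expect_true(is.na(m$rpiq))
  # zero-variance reference: R2 undefined
  expect_true(is.na(prediction_metrics(rep(1, 4), c(1, 2, 1, 2))$r2))
  # the two R2 conventions differ off the 45-degree line
  yp <- 2 * y
  expect_equal(prediction_metrics(y, yp, r2_method = "pearson")$r2, 1)
  expect_lt(prediction_metrics(y, yp, r2_method = "ss")$r2, 0)
})

test_that("RPIQ is shift-invariant and uses the evaluation-set quartiles", {
  set.seed(19)
  y <- rnorm(50); yp <- y + rnorm(50, sd = 0.5)
  m1 <- prediction_metrics(y, yp)
  m2 <- prediction_metrics(y + 100, yp + 100)
  expect_equal(m1$rpiq, m2$rpiq)
  q <- quantile(y, c(0.25, 0.75), names = FALSE)
  expect_equal(m1$rpiq, (q[2] - q[1]) / m1$rmse)
})
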