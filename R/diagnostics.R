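#' Hotelling T² / Q-residual outlier screening
#'
#' Computes, for each supplied spectrum, its leverage in the model's score
#' space (Hotelling T²) and its squared residual outside the model plane
#' (Q). Thresholds at significance level `alpha`: T² from the F-distribution
#' limit `h (n-1) / (n-h) * F(1-alpha; h, n-h)` with `h` components fitted
#' on `n` calibration samples; Q from the Jackson-Mudholkar approximation
#' based on the residual eigenvalues of the calibration data (a chi-squared
#' moment-matching alternative is available). Following the influence-plot
#' reading that a sample must be extreme in both senses, a sample is flagged
#' only when BOTH statistics exceed their thresholds (`rule = "both"`,
#' default); `rule = "either"` is available.
#'
#' @param model a [fit_pls()] model.
#' @param x row-preprocessed spectra to screen (calibration rows by
#'   default).
#' @param alpha significance level (default 0.05).
#' @param rule `"both"` (default) or `"either"`.
#' @param q_method `"jackson"` (default) or `"chisq"`.
#' @param sample_ids optional ids for reporting.
#' @return list with per-sample `t2`, `q`, thresholds, and logical
#'   `outlier`.
#' @export
hotelling_q_outliers <- function(model, x, alpha = 0.05,
                                 rule = c("both", "either"),
                                 q_method = c("jackson", "chisq"),
                                 sample_ids = rownames(x)) {
  rule <- match.arg(rule)
  q_method <- match.arg(q_method)
  h <- model$n_lv
  n <- model$n_train
  if (h >= n) stopf("T2 threshold undefined: h = %d components >= n = %d", h, n)
  x <- as.matrix(x)
  scores <- pls_scores(model, x)
  score_var <- colSums(model$scores^2) / (n - 1)
  t2 <- rowSums(sweep(scores^2, 2, score_var, `/`))
  t2_limit <- h * (n - 1) / (n - h) * stats::qf(1 - alpha, h, n - h)

  Xc <- pareto_apply(x, model$preprocess_state)
  resid <- Xc - scores %*% t(model$P)
  q <- rowSums(resid^2)

  # residual eigenvalues of the calibration data define the Q limit;
  # when the model does not carry its calibration matrix, the screened rows
  # are taken to be the calibration set itself
  cal_x <- model$x_cal %||% x
  if (nrow(cal_x) != n)
    stopf("model carries no calibration matrix and x is not the calibration set")
  cal_resid <- pareto_apply(cal_x, model$preprocess_state) -
    model$scores %*% t(model$P)
  lambda <- svd(cal_resid, nu = 0, nv = 0)$d^2 / (n - 1)
  lambda <- lambda[lambda > max(lambda, 0) * 1e-12]
  q_limit <- q_threshold(lambda, alpha, q_method)

  out <- switch(rule,
                both = (t2 > t2_limit) & (q > q_limit),
                either = (t2 > t2_limit) | (q > q_limit))
  list(t2 = t2, q = q, t2_limit = t2_limit, q_limit = q_limit,
       outlier = out, alpha = alpha, rule = rule, q_method = q_method,
       sample_ids = sample_ids %||% as.character(seq_len(nrow(x))))
}

q_threshold <- function(lambda, alpha, method = "jackson") {
  if (length(lambda) == 0 || sum(lambda) <= 0) return(Inf)
  th1 <- sum(lambda); th2 <- sum(lambda^2); th3 <- sum(lambda^3)
  if (method == "chisq") {
    g <- th2 / th1
    dof <- th1^2 / th2
    return(g * stats::qchisq(1 - alpha, dof))
  }
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  if (!is.finite(h0) || h0 <= 0) return(q_threshold(lambda, alpha, "chisq"))
  ca <- stats::qnorm(1 - alpha)
  th1 * (ca * sqrt(2 * th2 * h0^2) / th1 + 1 +
           th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
}

#' Reference-value outlier screening
#'
#' Flags calibration samples whose calibration residual exceeds three times
#' the RMSEC, the conventional screen for gross reference-laboratory errors.
#'
#' @param model a [fit_pls()] model carrying its calibration data.
#' @param x,y calibration spectra (row-preprocessed) and reference values.
#' @param sample_ids optional ids.
#' @return list with `residual`, `rmsec`, `threshold` (3 x RMSEC) and
#'   logical `outlier`.
#' @export
reference_outliers <- function(model, x, y, sample_ids = rownames(x)) {
  yhat <- predict(model, x)
  resid <- as.numeric(y) - yhat
  rmsec <- sqrt(mean(resid^2))
  list(residual = resid, rmsec = rmsec, threshold = 3 * rmsec,
       outlier = abs(resid) > 3 * rmsec,
       sample_ids = sample_ids %||% as.character(seq_along(y)))
}

#' Iterative calibration outlier removal
#'
#' Repeats {fit, spectral screening (T²/Q, both-rule), reference screening
#' (±3 RMSEC), refit} until no sample is removed or `max_iter` iterations
#' (default 3, the conventional cap for calibration cleanup) have run.
#' Validation samples never enter this loop. A warning is raised if the
#' cumulative removals exceed `max_fraction` of the calibration set.
#'
#' @param x,y calibration spectra (row-preprocessed) and references.
#' @param n_lv number of components for the screening fits.
#' @param alpha significance level for T²/Q thresholds.
#' @param max_iter maximum number of removal iterations.
#' @param max_fraction removal fraction above which a warning is raised.
#' @param sample_ids optional ids (default row names or indices).
#' @return list with cleaned `x`, `y`, `kept_ids`, the final `model`, and
#'   `history`: one record per iteration with removed ids and reasons.
#' @export
outlier_loop <- function(x, y, n_lv, alpha = 0.05, max_iter = 3,
                         max_fraction = 0.1,
                         sample_ids = rownames(x)) {
  x <- as.matrix(x); y <- as.numeric(y)
  ids <- sample_ids %||% as.character(seq_len(nrow(x)))
  n0 <- nrow(x)
  history <- list()
  model <- NULL
  for (it in seq_len(max_iter)) {
    model <- fit_pls(x, y, min(n_lv, nrow(x) - 2, ncol(x)), sample_ids = ids)
    model$x_cal <- x
    spec <- hotelling_q_outliers(model, x, alpha = alpha, sample_ids = ids)
    ref <- reference_outliers(model, x, y, sample_ids = ids)
    drop <- spec$outlier | ref$outlier
    reason <- ifelse(spec$outlier, "spectral", "reference")[drop]
    history[[it]] <- list(iteration = it,
                          removed_ids = ids[drop], reason = reason,
                          rmsec = ref$rmsec,
                          t2_limit = spec$t2_limit, q_limit = spec$q_limit)
    if (!any(drop)) break
    x <- x[!drop, , drop = FALSE]; y <- y[!drop]; ids <- ids[!drop]
  }
  removed_total <- n0 - nrow(x)
  if (removed_total > max_fraction * n0)
    warnf("outlier loop removed %d of %d calibration samples (> %.0f%%)",
          removed_total, n0, 100 * max_fraction)
  model <- fit_pls(x, y, min(n_lv, nrow(x) - 2, ncol(x)), sample_ids = ids)
  model$x_cal <- x
  list(x = x, y = y, kept_ids = ids, model = model, history = history,
       n_removed = removed_total)
}

#' Variable importance in projection
#'
#' For a fitted model with `h` components over `p` wavelengths,
#' `VIP_j = sqrt( p * sum_k Z_k (w_jk / ||w_k||)^2 / sum_k Z_k )`, where
#' `w_k` are the loading weights and `Z_k` the fraction of response variance
#' explained by component `k`. The mean of `VIP_j^2` is 1 by construction.
#' Wavelengths are categorised as influential (> 1.0), moderate
#' (0.8 to 1.0) or insignificant (< 0.8).
#'
#' @param model a [fit_pls()] model.
#' @param wavelengths optional wavelength labels (length `p`).
#' @return list with `vip`, `category`, `p`, `h`, `wavelengths`.
#' @export
vip <- function(model, wavelengths = NULL) {
  Z <- model$explained_y_variance
  if (sum(Z) <= 0)
    stopf("model explains no response variance; VIP undefined")
  W <- model$W
  p <- nrow(W); h <- ncol(W)
  wn <- sweep(W, 2, sqrt(colSums(W^2)), `/`)
  v <- sqrt(p * as.numeric(wn^2 %*% Z) / sum(Z))
  category <- cut(v, c(-Inf, 0.8, 1.0, Inf), right = FALSE,
                  labels = c("insignificant", "moderate", "influential"))
  # boundary convention: VIP == 1.0 is moderate, VIP > 1.0 influential
  category[v == 1.0] <- "moderate"
  list(vip = v, category = as.character(category), p = p, h = h,
       wavelengths = wavelengths)
}

#' Exploratory PCA of pooled mean spectra
#'
#' Mean-centered principal component analysis of the pooled per-sample
#' spectra of several sample types, the standard first look at whether
#' sample preparation dominates spectral variance.
#'
#' @param sets list of replicate-averaged [spectra_set()] sharing one grid.
#' @param n_pc number of components to return.
#' @return list with `scores`, `explained_variance` (fractions,
#'   non-increasing), `sample_type` labels and `sample_ids`.
#' @export
pca_overview <- function(sets, n_pc = 2) {
  wl <- sets[[1]]$wavelengths
  for (s in sets)
    if (length(s$wavelengths) != length(wl) ||
        max(abs(s$wavelengths - wl)) > 1e-6)
      stopf("all sets must share one wavelength grid")
  X <- do.call(rbind, lapply(sets, function(s) s$absorbance))
  labels <- unlist(lapply(sets, function(s) rep(s$sample_type, nrow(s$absorbance))))
  ids <- unlist(lapply(sets, function(s) s$sample_ids))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  n_pc <- min(n_pc, ncol(pc$x))
  list(scores = pc$x[, seq_len(n_pc), drop = FALSE],
       explained_variance = ev,
       sample_type = labels, sample_ids = ids)
}
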