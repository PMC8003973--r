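#' Kennard-Stone calibration-set selection
#'
#' The classic deterministic max-min algorithm: seed with the two samples at
#' maximal Euclidean distance, then repeatedly add the sample whose minimum
#' distance to the already-selected set is largest, until
#' `ceiling(fraction * n)` samples are selected. The remainder forms the
#' external validation set and lies within the span of the selected set by
#' construction.
#'
#' @param x numeric matrix, samples in rows (typically the concatenated
#'   preprocessed spectra of all sample types).
#' @param fraction calibration fraction, strictly between 0 and 1.
#' @return list with `calibration` (indices in selection order) and
#'   `validation` (remaining indices, ascending).
#' @export
kennard_stone <- function(x, fraction = 0.75) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stopf("need at least 2 samples")
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0, 1)")
  if (anyNA(x)) stopf("NaN/NA features are not allowed")
  n_cal <- ceiling(fraction * n)
  d <- as.matrix(stats::dist(x))
  first <- which(d == max(d), arr.ind = TRUE)[1, ]
  sel <- c(first[[2]], first[[1]])          # row-major which() order: keep
  sel <- sort(sel)                          # deterministic tie-break: lower first
  mind <- pmin(d[, sel[1]], d[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < n_cal) {
    nxt <- which.max(mind)
    sel <- c(sel, nxt)
    mind <- pmin(mind, d[, nxt])
    mind[nxt] <- -Inf
  }
  list(calibration = as.integer(unname(sel)),
       validation = setdiff(seq_len(n), sel))
}

#' Concatenate the spectra of several sample types feature-wise
#'
#' Aligns rows by sample id (erroring on any mismatch) and binds the
#' absorbance matrices column-wise in the fixed order SS, CSS, DF, RJ (types
#' absent from the input keep their relative order). One Kennard-Stone split
#' of the result serves every sample type, so calibration and validation
#' contain the same mill samples for all types.
#'
#' @param sets named list of [spectra_set()], one per sample type, replicate
#'   averaged (one row per sample).
#' @return numeric matrix, samples x (sum of per-type wavelengths), with
#'   sample ids as row names.
#' @export
concatenate_types <- function(sets) {
  order_pref <- c("SS", "CSS", "DF", "RJ")
  ids <- sets[[1]]$sample_ids        # row order of the first set as given
  nm <- names(sets)
  nm <- c(intersect(order_pref, nm), setdiff(nm, order_pref))
  sets <- sets[nm]
  for (ty in nm) {
    missing <- setdiff(ids, sets[[ty]]$sample_ids)
    extra <- setdiff(sets[[ty]]$sample_ids, ids)
    if (length(missing) || length(extra))
      stopf("sample ids differ for type %s (missing: %s; extra: %s)", ty,
            paste(missing, collapse = ",") , paste(extra, collapse = ","))
  }
  blocks <- lapply(sets, function(s)
    s$absorbance[match(ids, s$sample_ids), , drop = FALSE])
  out <- do.call(cbind, blocks)
  rownames(out) <- ids
  out
}

#' Fit a PLS1 regression model (NIPALS)
#'
#' Univariate-response partial least squares by the NIPALS algorithm.
#' Column preprocessing (Pareto centering/scaling) is fitted on the supplied
#' calibration rows unless a pre-fitted `state` is given; the response is
#' centered on its calibration mean. Stores loading weights `W`, x-loadings
#' `P`, y-loadings `q`, scores `T` and the per-component fraction of
#' response variance explained, `Z` (so `sum(Z)` equals the calibration R²
#' in its sum-of-squares form).
#'
#' @param x calibration spectra (rows), already row-preprocessed (SNV + SG).
#' @param y calibration response vector.
#' @param n_lv number of latent variables.
#' @param state optional pre-fitted [pareto_fit()] state (to mimic scaling
#'   fitted outside the resampling loop); default refits on `x`.
#' @param sample_ids optional ids stored with the model.
#' @param allow_fewer if the data run out of rank before `n_lv` components,
#'   return the model with the components that could be extracted instead of
#'   erroring (used by resampling loops on near-noiseless data).
#' @return object of class `pls_model`.
#' @export
fit_pls <- function(x, y, n_lv, state = NULL, sample_ids = rownames(x),
                    allow_fewer = FALSE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stopf("x and y disagree on sample count")
  if (n_lv < 1 || n_lv > min(n - 1, p))
    stopf("n_lv = %d outside valid range 1..%d", n_lv, min(n - 1, p))
  if (is.null(state)) state <- pareto_fit(x)
  X <- pareto_apply(x, state)
  y_mean <- mean(y)
  yc <- y - y_mean
  ssy <- sum(yc^2)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv); qv <- numeric(n_lv); Z <- numeric(n_lv)
  Xd <- X; yd <- yc
  reached <- 0L
  for (k in seq_len(n_lv)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(ssy))) {
      if (allow_fewer) break
      stopf("n_lv = %d exceeds the effective rank of the data (failed at LV %d)",
            n_lv, k)
    }
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-24) {
      if (allow_fewer) break
      stopf("n_lv = %d exceeds the effective rank of the data (failed at LV %d)",
            n_lv, k)
    }
    pk <- crossprod(Xd, t) / tt
    qk <- sum(yd * t) / tt
    Xd <- Xd - t %*% t(pk)
    yd <- yd - qk * t
    W[, k] <- w; P[, k] <- pk; Tm[, k] <- t; qv[k] <- qk
    Z[k] <- if (ssy > 0) qk^2 * tt / ssy else 0
    reached <- k
  }
  if (reached == 0L)
    stopf("no PLS component could be extracted (response constant or X rank 0)")
  if (reached < n_lv) {
    keep <- seq_len(reached)
    W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
    Tm <- Tm[, keep, drop = FALSE]; qv <- qv[keep]; Z <- Z[keep]
    n_lv <- reached
  }
  structure(list(n_lv = n_lv, W = W, P = P, q = qv, scores = Tm,
                 explained_y_variance = Z, preprocess_state = state,
                 y_mean = y_mean, ssy = ssy,
                 n_train = n, sample_ids = sample_ids),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d LV, %d training samples, %d variables; R2c = %.4f\n",
              x$n_lv, x$n_train, nrow(x$W), sum(x$explained_y_variance)))
  invisible(x)
}

# X-side rotation turning preprocessed spectra into scores: T = Xc %*% R
pls_rotation <- function(model, n_lv = model$n_lv) {
  W <- model$W[, seq_len(n_lv), drop = FALSE]
  P <- model$P[, seq_len(n_lv), drop = FALSE]
  W %*% solve(crossprod(P, W))
}

#' Predict from a PLS model
#'
#' @param object a [fit_pls()] model.
#' @param newdata matrix of row-preprocessed spectra.
#' @param n_lv number of components to use (default: all fitted).
#' @param ... unused.
#' @export
predict.pls_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  Xc <- pareto_apply(as.matrix(newdata), object$preprocess_state)
  R <- pls_rotation(object, n_lv)
  q <- object$q[seq_len(n_lv)]
  drop(object$y_mean + Xc %*% (R %*% q))
}

# Scores of (possibly new) preprocessed rows in the model's LV space.
pls_scores <- function(model, x) {
  Xc <- pareto_apply(as.matrix(x), model$preprocess_state)
  Xc %*% pls_rotation(model)
}

#' Venetian-blinds fold assignment
#'
#' Sample `i` (1-based, in calibration order) goes to fold
#' `((i - 1) mod splits) + 1`, the interleaved pattern used for ordered
#' calibration sets. With `splits = n` this is leave-one-out.
#'
#' @param n number of calibration samples.
#' @param splits number of folds (>= 2).
#' @export
venetian_blinds_folds <- function(n, splits = 10) {
  if (splits < 2) stopf("splits must be >= 2")
  ((seq_len(n) - 1L) %% as.integer(splits)) + 1L
}

#' Venetian-blinds cross-validation of a PLS model
#'
#' For each fold, a model with `max_lv` components is fitted on the
#' remaining folds (Pareto scaling refit within each training fold unless
#' `state` is supplied) and held-out predictions are collected for every
#' component count, yielding an RMSECV curve and the per-sample held-out
#' residuals needed for significance-based component selection.
#'
#' @param x,y calibration data in calibration (Kennard-Stone) order.
#' @param max_lv largest component count to evaluate.
#' @param splits number of venetian-blinds folds.
#' @param state optional global [pareto_fit()] state (leakage-prone; default
#'   refits per fold).
#' @return list with `rmsecv` (length `max_lv`), `residuals`
#'   (n x max_lv held-out residual matrix) and `folds`.
#' @export
cross_validate <- function(x, y, max_lv, splits = 10, state = NULL) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  folds <- venetian_blinds_folds(n, splits)
  min_train <- n - max(table(folds))
  cap <- min(min_train - 1, ncol(x))
  if (max_lv > cap)
    stopf("max_lv = %d too large for the smallest training fold (cap %d)",
          max_lv, cap)
  pred <- matrix(NA_real_, n, max_lv)
  for (f in unique(folds)) {
    test <- folds == f
    fit <- fit_pls(x[!test, , drop = FALSE], y[!test], max_lv, state = state,
                   allow_fewer = TRUE)
    for (a in seq_len(max_lv))  # beyond the reachable rank the fit is flat
      pred[test, a] <- predict(fit, x[test, , drop = FALSE],
                               n_lv = min(a, fit$n_lv))
  }
  resid <- pred - y
  list(rmsecv = sqrt(colMeans(resid^2)), residuals = resid, folds = folds)
}

#' Select the number of latent variables from an RMSECV curve
#'
#' Returns the lowest component count whose cross-validation error is not
#' significantly higher than the minimum of the curve. For each candidate
#' `k` below the argmin `k*`, the paired per-sample squared held-out errors
#' at `k` and `k*` are compared with the sign-flip randomization test (see
#' [randomization_test()]); the smallest `k` with `p >= alpha` is chosen,
#' falling back to `k*` when every smaller count is significantly worse.
#'
#' @param cv a [cross_validate()] result (or a list with `residuals`).
#' @param alpha significance level (default 0.05).
#' @param n_perm Monte-Carlo permutations for the embedded tests.
#' @param seed seed for the embedded tests.
#' @export
select_lv <- function(cv, alpha = 0.05, n_perm = 4999, seed = 1) {
  rmsecv <- cv$rmsecv
  kstar <- which.min(rmsecv)
  if (kstar == 1) return(1L)
  for (k in seq_len(kstar - 1)) {
    rt <- randomization_test(abs(cv$residuals[, k]), abs(cv$residuals[, kstar]),
                             n_perm = n_perm,
                             seed = derive_seed(seed, 7000 + k))
    if (rt$p_value >= alpha) return(as.integer(k))
  }
  as.integer(kstar)
}

#' Prediction metrics: RMSE, R² and RPIQ
#'
#' RMSE is `sqrt(mean((y - yhat)^2))`. R² defaults to the squared Pearson
#' correlation between reference and predicted values (`method = "pearson"`);
#' `method = "ss"` gives `1 - SSE/SST`. RPIQ is the interquartile range of
#' the reference values of the evaluation set divided by the RMSE; quartiles
#' use linear interpolation between order statistics (`quantile` type 7).
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @param quartiles_source values whose quartiles form the RPIQ numerator
#'   (default `y_true`).
#' @param r2_method `"pearson"` or `"ss"`.
#' @return list with `rmse`, `r2`, `rpiq` (NA with zero RMSE or degenerate
#'   input).
#' @export
prediction_metrics <- function(y_true, y_pred, quartiles_source = y_true,
                               r2_method = c("pearson", "ss")) {
  r2_method <- match.arg(r2_method)
  if (length(y_true) != length(y_pred)) stopf("length mismatch")
  if (length(y_true) < 2) stopf("need at least 2 samples")
  rmse <- sqrt(mean((y_true - y_pred)^2))
  r2 <- if (stats::var(y_true) == 0) {
    NA_real_
  } else if (r2_method == "pearson") {
    if (stats::var(y_pred) == 0) NA_real_ else stats::cor(y_true, y_pred)^2
  } else {
    1 - sum((y_true - y_pred)^2) / sum((y_true - mean(y_true))^2)
  }
  qs <- stats::quantile(quartiles_source, c(0.25, 0.75), names = FALSE, type = 7)
  list(rmse = rmse, r2 = r2, rpiq = rpiq(qs[1], qs[2], rmse))
}

#' RPIQ from quartiles and an RMSE
#'
#' @param q25,q75 lower and upper quartiles of the evaluation reference
#'   values.
#' @param rmse the corresponding root mean square error.
#' @return `(q75 - q25) / rmse`; `NA` when `rmse` is 0 (undefined at zero
#'   error).
#' @export
rpiq <- function(q25, q75, rmse) {
  if (rmse == 0) return(NA_real_)
  (q75 - q25) / rmse
}
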