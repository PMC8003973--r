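#' Standard normal variate
#'
#' Centers each spectrum (row) on its mean and scales it by its sample SD
#' (n-1 denominator), removing additive baseline offsets and multiplicative
#' scatter. Invariant under `a * x + b` for `a > 0`.
#'
#' @param x numeric vector (one spectrum) or matrix (one spectrum per row).
#' @return object of the same shape; each row has mean 0 and sample SD 1.
#' @export
snv <- function(x) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1, snv))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  if (length(x) < 2) stopf("SNV needs at least 2 wavelengths")
  s <- stats::sd(x)
  if (s == 0)
    stopf("constant spectrum (zero SD); SNV undefined%s",
          if (!is.null(names(s))) paste0(" for sample ", names(s)) else "")
  (x - mean(x)) / s
}

snv_set <- function(set) {
  s <- apply(set$absorbance, 1, stats::sd)
  if (any(s == 0))
    stopf("constant spectrum (zero SD); SNV undefined for sample %s",
          set$sample_ids[which(s == 0)[1]])
  set$absorbance <- snv(set$absorbance)
  set
}

#' Savitzky-Golay second derivative
#'
#' Filters each spectrum with a Savitzky-Golay second-derivative filter
#' (default window 11 points, polynomial order 2). Each contiguous detector
#' segment (see [wavelength_segments()]) is filtered independently; the
#' filter never spans the inter-detector gap. Edge points are produced by
#' the filter's one-sided polynomial fits so the grid length is preserved.
#' The output is the raw per-index second difference of the local fit (not
#' divided by the squared wavelength step); the convention is irrelevant
#' after Pareto scaling but fixed here for reproducibility.
#'
#' @param x numeric matrix, spectra in rows.
#' @param wavelengths grid matching `ncol(x)`.
#' @param window odd filter length (points).
#' @param polyorder polynomial order (< window).
#' @export
sg_second_derivative <- function(x, wavelengths, window = 11, polyorder = 2) {
  if (window %% 2 != 1 || window <= polyorder)
    stopf("window must be odd and greater than polyorder")
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != length(wavelengths))
    stopf("matrix width %d != number of wavelengths %d", ncol(x),
          length(wavelengths))
  segs <- wavelength_segments(wavelengths)
  short <- vapply(segs, length, 1L) < window
  if (any(short))
    stopf(paste("wavelength segment %g-%g nm has only %d points, fewer than",
                "the filter window (%d); review trimming before derivation"),
          wavelengths[segs[[which(short)[1]]][1]],
          wavelengths[rev(segs[[which(short)[1]]])[1]],
          length(segs[[which(short)[1]]]), window)
  out <- x
  for (s in segs)
    out[, s] <- t(apply(x[, s, drop = FALSE], 1, signal::sgolayfilt,
                        p = polyorder, n = window, m = 2))
  out
}

sg_set <- function(set, window = 11, polyorder = 2) {
  set$absorbance <- sg_second_derivative(set$absorbance, set$wavelengths,
                                         window, polyorder)
  set
}

#' Pareto scaling state
#'
#' Fits column (wavelength-wise) centering and Pareto scaling — division by
#' the square root of the sample SD — on calibration rows only. Zero-SD
#' columns get scale 1 (center only) and are flagged.
#'
#' @param x calibration matrix, spectra in rows.
#' @param window,polyorder Savitzky-Golay settings carried in the state for
#'   provenance.
#' @return object of class `preprocess_state` with `column_means`,
#'   `column_pareto_scales` and `zero_variance` flags.
#' @export
pareto_fit <- function(x, window = 11, polyorder = 2) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  zero <- sdv == 0
  scales <- ifelse(zero, 1, sqrt(sdv))
  structure(list(sg_window = window, sg_polyorder = polyorder, sg_deriv = 2,
                 column_means = mu, column_pareto_scales = scales,
                 zero_variance = zero),
            class = "preprocess_state")
}

#' Apply fitted Pareto scaling
#'
#' Uses the calibration means and scales, whatever rows are supplied —
#' validation rows are never re-centered on their own statistics.
#'
#' @param x matrix, spectra in rows.
#' @param state a [pareto_fit()] result.
#' @export
pareto_apply <- function(x, state) {
  stopifnot(inherits(state, "preprocess_state"))
  if (ncol(x) != length(state$column_means))
    stopf("matrix width %d does not match fitted state (%d columns)",
          ncol(x), length(state$column_means))
  sweep(sweep(x, 2, state$column_means, `-`), 2, state$column_pareto_scales, `/`)
}

#' Row-wise spectral preprocessing (SNV then SG second derivative)
#'
#' The enforced order is SNV, then the Savitzky-Golay second derivative;
#' Pareto scaling is column-wise and fitted later, on calibration rows only
#' (see [pareto_fit()]). Reordering requires calling the individual steps
#' explicitly.
#'
#' @param set a [spectra_set()].
#' @param window,polyorder Savitzky-Golay settings.
#' @export
preprocess_spectra <- function(set, window = 11, polyorder = 2) {
  sg_set(snv_set(set), window = window, polyorder = polyorder)
}

#' Serialize / restore a preprocess state
#'
#' @param state a `preprocess_state`.
#' @param path JSON file.
#' @export
write_preprocess_state <- function(state, path) {
  jsonlite::write_json(unclass(state), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_preprocess_state
#' @export
read_preprocess_state <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(sg_window = s$sg_window, sg_polyorder = s$sg_polyorder,
                 sg_deriv = s$sg_deriv,
                 column_means = as.numeric(s$column_means),
                 column_pareto_scales = as.numeric(s$column_pareto_scales),
                 zero_variance = as.logical(s$zero_variance)),
            class = "preprocess_state")
}
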