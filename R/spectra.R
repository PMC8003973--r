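#' Construct a spectra set
#'
#' A `spectra_set` bundles an absorbance matrix with its wavelength grid,
#' sample identifiers, the sample-preparation type, and (optionally) a
#' replicate index per scan. The wavelength grid may contain a gap between
#' detector segments (e.g. a CCD segment up to ~1011 nm and an InGaAs segment
#' from ~1170 nm); operations that care about contiguity use
#' [wavelength_segments()] to respect it.
#'
#' @param wavelengths strictly increasing numeric vector, nm.
#' @param absorbance numeric matrix, one row per scan, `length(wavelengths)`
#'   columns, absorbance units.
#' @param sample_ids character vector, one per row of `absorbance`.
#' @param sample_type single label, conventionally one of `"SS"`, `"CSS"`,
#'   `"DF"`, `"RJ"` (skin scan, cross-sectional scan, defibrated cane, raw
#'   juice).
#' @param replicate optional integer vector of replicate indices per row;
#'   `NULL` once replicates have been averaged.
#' @return an object of class `spectra_set`.
#' @export
spectra_set <- function(wavelengths, absorbance, sample_ids, sample_type,
                        replicate = NULL) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  sample_ids <- as.character(sample_ids)
  if (any(diff(wavelengths) <= 0))
    stopf("wavelengths must be strictly increasing (first violation after %g nm)",
          wavelengths[which(diff(wavelengths) <= 0)[1]])
  if (ncol(absorbance) != length(wavelengths))
    stopf("absorbance has %d columns but there are %d wavelengths",
          ncol(absorbance), length(wavelengths))
  if (nrow(absorbance) != length(sample_ids))
    stopf("absorbance has %d rows but there are %d sample ids",
          nrow(absorbance), length(sample_ids))
  if (length(sample_type) != 1L)
    stopf("sample_type must be a single label")
  if (!is.null(replicate)) {
    replicate <- as.integer(replicate)
    if (length(replicate) != nrow(absorbance))
      stopf("replicate index length must match rows")
    key <- paste(sample_ids, replicate)
    if (anyDuplicated(key))
      stopf("duplicate (sample_id, replicate) pair: %s", key[anyDuplicated(key)])
  } else if (anyDuplicated(sample_ids)) {
    stopf("duplicate sample_id without replicate index: %s",
          sample_ids[anyDuplicated(sample_ids)])
  }
  if (anyNA(absorbance)) {
    bad <- which(is.na(absorbance), arr.ind = TRUE)[1, ]
    stopf("missing absorbance value at row %d (sample %s), wavelength %g nm",
          bad[1], sample_ids[bad[1]], wavelengths[bad[2]])
  }
  structure(list(wavelengths = wavelengths, absorbance = absorbance,
                 sample_ids = sample_ids, sample_type = as.character(sample_type),
                 replicate = replicate),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  segs <- wavelength_segments(x$wavelengths)
  cat(sprintf("<spectra_set> type %s: %d scans (%d samples), %d bands\n",
              x$sample_type, nrow(x$absorbance), length(unique(x$sample_ids)),
              length(x$wavelengths)))
  for (s in segs)
    cat(sprintf("  segment %g-%g nm (%d bands)\n",
                x$wavelengths[s[1]], x$wavelengths[s[length(s)]], length(s)))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Split a wavelength grid into contiguous segments
#'
#' Detector gaps are detected as steps larger than `gap_factor` times the
#' median step. Returns a list of index vectors, one per contiguous segment.
#'
#' @param wavelengths increasing numeric vector, nm.
#' @param gap_factor multiple of the median step that counts as a gap.
#' @export
wavelength_segments <- function(wavelengths, gap_factor = 3) {
  if (length(wavelengths) < 2) return(list(seq_along(wavelengths)))
  d <- diff(wavelengths)
  breaks <- which(d > gap_factor * stats::median(d))
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(wavelengths))
  mapply(seq, starts, ends, SIMPLIFY = FALSE)
}

#' Write / read a spectra set as wide CSV
#'
#' Columns are `sample_id`, `sample_type`, `replicate` (may be empty), then
#' one column per wavelength labelled in nm. `read_spectra(write_spectra(x))`
#' round-trips up to float formatting (15 significant digits).
#'
#' @param x a [spectra_set()].
#' @param path CSV file path.
#' @export
write_spectra <- function(x, path) {
  stopifnot(inherits(x, "spectra_set"))
  df <- data.frame(sample_id = x$sample_ids,
                   sample_type = x$sample_type,
                   replicate = if (is.null(x$replicate)) NA_integer_ else x$replicate,
                   check.names = FALSE)
  ab <- as.data.frame(x$absorbance)
  names(ab) <- format(x$wavelengths, trim = TRUE, digits = 10)
  utils::write.csv(cbind(df, ab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  meta_cols <- c("sample_id", "sample_type", "replicate")
  if (!all(meta_cols %in% names(df)[1:3]))
    stopf("expected leading columns %s", paste(meta_cols, collapse = ", "))
  wl_names <- setdiff(names(df), meta_cols)
  wl <- suppressWarnings(as.numeric(wl_names))
  if (anyNA(wl))
    stopf("non-numeric wavelength column label: '%s'", wl_names[which(is.na(wl))[1]])
  if (any(diff(wl) <= 0))
    stopf("wavelength columns out of order starting at column '%s'",
          wl_names[which(diff(wl) <= 0)[1] + 1L])
  ab <- suppressWarnings(
    vapply(df[wl_names], as.numeric, numeric(nrow(df))))
  ab <- matrix(ab, nrow = nrow(df),
               dimnames = list(NULL, wl_names))
  if (anyNA(ab)) {
    bad <- which(is.na(ab), arr.ind = TRUE)[1, ]
    stopf("missing or non-numeric absorbance cell at row %d, column '%s'",
          bad[1], wl_names[bad[2]])
  }
  rep_idx <- suppressWarnings(as.integer(df$replicate))
  if (all(is.na(rep_idx))) rep_idx <- NULL
  spectra_set(wl, ab, df$sample_id, unique(df$sample_type), replicate = rep_idx)
}

#' Average replicate scans
#'
#' Each sample's replicate scans are reduced to their arithmetic mean; the
#' replicate index is dropped and sample order follows first appearance.
#'
#' @param x a [spectra_set()] with a replicate index.
#' @export
average_replicates <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  if (is.null(x$replicate))
    stopf("replicate index absent; nothing to average")
  ids <- unique(x$sample_ids)
  ab <- rowsum(x$absorbance, group = x$sample_ids, reorder = FALSE)
  counts <- as.vector(table(factor(x$sample_ids, levels = rownames(ab))))
  ab <- ab / counts
  ab <- ab[match(ids, rownames(ab)), , drop = FALSE]
  rownames(ab) <- NULL
  spectra_set(x$wavelengths, ab, ids, x$sample_type)
}

#' Remove the noisy visible region
#'
#' Drops all wavelengths below `cutoff_low` (default 699 nm), the region
#' dominated by pigment absorption and detector noise in field vis-NIR scans
#' of cane. The number of dropped bands is recorded in the returned object's
#' `trim_log` attribute.
#'
#' @param x a [spectra_set()].
#' @param cutoff_low retain wavelengths `>= cutoff_low` (nm).
#' @export
trim_visible <- function(x, cutoff_low = 699) {
  stopifnot(inherits(x, "spectra_set"))
  keep <- x$wavelengths >= cutoff_low
  out <- spectra_set(x$wavelengths[keep], x$absorbance[, keep, drop = FALSE],
                     x$sample_ids, x$sample_type, x$replicate)
  log <- c(trim_log(x),
           list(list(op = "trim_visible", cutoff_low = cutoff_low,
                     n_dropped = sum(!keep))))
  attr(out, "trim_log") <- log
  out
}

#' Remove high-coefficient-of-variation bands
#'
#' Computes the per-wavelength coefficient of variation (SD / |mean| across
#' samples). Bands whose CV exceeds `cv_threshold` times the median CV are
#' dropped: by default only the maximal contiguous suffix of such bands (the
#' typical failure mode of the long-wavelength detector tail); with
#' `tail_only = FALSE`, anywhere in the grid. Bands with zero mean have
#' undefined CV and are treated as exceeding the threshold.
#'
#' @param x a [spectra_set()] with at least 2 samples.
#' @param cv_threshold multiple of the median CV above which a band is
#'   considered unstable.
#' @param tail_only drop only the trailing run of high-CV bands.
#' @export
trim_high_cv <- function(x, cv_threshold = 5, tail_only = TRUE) {
  stopifnot(inherits(x, "spectra_set"))
  if (nrow(x$absorbance) < 2) stopf("need at least 2 samples to compute CV")
  mu <- colMeans(x$absorbance)
  sdv <- apply(x$absorbance, 2, stats::sd)
  cv <- ifelse(mu == 0, Inf, sdv / abs(mu))
  thr <- cv_threshold * stats::median(cv[is.finite(cv)])
  high <- cv > thr
  drop <- if (tail_only) {
    d <- logical(length(high))
    i <- length(high)
    while (i >= 1 && high[i]) { d[i] <- TRUE; i <- i - 1 }
    d
  } else high
  out <- spectra_set(x$wavelengths[!drop], x$absorbance[, !drop, drop = FALSE],
                     x$sample_ids, x$sample_type, x$replicate)
  log <- c(trim_log(x),
           list(list(op = "trim_high_cv", cv_threshold = cv_threshold,
                     tail_only = tail_only, n_dropped = sum(drop),
                     retained_range = range(x$wavelengths[!drop]))))
  attr(out, "trim_log") <- log
  out
}

#' Trimming provenance of a spectra set
#'
#' @param x a [spectra_set()].
#' @return list of trimming records (possibly empty).
#' @export
trim_log <- function(x) attr(x, "trim_log") %||% list()

#' Write trimming provenance as a JSON sidecar
#'
#' @param x a trimmed [spectra_set()].
#' @param path JSON file path.
#' @export
write_trim_log <- function(x, path) {
  jsonlite::write_json(trim_log(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
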