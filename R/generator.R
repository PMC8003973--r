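#' Configuration for the synthetic mill dataset generator
#'
#' Defines a simulated campaign of mill samples measured as four
#' sample-preparation types (SS, CSS, DF, RJ) on a two-detector vis-NIR
#' instrument. Defaults emulate a season of 302 mill samples: quality
#' parameters drawn from a multivariate Gaussian with the location, scale,
#' range and correlation structure typical of mill reference data (sugar
#' parameters mutually correlated above 0.94, Fibre essentially
#' uncorrelated), and spectra built from a Beer-Lambert surrogate: each
#' parameter contributes Gaussian absorption bands placed in the overtone
#' regions known to carry sugar and fibre information (~960, 1139, 1360,
#' 1600, 1850-1900 and 2100 nm), plus per-type interference bands,
#' multiplicative scatter, additive baseline and white noise.
#'
#' @param n_samples number of mill samples.
#' @param seed integer seed; the whole dataset is a pure function of the
#'   config including this seed.
#' @param grid_low,grid_high `(start, stop, step)` in nm for the CCD and
#'   InGaAs detector segments; the gap between them is preserved, never
#'   interpolated.
#' @param param_means,param_sds named numeric vectors for the five quality
#'   parameters (Brix, Pol, Fibre %, PolOfCane %, TRS kg/Mg).
#' @param param_ranges 5x2 matrix of admissible bounds; draws are clipped
#'   and the clipped fraction recorded (kept well below 1% by the default
#'   ranges, roughly +/- 3 SD).
#' @param target_corr 5x5 correlation matrix; must be symmetric positive
#'   semi-definite with unit diagonal.
#' @param constituent_bands named list, one element per parameter, each a
#'   matrix with columns `center` (nm), `width` (nm, Gaussian sigma),
#'   `intensity` (absorbance per concentration unit).
#' @param background_bands band matrix (columns `center`, `width`,
#'   `intensity`) of the matrix background common to every sample: the
#'   broad water and cellulose absorption continuum that dominates cane
#'   spectra. Its amplitude varies mildly (2% SD) between samples,
#'   independently of the quality parameters. This background is what makes
#'   SNV meaningful: scatter is removed relative to a stable absorbance
#'   floor rather than relative to the analyte signal itself.
#' @param sample_type_effects named list per sample type with elements
#'   `bands` (interference band matrix as above, amplitudes in absorbance
#'   with 30% between-sample variation) and `noise_scale` (multiplier on
#'   `noise_sd`). Types are the names of this list.
#' @param noise_sd per-band white-noise SD, absorbance units.
#' @param scatter_sd SD of the per-scan multiplicative scatter factor.
#' @param baseline_sd SD of the per-scan additive baseline offset.
#' @param n_replicates successive scans per sample and type (default 9).
#' @param reference_noise_sd optional per-parameter SD of extra measurement
#'   noise added to the reference values; `NULL` (default) adds none.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_samples = 302,
                             seed = 1,
                             grid_low = c(373, 1011, 5),
                             grid_high = c(1170, 2222, 5),
                             param_means = c(Brix = 18.95, Pol = 16.67,
                                             Fibre = 13.29, PolOfCane = 13.80,
                                             TRS = 137.66),
                             param_sds = c(Brix = 1.71, Pol = 1.90,
                                           Fibre = 1.79, PolOfCane = 1.56,
                                           TRS = 14.48),
                             param_ranges = default_param_ranges(),
                             target_corr = default_target_corr(),
                             constituent_bands = default_constituent_bands(),
                             background_bands = default_background_bands(),
                             sample_type_effects = default_sample_type_effects(),
                             noise_sd = 0.002,
                             scatter_sd = 0.02,
                             baseline_sd = 0.01,
                             n_replicates = 9,
                             reference_noise_sd = NULL) {
  params <- names(param_means)
  stopifnot(length(params) >= 1, !is.null(params))
  if (!identical(params, names(param_sds)))
    stopf("param_means and param_sds must share names")
  if (grid_low[3] <= 0 || grid_high[3] <= 0) stopf("grid step must be > 0")
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  if (any(c(noise_sd, scatter_sd, baseline_sd) < 0))
    stopf("noise/scatter/baseline SDs must be >= 0")
  target_corr <- as.matrix(target_corr)
  p <- length(params)
  if (!all(dim(target_corr) == p))
    stopf("target_corr must be %dx%d", p, p)
  if (max(abs(target_corr - t(target_corr))) > 1e-10)
    stopf("target_corr must be symmetric")
  if (max(abs(diag(target_corr) - 1)) > 1e-10)
    stopf("target_corr must have unit diagonal")
  ev <- eigen(target_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stopf(paste("target_corr is not positive semi-definite (smallest",
                "eigenvalue %.3g); supply a valid matrix, e.g. project it to",
                "the nearest PSD correlation matrix yourself -- no silent",
                "repair is applied"), min(ev))
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 grid_low = grid_low, grid_high = grid_high,
                 param_names = params, param_means = param_means,
                 param_sds = param_sds, param_ranges = param_ranges,
                 target_corr = target_corr,
                 constituent_bands = constituent_bands,
                 background_bands = background_bands,
                 sample_type_effects = sample_type_effects,
                 noise_sd = noise_sd, scatter_sd = scatter_sd,
                 baseline_sd = baseline_sd,
                 n_replicates = as.integer(n_replicates),
                 reference_noise_sd = reference_noise_sd),
            class = "generator_config")
}

#' @rdname generator_config
#' @export
default_param_ranges <- function() {
  m <- rbind(Brix = c(13.08, 23.42), Pol = c(10.78, 21.20),
             Fibre = c(7.22, 20.08), PolOfCane = c(8.40, 17.56),
             TRS = c(86.94, 173.80))
  colnames(m) <- c("min", "max")
  m
}

#' @rdname generator_config
#' @export
default_target_corr <- function() {
  r <- matrix(c(1.00, 0.97, 0.05, 0.94, 0.94,
                0.97, 1.00, 0.05, 0.97, 0.96,
                0.05, 0.05, 1.00, 0.05, 0.05,
                0.94, 0.97, 0.05, 1.00, 0.99,
                0.94, 0.96, 0.05, 0.99, 1.00), 5, 5)
  nm <- c("Brix", "Pol", "Fibre", "PolOfCane", "TRS")
  dimnames(r) <- list(nm, nm)
  r
}

band_matrix <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("center", "width", "intensity")
  m
}

#' @rdname generator_config
#' @export
default_constituent_bands <- function() {
  # Band centers follow the overtone regions that dominate sugar and fibre
  # signals; intensities are scaled so each parameter's peak contribution is
  # of order 0.1 absorbance at its mean concentration.
  list(
    Brix      = band_matrix(c(960, 15, 0.004), c(1360, 25, 0.006),
                            c(2100, 30, 0.005)),
    Pol       = band_matrix(c(960, 15, 0.003), c(1139, 20, 0.005),
                            c(1600, 25, 0.006)),
    Fibre     = band_matrix(c(1180, 20, 0.005), c(1875, 30, 0.007)),
    PolOfCane = band_matrix(c(1139, 20, 0.004), c(1600, 25, 0.005),
                            c(2100, 30, 0.004)),
    TRS       = band_matrix(c(960, 15, 0.0005), c(1360, 25, 0.0007),
                            c(2100, 30, 0.0006))
  )
}

#' @rdname generator_config
#' @export
default_background_bands <- function() {
  # water (1450, 1940 nm) and broad cellulose/matrix continuum; amplitudes
  # of order 1 absorbance so the analyte bands ride on a dominant floor
  band_matrix(c(1450, 120, 0.90), c(1940, 140, 1.10),
              c(1150, 300, 0.50), c(2100, 200, 0.60),
              c(850, 250, 0.35))
}

#' @rdname generator_config
#' @export
default_sample_type_effects <- function() {
  list(
    SS  = list(bands = band_matrix(c(1730, 30, 0.05)),  noise_scale = 2.0),
    CSS = list(bands = band_matrix(c(1450, 40, 0.04)),  noise_scale = 1.5),
    DF  = list(bands = band_matrix(c(1930, 40, 0.03)),  noise_scale = 1.2),
    RJ  = list(bands = band_matrix(c(1450, 60, 0.08), c(550, 80, 0.06)),
               noise_scale = 1.0)
  )
}

#' Wavelength grid of a generator config
#'
#' Union of the two detector segments, gap preserved.
#' @param config a [generator_config()].
#' @export
config_grid <- function(config) {
  c(seq(config$grid_low[1], config$grid_low[2], by = config$grid_low[3]),
    seq(config$grid_high[1], config$grid_high[2], by = config$grid_high[3]))
}

#' Generate the per-sample quality reference table
#'
#' Draws the five quality parameters from a multivariate Gaussian with the
#' configured means, SDs and correlation matrix, then clips to the configured
#' ranges. The clipped fraction is attached as attribute `clip_fraction` and
#' a warning is raised if it reaches 1%.
#'
#' @param config a [generator_config()].
#' @return tibble with `sample_id` and one column per parameter.
#' @export
generate_references <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  p <- length(config$param_names)
  L <- chol(config$target_corr)
  vals <- with_seed(derive_seed(config$seed, 101), {
    z <- matrix(stats::rnorm(config$n_samples * p), config$n_samples, p)
    z <- z %*% L
    v <- sweep(sweep(z, 2, config$param_sds, `*`), 2, config$param_means, `+`)
    if (!is.null(config$reference_noise_sd))
      v <- v + matrix(stats::rnorm(length(v), sd = rep(config$reference_noise_sd,
                                                       each = config$n_samples)),
                      nrow = config$n_samples)
    v
  })
  lo <- config$param_ranges[config$param_names, "min"]
  hi <- config$param_ranges[config$param_names, "max"]
  clipped <- sweep(vals, 2, lo, `<`) | sweep(vals, 2, hi, `>`)
  vals <- pmin(pmax(vals, rep(lo, each = nrow(vals))), rep(hi, each = nrow(vals)))
  clip_fraction <- mean(clipped)
  if (clip_fraction >= 0.01)
    warnf("range clipping affected %.2f%% of draws (>= 1%%); widen ranges or shrink SDs",
          100 * clip_fraction)
  colnames(vals) <- config$param_names
  out <- tibble::as_tibble(vals)
  out <- tibble::add_column(out,
                            sample_id = sprintf("S%03d", seq_len(config$n_samples)),
                            .before = 1)
  attr(out, "clip_fraction") <- clip_fraction
  out
}

#' Generate replicate spectra for one sample type
#'
#' Builds, for each sample, a noiseless Beer-Lambert signal (the sum over
#' parameters of concentration times Gaussian band profiles, plus that
#' sample's type-specific interference bands), then produces `n_replicates`
#' scans that share the signal and differ only in multiplicative scatter,
#' additive baseline and white noise.
#'
#' @param config a [generator_config()].
#' @param refs the table from [generate_references()] under the same config.
#' @param sample_type one of the names of `config$sample_type_effects`.
#' @return a [spectra_set()] with `n_samples * n_replicates` rows.
#' @export
generate_spectra <- function(config, refs, sample_type) {
  stopifnot(inherits(config, "generator_config"))
  types <- names(config$sample_type_effects)
  if (!sample_type %in% types)
    stopf("unknown sample type '%s' (configured: %s)", sample_type,
          paste(types, collapse = ", "))
  if (nrow(refs) != config$n_samples)
    stopf("refs has %d rows but config expects %d samples",
          nrow(refs), config$n_samples)
  wl <- config_grid(config)
  n <- config$n_samples
  nrep <- config$n_replicates
  eff <- config$sample_type_effects[[sample_type]]

  # sample signal: constituent bands weighted by concentration
  signal <- matrix(0, n, length(wl))
  for (pn in config$param_names) {
    bands <- config$constituent_bands[[pn]]
    if (is.null(bands)) next
    prof <- band_profile(wl, bands)
    signal <- signal + refs[[pn]] %o% prof
  }

  type_seed <- derive_seed(config$seed, 1000 + match(sample_type, types))
  with_seed(type_seed, {
    # matrix background shared by all samples, with mild (2%) per-sample
    # amplitude variation independent of the quality values
    if (!is.null(config$background_bands) && nrow(config$background_bands) > 0) {
      bg <- band_profile(wl, config$background_bands)
      bg_amp <- 1 + 0.02 * stats::rnorm(n)
      signal <- signal + bg_amp %o% bg
    }
    # per-sample interference amplitude variation (not tied to quality values)
    if (!is.null(eff$bands) && nrow(eff$bands) > 0) {
      for (b in seq_len(nrow(eff$bands))) {
        amp <- eff$bands[b, "intensity"] *
          (1 + 0.3 * stats::rnorm(n))
        prof <- exp(-0.5 * ((wl - eff$bands[b, "center"]) / eff$bands[b, "width"])^2)
        signal <- signal + amp %o% prof
      }
    }
    scatter <- matrix(stats::rnorm(n * nrep, sd = config$scatter_sd), n, nrep)
    baseline <- matrix(stats::rnorm(n * nrep, sd = config$baseline_sd), n, nrep)
    noise_scale <- eff$noise_scale %||% 1
    ab <- matrix(0, n * nrep, length(wl))
    ids <- character(n * nrep)
    reps <- integer(n * nrep)
    row <- 1L
    for (i in seq_len(n)) {
      for (r in seq_len(nrep)) {
        eps <- stats::rnorm(length(wl), sd = config$noise_sd * noise_scale)
        ab[row, ] <- (1 + scatter[i, r]) * signal[i, ] + baseline[i, r] + eps
        ids[row] <- refs$sample_id[i]
        reps[row] <- r
        row <- row + 1L
      }
    }
    spectra_set(wl, ab, ids, sample_type, replicate = reps)
  })
}

band_profile <- function(wl, bands) {
  prof <- numeric(length(wl))
  for (b in seq_len(nrow(bands)))
    prof <- prof + bands[b, "intensity"] *
      exp(-0.5 * ((wl - bands[b, "center"]) / bands[b, "width"])^2)
  prof
}

#' Generate the full study dataset
#'
#' References plus one spectra set per configured sample type.
#'
#' @param config a [generator_config()].
#' @return list with `references` (tibble) and `spectra` (named list of
#'   [spectra_set()]).
#' @export
generate_study <- function(config) {
  refs <- generate_references(config)
  sets <- lapply(names(config$sample_type_effects),
                 function(ty) generate_spectra(config, refs, ty))
  names(sets) <- names(config$sample_type_effects)
  list(references = refs, spectra = sets)
}

#' Read / write a generator config as YAML
#'
#' A YAML file fully determines a synthetic dataset.
#' @param path YAML file.
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  to_bands <- function(x) {
    m <- do.call(rbind, lapply(x, unlist))
    colnames(m) <- c("center", "width", "intensity")
    m
  }
  args <- list()
  for (nm in c("n_samples", "seed", "grid_low", "grid_high", "noise_sd",
               "scatter_sd", "baseline_sd", "n_replicates", "reference_noise_sd"))
    if (!is.null(y[[nm]])) args[[nm]] <- unlist(y[[nm]])
  if (!is.null(y$param_means)) args$param_means <- unlist(y$param_means)
  if (!is.null(y$param_sds)) args$param_sds <- unlist(y$param_sds)
  if (!is.null(y$param_ranges)) {
    m <- do.call(rbind, lapply(y$param_ranges, unlist))
    colnames(m) <- c("min", "max")
    args$param_ranges <- m
  }
  if (!is.null(y$target_corr))
    args$target_corr <- do.call(rbind, lapply(y$target_corr, unlist))
  if (!is.null(y$constituent_bands))
    args$constituent_bands <- lapply(y$constituent_bands, to_bands)
  if (!is.null(y$background_bands))
    args$background_bands <- to_bands(y$background_bands)
  if (!is.null(y$sample_type_effects))
    args$sample_type_effects <- lapply(y$sample_type_effects, function(e)
      list(bands = to_bands(e$bands), noise_scale = e$noise_scale))
  if (!is.null(args$target_corr))
    dimnames(args$target_corr) <- list(names(args$param_means),
                                       names(args$param_means))
  do.call(generator_config, args)
}

#' @rdname read_generator_config
#' @param config a [generator_config()].
#' @export
write_generator_config <- function(config, path) {
  y <- unclass(config)
  y$param_means <- as.list(config$param_means)   # keep names in YAML maps
  y$param_sds <- as.list(config$param_sds)
  y$param_ranges <- apply(config$param_ranges, 1, as.list, simplify = FALSE)
  y$target_corr <- apply(config$target_corr, 1, as.list, simplify = FALSE)
  y$constituent_bands <- lapply(config$constituent_bands, function(m)
    apply(m, 1, as.list, simplify = FALSE))
  y$background_bands <- apply(config$background_bands, 1, as.list,
                              simplify = FALSE)
  y$sample_type_effects <- lapply(config$sample_type_effects, function(e)
    list(bands = apply(e$bands, 1, as.list, simplify = FALSE),
         noise_scale = e$noise_scale))
  yaml::write_yaml(y, path)
  invisible(path)
}
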