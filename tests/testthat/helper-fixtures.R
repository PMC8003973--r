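# Shared fixtures and independent oracles. Everything is generated in code;
# no data files.

# Small default-structure generator config for quick end-to-end runs.
small_config <- function(n_samples = 40, n_replicates = 3, seed = 42, ...) {
  generator_config(n_samples = n_samples, n_replicates = n_replicates,
                   seed = seed, ...)
}

# Single-constituent config: one quality parameter, one absorption band,
# optional noise terms, no type-specific interference.
single_param_config <- function(n_samples = 30, seed = 7,
                                band = c(1500, 30, 0.01),
                                noise_sd = 0, scatter_sd = 0, baseline_sd = 0,
                                background = FALSE,
                                n_replicates = 1) {
  generator_config(
    n_samples = n_samples, seed = seed,
    param_means = c(Sugar = 15), param_sds = c(Sugar = 2),
    param_ranges = matrix(c(5, 25), 1, 2,
                          dimnames = list("Sugar", c("min", "max"))),
    target_corr = matrix(1, 1, 1, dimnames = list("Sugar", "Sugar")),
    constituent_bands = list(Sugar = matrix(band, 1, 3,
      dimnames = list(NULL, c("center", "width", "intensity")))),
    background_bands = if (background) default_background_bands() else
      matrix(numeric(0), 0, 3,
             dimnames = list(NULL, c("center", "width", "intensity"))),
    sample_type_effects = list(
      PLAIN = list(bands = matrix(numeric(0), 0, 3,
        dimnames = list(NULL, c("center", "width", "intensity"))),
        noise_scale = 1)),
    noise_sd = noise_sd, scatter_sd = scatter_sd, baseline_sd = baseline_sd,
    n_replicates = n_replicates)
}

# Independent Savitzky-Golay oracle: least-squares quadratic (or higher) fit
# in each window, one-sided at the edges, evaluated at the window point.
sg_polyfit_oracle <- function(x, window = 11, polyorder = 2) {
  k <- (window - 1) / 2
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- if (i <= k) 1:window else if (i > n - k) (n - window + 1):n
           else (i - k):(i + k)
    fit <- lm.fit(outer(idx - i, 0:polyorder, `^`), x[idx])
    out[i] <- 2 * fit$coefficients[3]
  }
  out
}

# Independent Kennard-Stone oracle: literal max-min rule with explicit loops.
ks_oracle <- function(x, fraction) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) d[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  n_cal <- ceiling(fraction * n)
  pair <- c(1, 2); best <- -Inf
  for (i in 1:n) for (j in 1:n) if (i < j && d[i, j] > best) {
    best <- d[i, j]; pair <- c(i, j)
  }
  sel <- pair
  while (length(sel) < n_cal) {
    best <- -Inf; nxt <- NA
    for (i in setdiff(1:n, sel)) {
      mi <- min(d[i, sel])
      if (mi > best) { best <- mi; nxt <- i }
    }
    sel <- c(sel, nxt)
  }
  list(calibration = sel, validation = setdiff(1:n, sel))
}

# A small preprocessed regression fixture with known low-rank structure.
low_rank_fixture <- function(n = 40, p = 25, n_factors = 1, noise = 0,
                             seed = 5) {
  set.seed(seed)
  scores <- matrix(rnorm(n * n_factors), n, n_factors)
  load <- matrix(rnorm(n_factors * p), n_factors, p)
  X <- scores %*% load + matrix(rnorm(n * p, sd = noise), n, p)
  y <- drop(scores %*% seq_len(n_factors)) + rnorm(n, sd = noise)
  list(X = X, y = y)
}
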