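#' Study configuration
#'
#' Collects every stage parameter of the end-to-end calibration study. All
#' defaults are the study conditions: 75/25 Kennard-Stone split,
#' venetian-blinds cross-validation with 10 splits, Savitzky-Golay window 11
#' / order 2 / second derivative, significance level 0.05 throughout, and
#' the visible-region cutoff at 699 nm.
#'
#' @param generator a [generator_config()] describing the synthetic dataset
#'   (or `NULL` when `spectra_paths`/`references_path` are given).
#' @param spectra_paths named list of per-type wide CSV paths (alternative
#'   to `generator`).
#' @param references_path CSV of reference values with a `sample_id` column.
#' @param sample_types types to model, default `c("SS","CSS","DF","RJ")`.
#' @param attributes quality parameters to model; Fibre is never modelled
#'   from RJ (fibre cannot be measured in raw juice).
#' @param fraction Kennard-Stone calibration fraction.
#' @param splits venetian-blinds folds.
#' @param trim_cutoff_low visible-region cutoff, nm.
#' @param cv_trim_threshold multiple of the median CV for tail trimming.
#' @param sg_window,sg_polyorder Savitzky-Golay settings.
#' @param max_lv largest component count screened in cross-validation.
#' @param outlier_lv provisional component count for the outlier loop.
#' @param alpha significance level (outliers, LV selection, comparisons).
#' @param n_perm permutations for the randomization tests.
#' @param max_outlier_iter cap on outlier-loop iterations.
#' @param r2_method `"pearson"` (default) or `"ss"`.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return object of class `study_config`.
#' @export
study_config <- function(generator = generator_config(),
                         spectra_paths = NULL,
                         references_path = NULL,
                         sample_types = c("SS", "CSS", "DF", "RJ"),
                         attributes = c("Brix", "Pol", "Fibre", "PolOfCane", "TRS"),
                         fraction = 0.75,
                         splits = 10,
                         trim_cutoff_low = 699,
                         cv_trim_threshold = 5,
                         sg_window = 11,
                         sg_polyorder = 2,
                         max_lv = 15,
                         outlier_lv = 10,
                         alpha = 0.05,
                         n_perm = 19999,
                         max_outlier_iter = 3,
                         r2_method = "pearson",
                         seed = 1,
                         out_dir = NULL) {
  structure(list(generator = generator, spectra_paths = spectra_paths,
                 references_path = references_path,
                 sample_types = sample_types, attributes = attributes,
                 fraction = fraction, splits = splits,
                 trim_cutoff_low = trim_cutoff_low,
                 cv_trim_threshold = cv_trim_threshold,
                 sg_window = sg_window, sg_polyorder = sg_polyorder,
                 max_lv = max_lv, outlier_lv = outlier_lv, alpha = alpha,
                 n_perm = n_perm, max_outlier_iter = max_outlier_iter,
                 r2_method = r2_method, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "study_config")
}

#' Descriptive statistics of reference values
#'
#' Mean, SD, median, range and quartiles per quality parameter, the summary
#' conventionally reported for the full set and each split.
#'
#' @param refs reference tibble (with `sample_id`).
#' @param attributes columns to summarise.
#' @param subset_name label for the `set` column.
#' @export
descriptive_stats <- function(refs, attributes, subset_name = "all") {
  rows <- lapply(attributes, function(a) {
    v <- refs[[a]]
    qs <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    tibble::tibble(set = subset_name, parameter = a, n = length(v),
                   mean = mean(v), sd = stats::sd(v),
                   median = stats::median(v),
                   min = min(v), max = max(v), p25 = qs[1], p75 = qs[2])
  })
  do.call(rbind, rows)
}

#' Run the full calibration study
#'
#' Executes the complete procedure: generate (or read) the four sample-type
#' spectra and references; average replicate scans; trim the visible region
#' and the unstable high-wavelength tail; apply SNV and the Savitzky-Golay
#' second derivative; concatenate the four types and split once by
#' Kennard-Stone so every type shares the same calibration and validation
#' samples; then, per sample type and attribute, run the calibration outlier
#' loop, venetian-blinds cross-validation, significance-based component
#' selection, the final fit, external validation metrics and the VIP
#' profile; and finally compare every pair of sample types with the
#' randomization test. Validation rows never influence preprocessing
#' statistics, outlier removal or component choice.
#'
#' @param config a [study_config()].
#' @return object of class `study_result`: `descriptive` (per-split summary
#'   table), `report` (one row per type x attribute: LV, RMSEC, RMSECV,
#'   RMSEP, R2c, R2p, RPIQ, outliers removed), `pvalues` (pairwise
#'   comparison tables per attribute), `vip` (tidy VIP table), `pca`
#'   (exploratory overview), `predictions`, `split`, `models`, and
#'   `provenance`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  types <- config$sample_types

  # ---- data ----
  if (!is.null(config$spectra_paths)) {
    sets <- lapply(config$spectra_paths[types], read_spectra)
    refs <- tibble::as_tibble(utils::read.csv(config$references_path))
  } else {
    study <- generate_study(config$generator)
    sets <- study$spectra[types]
    refs <- study$references
  }
  for (a in config$attributes)
    if (is.null(refs[[a]])) stopf("reference table lacks column '%s'", a)

  # ---- replicate averaging, trimming, row preprocessing ----
  sets <- lapply(sets, function(s) {
    if (!is.null(s$replicate)) s <- average_replicates(s)
    s <- trim_visible(s, config$trim_cutoff_low)
    trim_high_cv(s, config$cv_trim_threshold, tail_only = TRUE)
  })
  pca <- pca_overview_safe(sets)
  pre <- lapply(sets, preprocess_spectra,
                window = config$sg_window, polyorder = config$sg_polyorder)

  # ---- one Kennard-Stone split on the concatenated types ----
  concat <- concatenate_types(pre)
  refs <- refs[match(rownames(concat), refs$sample_id), ]
  split <- kennard_stone(concat, config$fraction)
  cal_ids <- rownames(concat)[split$calibration]   # selection order
  val_ids <- rownames(concat)[split$validation]

  descriptive <- rbind(
    descriptive_stats(refs, config$attributes, "all"),
    descriptive_stats(refs[match(cal_ids, refs$sample_id), ],
                      config$attributes, "calibration"),
    descriptive_stats(refs[match(val_ids, refs$sample_id), ],
                      config$attributes, "validation"))

  # ---- per (type, attribute) modelling ----
  report <- list(); vip_rows <- list(); models <- list(); predictions <- list()
  for (ty in types) {
    Xty <- pre[[ty]]$absorbance[match(rownames(concat), pre[[ty]]$sample_ids), ,
                                drop = FALSE]
    rownames(Xty) <- rownames(concat)
    Xcal <- Xty[match(cal_ids, rownames(Xty)), , drop = FALSE]
    Xval <- Xty[match(val_ids, rownames(Xty)), , drop = FALSE]
    for (attr_name in config$attributes) {
      if (attr_name == "Fibre" && ty == "RJ") next  # not measurable in raw juice
      ycal <- refs[[attr_name]][match(cal_ids, refs$sample_id)]
      yval <- refs[[attr_name]][match(val_ids, refs$sample_id)]

      loop <- outlier_loop(Xcal, ycal, n_lv = config$outlier_lv,
                           alpha = config$alpha,
                           max_iter = config$max_outlier_iter,
                           sample_ids = cal_ids)
      cv <- cross_validate(loop$x, loop$y,
                           max_lv = min(config$max_lv, nrow(loop$x) - 2,
                                        ncol(loop$x)),
                           splits = config$splits)
      n_lv <- select_lv(cv, alpha = config$alpha,
                        seed = derive_seed(config$seed, 500 +
                                             match(ty, types) * 10 +
                                             match(attr_name, config$attributes)))
      model <- fit_pls(loop$x, loop$y, n_lv, sample_ids = loop$kept_ids)
      model$x_cal <- loop$x

      yhat_cal <- predict(model, loop$x)
      yhat_val <- predict(model, Xval)
      mc <- prediction_metrics(loop$y, yhat_cal, r2_method = config$r2_method)
      mp <- prediction_metrics(yval, yhat_val, quartiles_source = yval,
                               r2_method = config$r2_method)
      key <- paste(ty, attr_name, sep = ".")
      models[[key]] <- model
      predictions[[key]] <- tibble::tibble(sample_id = val_ids,
                                           y = yval, y_pred = yhat_val)
      report[[key]] <- tibble::tibble(
        attribute = attr_name, sample_type = ty, n_lv = n_lv,
        rmsec = mc$rmse, rmsecv = cv$rmsecv[n_lv], rmsep = mp$rmse,
        r2c = mc$r2, r2p = mp$r2, rpiq = mp$rpiq,
        n_outliers_removed = loop$n_removed)
      vp <- vip(model, wavelengths = pre[[ty]]$wavelengths)
      vip_rows[[key]] <- tibble::tibble(
        attribute = attr_name, sample_type = ty,
        wavelength = pre[[ty]]$wavelengths, vip = vp$vip,
        category = vp$category)
    }
  }
  report <- do.call(rbind, report)
  vip_table <- do.call(rbind, vip_rows)

  # ---- pairwise accuracy comparisons per attribute ----
  pvalues <- list()
  for (attr_name in config$attributes) {
    preds <- lapply(types, function(ty) {
      key <- paste(ty, attr_name, sep = ".")
      if (is.null(predictions[[key]])) NULL else predictions[[key]]$y_pred
    })
    names(preds) <- types
    yval <- refs[[attr_name]][match(val_ids, refs$sample_id)]
    tab <- pairwise_comparison_table(preds, yval, types = types,
                                     n_perm = config$n_perm,
                                     seed = derive_seed(config$seed, 900 +
                                                          match(attr_name,
                                                                config$attributes)))
    tab <- tibble::add_column(tab, attribute = attr_name, .before = 1)
    pvalues[[attr_name]] <- tab
  }
  pvalues <- do.call(rbind, pvalues)

  provenance <- list(
    package_version = as.character(utils::packageVersion("canespec")),
    seed = config$seed,
    config_hash = config_fingerprint(paste(deparse(unclass(config)), collapse = "")),
    n_samples = nrow(refs), n_calibration = length(cal_ids),
    n_validation = length(val_ids),
    trim_log = lapply(sets, trim_log))

  result <- structure(list(descriptive = descriptive, report = report,
                           pvalues = pvalues, vip = vip_table, pca = pca,
                           predictions = predictions, models = models,
                           split = list(calibration = cal_ids,
                                        validation = val_ids),
                           provenance = provenance, config = config),
                      class = "study_result")
  if (!is.null(config$out_dir)) write_study_result(result, config$out_dir)
  result
}

pca_overview_safe <- function(sets) {
  grids_match <- all(vapply(sets, function(s)
    length(s$wavelengths) == length(sets[[1]]$wavelengths) &&
      max(abs(s$wavelengths - sets[[1]]$wavelengths)) < 1e-6, logical(1)))
  if (!grids_match) return(NULL)
  pca_overview(sets)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d samples (%d cal / %d val), %d models\n",
              x$provenance$n_samples, x$provenance$n_calibration,
              x$provenance$n_validation, nrow(x$report)))
  print(x$report, n = nrow(x$report))
  invisible(x)
}

#' Write study artifacts
#'
#' Writes the descriptive, model-report, p-value and VIP tables as CSV, the
#' PCA overview (when computed) as CSV, and a provenance JSON (config hash,
#' seed, split sizes, trim log) into `dir`. Metric tables keep full
#' precision; round for display only.
#'
#' @param result a [run_study()] result.
#' @param dir output directory (created if needed).
#' @export
write_study_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$descriptive, file.path(dir, "descriptive_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(result$report, file.path(dir, "model_report.csv"),
                   row.names = FALSE)
  utils::write.csv(result$pvalues, file.path(dir, "pairwise_pvalues.csv"),
                   row.names = FALSE)
  utils::write.csv(result$vip, file.path(dir, "vip_profiles.csv"),
                   row.names = FALSE)
  if (!is.null(result$pca)) {
    pca_df <- data.frame(sample_id = result$pca$sample_ids,
                         sample_type = result$pca$sample_type,
                         result$pca$scores)
    utils::write.csv(pca_df, file.path(dir, "pca_overview.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read / write a study config as YAML
#'
#' Only scalar stage parameters and the generator config are serialized;
#' path-based inputs round-trip as given.
#' @param path YAML file.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- if (!is.null(y$generator_file)) {
    gf <- y$generator_file
    if (!file.exists(gf)) gf <- file.path(dirname(path), gf)
    read_generator_config(gf)
  } else generator_config()
  args <- y[setdiff(names(y), "generator_file")]
  args$generator <- gen
  do.call(study_config, args)
}

#' @rdname read_study_config
#' @param config a [study_config()].
#' @param generator_file optional path where the generator config is written
#'   as its own YAML.
#' @export
write_study_config <- function(config, path, generator_file = NULL) {
  y <- unclass(config)
  y$generator <- NULL
  if (!is.null(generator_file) && !is.null(config$generator)) {
    write_generator_config(config$generator, generator_file)
    y$generator_file <- generator_file
  }
  y <- y[!vapply(y, is.null, logical(1))]
  yaml::write_yaml(y, path)
  invisible(path)
}
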