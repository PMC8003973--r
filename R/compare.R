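#' Randomization test for equal prediction accuracy
#'
#' Distribution-free paired comparison of two models' prediction errors on
#' the same validation samples. The statistic is the mean paired difference
#' of squared errors, `mean(e1^2 - e2^2)` (absolute errors via
#' `method = "absolute"`). Under the null hypothesis that the two models are
#' equally accurate, the sign of each paired difference is exchangeable, so
#' the null distribution is built by flipping each difference's sign
#' independently with probability 1/2: exhaustively over all `2^n` patterns
#' when `n <= 15`, otherwise by `n_perm` seed-pinned Monte-Carlo draws. The
#' two-sided p-value uses the add-one correction
#' `(#(|stat*| >= |stat|) + 1) / (N + 1)`.
#'
#' @param e1,e2 paired per-sample prediction errors (same validation
#'   samples, two models); equal length `n >= 2`.
#' @param n_perm Monte-Carlo permutations when exhaustive enumeration is not
#'   feasible; at least 100.
#' @param seed seed for the Monte-Carlo draws.
#' @param method `"squared"` (default) or `"absolute"` error differences.
#' @param alpha significance level for the reported decision.
#' @param force_monte_carlo use Monte-Carlo draws even when exhaustive
#'   enumeration would be feasible (mainly for validating the Monte-Carlo
#'   approximation against the exact null).
#' @return object of class `rand_test` with `statistic`, `p_value`,
#'   `n_permutations`, `exhaustive`, `alpha` and `decision`
#'   (`"similar"` / `"not similar"`).
#' @export
randomization_test <- function(e1, e2, n_perm = 19999, seed = 1,
                               method = c("squared", "absolute"),
                               alpha = 0.05, force_monte_carlo = FALSE) {
  method <- match.arg(method)
  if (length(e1) != length(e2)) stopf("error vectors differ in length")
  n <- length(e1)
  if (n < 2) stopf("need at least 2 paired errors")
  if (n_perm < 100) stopf("n_perm must be at least 100")
  d <- if (method == "squared") e1^2 - e2^2 else abs(e1) - abs(e2)
  stat <- mean(d)
  tol <- 1e-12 * max(1, mean(abs(d)))
  if (n <= 15 && !force_monte_carlo) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stats_null <- as.numeric(signs %*% d) / n
    N <- nrow(signs)
    exhaustive <- TRUE
  } else {
    stats_null <- with_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
      as.numeric(crossprod(signs, d)) / n
    })
    N <- n_perm
    exhaustive <- FALSE
  }
  count <- sum(abs(stats_null) >= abs(stat) - tol)
  p <- (count + 1) / (N + 1)
  structure(list(statistic = stat, p_value = p, n_permutations = N,
                 exhaustive = exhaustive, alpha = alpha,
                 method = method,
                 decision = if (p < alpha) "not similar" else "similar"),
            class = "rand_test")
}

#' @export
print.rand_test <- function(x, ...) {
  cat(sprintf("Randomization test (%s errors, %s): stat = %.4g, p = %.4g -> %s\n",
              x$method, if (x$exhaustive) "exhaustive" else
                sprintf("%d permutations", x$n_permutations),
              x$statistic, x$p_value, x$decision))
  invisible(x)
}

#' Pairwise accuracy comparison across sample types
#'
#' Runs the randomization test for every unordered pair of sample types on
#' their shared validation predictions of one attribute, producing one row
#' per binary combination. Pairs for which either type has no model (e.g.
#' Fibre from raw juice) get `NA`.
#'
#' @param predictions named list, one numeric prediction vector per sample
#'   type (aligned to `y_val`); `NULL` entries are skipped.
#' @param y_val validation reference values.
#' @param types type order for the combinations (default: fixed mill order
#'   SS, CSS, DF, RJ restricted to names present).
#' @param ... passed to [randomization_test()].
#' @return tibble with `pair`, `type1`, `type2`, `statistic`, `p_value`.
#' @export
pairwise_comparison_table <- function(predictions, y_val, types = NULL, ...) {
  order_pref <- c("SS", "CSS", "DF", "RJ")
  nm <- names(predictions)
  types <- types %||% c(intersect(order_pref, nm), setdiff(nm, order_pref))
  combos <- utils::combn(types, 2)
  rows <- lapply(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    pa <- predictions[[a]]; pb <- predictions[[b]]
    if (is.null(pa) || is.null(pb))
      return(tibble::tibble(pair = paste(a, "vs.", b), type1 = a, type2 = b,
                            statistic = NA_real_, p_value = NA_real_))
    rt <- randomization_test(y_val - pa, y_val - pb, ...)
    tibble::tibble(pair = paste(a, "vs.", b), type1 = a, type2 = b,
                   statistic = rt$statistic, p_value = rt$p_value)
  })
  do.call(rbind, rows)
}
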