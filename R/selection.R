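#' Mean squared residual of a series around its block means
#'
#' The benchmark error metric: the mean over all points of the squared
#' difference between the signal and the mean of its own block,
#' `(1/n) sum_i (x_i - mean(block of i))^2`. It equals the `dp2` cumulative
#' score of the partition divided by `n`. No square root is taken: this is
#' an MSE, not an RMSE.
#'
#' @param values Numeric vector, all finite.
#' @param partition A `qcseg_partition` covering the series.
#' @return A single nonnegative number.
#' @examples
#' partition_error(c(1, 2, 6, 7), new_partition(2, 4))  # 0.25
#' @export
partition_error <- function(values, partition) {
  stopifnot(inherits(partition, "qcseg_partition"))
  x <- check_values(values)
  if (length(x) != partition$n) {
    stop("partition was built for n = ", partition$n,
         " but `values` has length ", length(x), call. = FALSE)
  }
  fitted <- fitted_step(x, partition)
  mean((x - fitted)^2)
}

# Step function of block means, evaluated at every index.
fitted_step <- function(values, partition) {
  b <- partition$blocks
  means <- purrr::map2_dbl(b$start, b$end, ~ mean(values[.x:.y]))
  rep(means, b$length)
}

block_of <- function(partition) {
  rep(seq_len(partition$n_blocks), partition$blocks$length)
}

#' Error as a function of the number of change points
#'
#' For each candidate change-point count `m`, fits the optimal
#' `(m + 1)`-block partition and records [partition_error()]. With the
#' default `dp2` scoring the optimum minimises exactly this error, so the
#' curve is non-increasing in `m`; other scorings optimise a different cost
#' and their error curves may not be monotone.
#'
#' @param values Numeric vector.
#' @param m_range Integer vector of change-point counts (e.g. `1:15`).
#' @param method A method name from [score_methods()].
#' @param min_seg_len Minimum block length.
#' @return A tibble with columns `m`, `K`, `error`, `score` and a
#'   list-column `change_points`.
#' @export
error_curve <- function(values, m_range = 1:15, method = "dp2",
                        min_seg_len = 2L) {
  x <- check_values(values)
  method <- match_score_method(method)
  m_range <- sort(unique(as.integer(m_range)))
  if (any(m_range < 0L)) stop("`m_range` must be nonnegative", call. = FALSE)
  k_max <- max(m_range) + 1L
  if (k_max * min_seg_len > length(x)) {
    stop("infeasible: largest K * min_seg_len exceeds series length",
         call. = FALSE)
  }
  cost <- segment_cost_matrix(x, method, min_seg_len)
  tab <- dp_fill(cost, k_max, min_seg_len)
  rows <- purrr::map(m_range, function(m) {
    part <- backtrack(tab, m + 1L)
    tibble::tibble(
      m = m,
      K = m + 1L,
      error = partition_error(x, part),
      score = tab$opt[m + 1L, length(x)],
      change_points = list(part$change_points)
    )
  })
  dplyr::bind_rows(rows)
}

#' Choose the number of change points by BIC
#'
#' Scans change-point counts `m = 0..m_max`, fits the optimal partition at
#' each, and scores each fit with a Bayesian Information Criterion for the
#' Gaussian piecewise-constant-mean model:
#' `BIC(m) = n * log(RSS_m / n) + p(m) * log(n)`.
#' The selected `m_hat` minimises the criterion.
#'
#' Two penalties are offered. The default, `penalty = "mbic"`, uses
#' `p(m) = 3m + 2`: each change point costs `3 * log(n)` on the deviance
#' scale — 1 for the extra segment mean and 2 for its location, because a
#' change-point location is not a regular parameter and carries a higher
#' asymptotic cost (the modified-BIC argument of the change-point
#' literature). `penalty = "bic"` uses the naive parameter count
#' `p(m) = 2m + 2` (`m` locations, `m + 1` means, one variance); it is
#' known to over-segment noisy series and is provided for comparison.
#'
#' RSS is floored at `1e-12 * n * var(x)` (absolute `1e-12` for a constant
#' series) to keep the log finite on noiseless data; an all-constant series
#' returns `m_hat = 0` with `degenerate = TRUE`.
#'
#' @param values Numeric vector of length >= 4.
#' @param m_max Largest change-point count considered (default 15).
#' @param method A method name from [score_methods()]; the partition is
#'   fitted under this scoring, while RSS in the BIC is always the squared
#'   residual around block means.
#' @param min_seg_len Minimum block length.
#' @param penalty `"mbic"` (default) or `"bic"`, see Details.
#' @return An object of class `qcseg_bic`: a list with `curve` (tibble with
#'   `m`, `K`, `rss`, `bic`, list-column `change_points`), `m_hat`,
#'   `partition` (the selected `qcseg_partition`) and `degenerate`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(30, 0), rnorm(30, 8))
#' bic_select(x, m_max = 5)$m_hat  # 1
#' @export
bic_select <- function(values, m_max = 15L, method = "dp2", min_seg_len = 2L,
                       penalty = c("mbic", "bic")) {
  penalty <- match.arg(penalty)
  x <- check_values(values)
  n <- length(x)
  if (n < 4L) stop("BIC selection needs at least 4 points", call. = FALSE)
  m_max <- as.integer(m_max)
  m_max <- min(m_max, n %/% as.integer(min_seg_len) - 1L)
  if (m_max < 0L) stop("infeasible `min_seg_len` for this series", call. = FALSE)

  vx <- stats::var(x)
  degenerate <- vx == 0
  eps <- if (degenerate) 1e-12 else 1e-12 * n * vx

  cost <- segment_cost_matrix(x, method, min_seg_len)
  tab <- dp_fill(cost, m_max + 1L, min_seg_len)
  m_vals <- 0:m_max
  parts <- purrr::map(m_vals, ~ backtrack(tab, .x + 1L))
  rss <- purrr::map_dbl(parts, ~ partition_error(x, .x) * n)
  p_m <- if (penalty == "mbic") 3 * m_vals + 2 else 2 * m_vals + 2
  bic <- n * log(pmax(rss, eps) / n) + p_m * log(n)
  m_hat <- if (degenerate) 0L else m_vals[which.min(bic)]

  structure(
    list(
      curve = tibble::tibble(
        m = m_vals, K = m_vals + 1L, rss = rss, bic = bic,
        change_points = purrr::map(parts, "change_points")
      ),
      m_hat = m_hat,
      partition = parts[[m_hat + 1L]],
      degenerate = degenerate
    ),
    class = "qcseg_bic"
  )
}

#' @export
print.qcseg_bic <- function(x, ...) {
  cat("<qcseg_bic> m_hat =", x$m_hat,
      if (x$degenerate) "(degenerate: constant series)" else "", "\n")
  print(x$curve)
  invisible(x)
}

#' Residual-bootstrap confidence intervals for change-point positions
#'
#' Resamples the residuals around the fitted step function (with
#' replacement, pooled over the whole series), adds them back to the step
#' function, re-estimates the partition at the same number of blocks, and
#' returns percentile bounds for each change-point position. Replicates are
#' paired with the original change points by rank (the refit has the same
#' number of change points by construction). Bounds are clamped to contain
#' the point estimate, so `ci_low <= position <= ci_high` always holds.
#'
#' @param values Numeric vector.
#' @param partition A fitted `qcseg_partition` for `values`.
#' @param n_boot Number of bootstrap replicates (default 1000, minimum 100).
#' @param level Coverage level of the percentile interval (default 0.95).
#' @param seed Integer seed; the result is reproducible given the seed.
#' @param method,min_seg_len Refitting options, matching the original fit.
#' @return A tibble with columns `change_point`, `position`, `ci_low`,
#'   `ci_high`.
#' @export
bootstrap_ci <- function(values, partition, n_boot = 1000L, level = 0.95,
                         seed = NULL, method = "dp2", min_seg_len = 2L) {
  stopifnot(inherits(partition, "qcseg_partition"))
  x <- check_values(values)
  if (length(x) != partition$n) {
    stop("partition/series length mismatch", call. = FALSE)
  }
  n_boot <- as.integer(n_boot)
  if (n_boot < 100L) stop("`n_boot` must be >= 100", call. = FALSE)
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  m <- length(partition$change_points)
  if (m == 0L) {
    return(tibble::tibble(change_point = integer(0), position = integer(0),
                          ci_low = integer(0), ci_high = integer(0)))
  }

  step <- fitted_step(x, partition)
  resid <- x - step
  K <- partition$n_blocks
  n <- length(x)

  draw <- function() {
    xb <- step + sample(resid, n, replace = TRUE)
    sort(optimal_partition(xb, K, method, min_seg_len)$partition$change_points)
  }
  reps <- if (is.null(seed)) {
    purrr::map(seq_len(n_boot), ~ draw())
  } else {
    withr::with_seed(as.integer(seed), purrr::map(seq_len(n_boot), ~ draw()))
  }
  reps <- do.call(rbind, reps)          # n_boot x m, ranks aligned

  alpha <- (1 - level) / 2
  lo <- apply(reps, 2L, stats::quantile, probs = alpha, type = 1)
  hi <- apply(reps, 2L, stats::quantile, probs = 1 - alpha, type = 1)
  tibble::tibble(
    change_point = seq_len(m),
    position = partition$change_points,
    ci_low = as.integer(pmin(lo, partition$change_points)),
    ci_high = as.integer(pmax(hi, partition$change_points))
  )
}

#' Per-interval summary statistics
#'
#' Mean, sample standard deviation (0 for a single-point block) and size of
#' each block of a partition, with first/last timestamps when available.
#'
#' @param values Numeric vector.
#' @param partition A `qcseg_partition` covering the series.
#' @param timestamps Optional vector of dates (same length as `values`).
#' @return A tibble with columns `block`, `start`, `end`, `n`, `mean`,
#'   `sd`, `median`, and `date_start`/`date_end` when timestamps are given.
#' @export
interval_stats <- function(values, partition, timestamps = NULL) {
  stopifnot(inherits(partition, "qcseg_partition"))
  x <- check_values(values)
  if (length(x) != partition$n) {
    stop("partition/series length mismatch", call. = FALSE)
  }
  if (!is.null(timestamps) && length(timestamps) != length(x)) {
    stop("`timestamps` must match the series length", call. = FALSE)
  }
  b <- partition$blocks
  out <- tibble::tibble(
    block = b$block,
    start = b$start,
    end = b$end,
    n = b$length,
    mean = purrr::map2_dbl(b$start, b$end, ~ mean(x[.x:.y])),
    sd = purrr::map2_dbl(b$start, b$end,
                         ~ if (.y > .x) stats::sd(x[.x:.y]) else 0),
    median = purrr::map2_dbl(b$start, b$end, ~ stats::median(x[.x:.y]))
  )
  if (!is.null(timestamps)) {
    out$date_start <- timestamps[b$start]
    out$date_end <- timestamps[b$end]
  }
  out
}

#' Per-change-point report
#'
#' One row per change point: position, confidence bounds, medians and means
#' of the flanking intervals, and the correction percentage
#' `(mean of the interval after the change point / mean of the FIRST
#' interval) * 100` — the relative signal level each new regime settles at,
#' referenced to the initial operating level.
#'
#' @param values Numeric vector.
#' @param partition A `qcseg_partition` covering the series.
#' @param cis Optional tibble from [bootstrap_ci()]; if `NULL`, the CI
#'   columns collapse to the point estimate.
#' @param timestamps Optional date vector; adds a `date` column.
#' @return A tibble with columns `ch_pt`, `ci_low`, `ci_high`,
#'   `median_before`, `median_after`, `mean_from`, `mean_to`,
#'   `correction_pct` (plus `date` when timestamps are given).
#' @examples
#' change_report(c(2, 2, 4, 4), new_partition(2, 4))
#' @export
change_report <- function(values, partition, cis = NULL, timestamps = NULL) {
  stopifnot(inherits(partition, "qcseg_partition"))
  x <- check_values(values)
  stats <- interval_stats(x, partition, timestamps)
  m <- length(partition$change_points)
  if (m == 0L) {
    out <- tibble::tibble(
      ch_pt = integer(0), ci_low = integer(0), ci_high = integer(0),
      median_before = double(0), median_after = double(0),
      mean_from = double(0), mean_to = double(0), correction_pct = double(0)
    )
    if (!is.null(timestamps)) out$date <- timestamps[integer(0)]
    return(out)
  }
  first_mean <- stats$mean[1L]
  if (first_mean == 0) {
    stop("correction percentage undefined: first interval has zero mean",
         call. = FALSE)
  }
  cp <- partition$change_points
  out <- tibble::tibble(
    ch_pt = cp,
    ci_low = if (is.null(cis)) cp else as.integer(cis$ci_low),
    ci_high = if (is.null(cis)) cp else as.integer(cis$ci_high),
    median_before = stats$median[seq_len(m)],
    median_after = stats$median[seq_len(m) + 1L],
    mean_from = stats$mean[seq_len(m)],
    mean_to = stats$mean[seq_len(m) + 1L],
    correction_pct = stats$mean[seq_len(m) + 1L] / first_mean * 100
  )
  if (!is.null(timestamps)) out$date <- timestamps[cp]
  out
}
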