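#' Detect change points in a QC time series
#'
#' The main entry point: takes a data frame (one row per measurement, in
#' acquisition order), segments the signal by exact dynamic programming,
#' picks the number of change points by BIC unless given manually,
#' bootstraps confidence intervals for the change-point locations, and
#' assembles the per-change-point report and per-interval statistics.
#'
#' Detection operates on sequence order only; dates, when present, are
#' carried through as metadata (irregular sampling does not affect the
#' block scores, which are computed over consecutive indices).
#'
#' @param data A data frame with at least a value column, or a bare numeric
#'   vector.
#' @param value Name of the signal column (default `"value"`).
#' @param date Optional name of a date/timestamp column.
#' @param n_changepoints Change-point count; `NULL` (default) selects it by
#'   BIC over `0:m_max`.
#' @param score Scoring method, one of [score_methods()] (default `"dp2"`).
#' @param min_seg_len Minimum segment length (default 2).
#' @param m_max Largest change-point count scanned by BIC (default 15).
#' @param penalty BIC penalty variant, `"mbic"` (default) or `"bic"`; see
#'   [bic_select()].
#' @param n_boot Bootstrap replicates for the location CIs (default 1000;
#'   set to 0 to skip the bootstrap).
#' @param ci_level Coverage of the percentile intervals (default 0.95).
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `qcseg_fit`, with broom-style [tidy()]
#'   (per-change-point report), [glance()] (one-row model summary),
#'   [augment()] (input data plus fitted step, residual and segment id)
#'   and [ggplot2::autoplot()] methods. Fields include `partition`,
#'   `report`, `intervals`, `bic` (when auto-selected) and `error`.
#' @examples
#' fit <- detect_changepoints(c(1, 1, 1, 5, 5, 5), n_changepoints = 1,
#'                            n_boot = 0)
#' tidy(fit)$ch_pt  # 3
#' @export
detect_changepoints <- function(data, value = "value", date = NULL,
                                n_changepoints = NULL, score = "dp2",
                                min_seg_len = 2L, m_max = 15L,
                                penalty = c("mbic", "bic"),
                                n_boot = 1000L, ci_level = 0.95,
                                seed = NULL) {
  penalty <- match.arg(penalty)
  if (is.data.frame(data)) {
    if (!value %in% names(data)) {
      stop("no value column '", value, "' in `data`", call. = FALSE)
    }
    x <- data[[value]]
    dates <- if (!is.null(date)) {
      if (!date %in% names(data)) {
        stop("no date column '", date, "' in `data`", call. = FALSE)
      }
      data[[date]]
    } else if ("date" %in% names(data)) data[["date"]] else NULL
    tbl <- tibble::as_tibble(data)
  } else {
    x <- data
    dates <- NULL
    tbl <- tibble::tibble(value = as.numeric(data))
    value <- "value"
  }
  x <- check_values(x, "value")
  if (length(x) < 2L) {
    stop("insufficient data: change-point detection needs at least 2 points",
         call. = FALSE)
  }
  score <- match_score_method(score)

  bic <- NULL
  if (is.null(n_changepoints)) {
    bic <- bic_select(x, m_max = m_max, method = score,
                      min_seg_len = min_seg_len, penalty = penalty)
    partition <- bic$partition
    m <- bic$m_hat
  } else {
    m <- as.integer(n_changepoints)
    if (m < 0L) stop("`n_changepoints` must be >= 0", call. = FALSE)
    partition <- optimal_partition(x, m + 1L, score, min_seg_len)$partition
  }

  cis <- if (n_boot > 0L && m > 0L) {
    bootstrap_ci(x, partition, n_boot = n_boot, level = ci_level,
                 seed = seed, method = score, min_seg_len = min_seg_len)
  } else NULL

  structure(
    list(
      data = tbl,
      value_col = value,
      values = x,
      dates = dates,
      score = score,
      min_seg_len = as.integer(min_seg_len),
      auto = is.null(n_changepoints),
      seed = seed,
      n_boot = as.integer(n_boot),
      ci_level = ci_level,
      partition = partition,
      n_changepoints = m,
      bic = bic,
      total_score = partition_score(x, partition, score),
      error = partition_error(x, partition),
      cis = cis,
      report = change_report(x, partition, cis, dates),
      intervals = interval_stats(x, partition, dates)
    ),
    class = "qcseg_fit"
  )
}

#' @export
print.qcseg_fit <- function(x, ...) {
  cat("<qcseg_fit> n =", length(x$values), "| score =", x$score,
      "| change points:", x$n_changepoints,
      if (x$auto) "(BIC-selected)" else "(fixed)", "\n")
  cat("mean squared residual:", format(x$error), "\n")
  if (x$n_changepoints > 0L) {
    cat("positions:", paste(x$partition$change_points, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Tidy a change-point fit
#'
#' @param x A `qcseg_fit`.
#' @param ... Unused.
#' @return The per-change-point report tibble (columns `ch_pt`, `ci_low`,
#'   `ci_high`, `median_before`, `median_after`, `mean_from`, `mean_to`,
#'   `correction_pct`, plus `date` when available).
#' @export
tidy.qcseg_fit <- function(x, ...) {
  x$report
}

#' One-row summary of a change-point fit
#'
#' @param x A `qcseg_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_changepoints`, `score_method`,
#'   `total_score`, `error`, `bic` (NA when K was fixed manually),
#'   `auto_selected`.
#' @export
glance.qcseg_fit <- function(x, ...) {
  tibble::tibble(
    n = length(x$values),
    n_changepoints = x$n_changepoints,
    score_method = x$score,
    total_score = x$total_score,
    error = x$error,
    bic = if (is.null(x$bic)) NA_real_ else
      x$bic$curve$bic[x$bic$curve$m == x$n_changepoints],
    auto_selected = x$auto
  )
}

#' Augment data with the fitted step function
#'
#' @param x A `qcseg_fit`.
#' @param ... Unused.
#' @return The input tibble plus `.segment`, `.fitted` (block mean) and
#'   `.resid` columns.
#' @export
augment.qcseg_fit <- function(x, ...) {
  out <- x$data
  out$.segment <- block_of(x$partition)
  out$.fitted <- fitted_step(x$values, x$partition)
  out$.resid <- x$values - out$.fitted
  out
}
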