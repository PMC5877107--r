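#' Read a QC series from a delimited text file
#'
#' Parses a delimited table with a header into the tibble the detection
#' functions expect: a `value` column, an optional `date` column and
#' optional gain-setting columns `tg`, `r1`, `r2`. Rows whose value is
#' missing are dropped with a warning reporting the count. Dates are
#' parsed as ISO 8601 (`2006-10-19`) or day/month/year (`19/10/2006`),
#' selectable via `date_format`; non-monotone dates produce a warning, not
#' an error (detection uses sequence order only).
#'
#' @param path Path to the file.
#' @param value Name of the value column in the file (default `"value"`).
#' @param date,tg,r1,r2 Optional column names in the file; mapped to the
#'   standard names when present.
#' @param delim Field delimiter (default `","`).
#' @param date_format `"iso"` (default) or `"dmy"`.
#' @return A tibble with columns `value` and, when present in the file,
#'   `date`, `tg`, `r1`, `r2`.
#' @export
read_series <- function(path, value = "value", date = "date",
                        tg = "TG", r1 = "R1", r2 = "R2",
                        delim = ",", date_format = c("iso", "dmy")) {
  date_format <- match.arg(date_format)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  if (!value %in% names(raw)) {
    stop("schema error: no value column '", value, "' in ", path,
         call. = FALSE)
  }
  out <- tibble::tibble(value = suppressWarnings(as.numeric(raw[[value]])))
  if (date %in% names(raw)) {
    out$date <- if (date_format == "iso") {
      as.Date(raw[[date]])
    } else {
      as.Date(raw[[date]], format = "%d/%m/%Y")
    }
  }
  gain_map <- c(tg = tg, r1 = r1, r2 = r2)
  for (std in names(gain_map)) {
    col <- gain_map[[std]]
    if (col %in% names(raw)) {
      out[[std]] <- suppressWarnings(as.numeric(raw[[col]]))
    }
  }
  drop <- !is.finite(out$value)
  if (any(drop)) {
    warning(sum(drop), " row(s) with missing value dropped", call. = FALSE)
    out <- out[!drop, , drop = FALSE]
  }
  if (nrow(out) < 2L) {
    stop("insufficient data: fewer than 2 usable rows in ", path,
         call. = FALSE)
  }
  if ("date" %in% names(out) && anyNA(out$date)) {
    warning("some dates failed to parse and are NA", call. = FALSE)
  }
  if ("date" %in% names(out) && !anyNA(out$date) &&
      is.unsorted(out$date)) {
    warning("dates are not non-decreasing; detection uses row order",
            call. = FALSE)
  }
  out
}

report_columns <- c("ch_pt", "ci_low", "ci_high", "median_before",
                    "median_after", "mean_from", "mean_to", "correction_pct")

#' Write a change-point report to CSV or JSON
#'
#' CSV output carries the report rows with a fixed column order
#' (`ch_pt, ci_low, ci_high, median_before, median_after, mean_from,
#' mean_to, correction_pct`, then `date` if present). JSON output bundles
#' the report, the per-interval statistics and run metadata (scoring
#' method, number of change points, seed, package version), and
#' round-trips all numeric fields at full precision.
#'
#' @param fit A `qcseg_fit` from [detect_changepoints()], or a report
#'   tibble (then `stats` may be supplied separately).
#' @param path Output path.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @param stats Optional interval-statistics tibble when `fit` is a bare
#'   report.
#' @return The path, invisibly.
#' @export
write_report <- function(fit, path, format = NULL, stats = NULL) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("csv", "json")) format <- "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (inherits(fit, "qcseg_fit")) {
    report <- fit$report
    stats <- fit$intervals
    meta <- list(
      score_method = fit$score,
      n_changepoints = fit$n_changepoints,
      auto_selected = fit$auto,
      min_seg_len = fit$min_seg_len,
      n_boot = fit$n_boot,
      ci_level = fit$ci_level,
      seed = fit$seed,
      n = length(fit$values),
      error = fit$error,
      total_score = fit$total_score,
      version = as.character(utils::packageVersion("qcseg"))
    )
  } else {
    report <- tibble::as_tibble(fit)
    meta <- list(version = as.character(utils::packageVersion("qcseg")))
  }
  missing_cols <- setdiff(report_columns, names(report))
  if (length(missing_cols)) {
    stop("report is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(report), report_columns)
  report <- report[, c(report_columns, extra), drop = FALSE]

  if (format == "csv") {
    readr::write_csv(report, path)
  } else {
    payload <- list(meta = meta, report = report)
    if (!is.null(stats)) payload$intervals <- stats
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", Date = "ISO8601")
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return A list with `meta`, `report` (tibble) and optionally
#'   `intervals` (tibble).
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  report <- tibble::as_tibble(obj$report)
  if (nrow(report) == 0L) {
    # an empty report serialises as [] and loses its columns; restore them
    report <- tibble::tibble(
      ch_pt = integer(0), ci_low = integer(0), ci_high = integer(0),
      median_before = double(0), median_after = double(0),
      mean_from = double(0), mean_to = double(0), correction_pct = double(0)
    )
  }
  out <- list(meta = obj$meta, report = report)
  if (!is.null(obj$intervals)) {
    out$intervals <- tibble::as_tibble(obj$intervals)
  }
  out
}

#' Write a simulated series to CSV with a truth sidecar
#'
#' @param sim A `qcseg_sim`.
#' @param path CSV path for the per-point values; the ground truth
#'   (change points, segment means, noise levels, seed) is written next to
#'   it as `<path>.truth.json`.
#' @return The CSV path, invisibly.
#' @export
write_sim <- function(sim, path) {
  stopifnot(inherits(sim, "qcseg_sim"))
  readr::write_csv(as_tibble(sim), path)
  jsonlite::write_json(
    list(
      true_change_points = sim$true_change_points,
      segment_means = sim$segment_means,
      segment_sd = sim$segment_sd,
      segment_snr_db = sim$segment_snr_db,
      seed = sim$seed,
      n = sim$n
    ),
    paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
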