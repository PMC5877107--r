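#' Transmitter/receiver gain correction factor
#'
#' Instrument gain settings drift over a long QC campaign and scale the raw
#' fitted metabolite level. The correction factor
#' `fcorr = 10^(0.005 * (TG - 65)) * 2^((6 - R1/2) + (30 - R2))`
#' removes that scaling, where `TG` is the transmitter gain in 0.1 dB
#' units, `R1` the digital receiver gain and `R2` the analogue receiver
#' gain. At the neutral settings `(TG, R1, R2) = (65, 12, 30)` the factor
#' is exactly 1. `fcorr` is strictly positive, increasing in `TG` and
#' decreasing in `R1` and `R2`.
#'
#' @param tg,r1,r2 Numeric vectors (recycled to a common length), all
#'   finite. `TG` is carried in its native 0.1 dB units; no conversion is
#'   applied.
#' @return A positive numeric vector.
#' @examples
#' gain_correction_factor(65, 12, 30)  # 1
#' gain_correction_factor(65, 14, 30)  # 0.5
#' @export
gain_correction_factor <- function(tg, r1, r2) {
  if (!all(is.finite(tg), is.finite(r1), is.finite(r2))) {
    stop("gain settings must all be finite", call. = FALSE)
  }
  10^(0.005 * (tg - 65)) * 2^((6 - r1 / 2) + (30 - r2))
}

#' Apply the gain correction to a raw metabolite series
#'
#' Multiplies (the default, or divides — both conventions are found in
#' practice) each raw level by its per-measurement correction factor.
#' Accepts either a data frame carrying `value`, `tg`, `r1`, `r2` columns
#' or a raw numeric vector plus explicit settings.
#'
#' @param data A data frame with columns `value`, `tg`, `r1`, `r2` (names
#'   configurable), or a numeric vector of raw levels.
#' @param tg,r1,r2 Gain settings, required when `data` is a vector;
#'   when `data` is a data frame these name the columns to use.
#' @param value Column holding the raw level when `data` is a data frame.
#' @param direction `"multiply"` (default) or `"divide"`.
#' @return For data-frame input, the input tibble with added columns
#'   `fcorr` and `value_corrected`; for vector input, the corrected
#'   numeric vector with the factors in attribute `"fcorr"`.
#' @examples
#' apply_correction(c(2), tg = 65, r1 = 14, r2 = 30)  # 1
#' @export
apply_correction <- function(data, tg = "tg", r1 = "r1", r2 = "r2",
                             value = "value",
                             direction = c("multiply", "divide")) {
  direction <- match.arg(direction)
  if (is.data.frame(data)) {
    need <- c(value, tg, r1, r2)
    missing_cols <- setdiff(need, names(data))
    if (length(missing_cols)) {
      stop("missing column(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    f <- gain_correction_factor(data[[tg]], data[[r1]], data[[r2]])
    out <- tibble::as_tibble(data)
    out$fcorr <- f
    out$value_corrected <- if (direction == "multiply") {
      out[[value]] * f
    } else {
      out[[value]] / f
    }
    return(out)
  }
  raw <- check_values(data, "data")
  settings <- cbind(tg, r1, r2)   # recycles scalars against raw
  if (nrow(settings) != length(raw) && nrow(settings) != 1L) {
    stop("gain settings must have length 1 or length(data)", call. = FALSE)
  }
  f <- gain_correction_factor(settings[, 1L], settings[, 2L], settings[, 3L])
  f <- rep_len(f, length(raw))
  out <- if (direction == "multiply") raw * f else raw / f
  attr(out, "fcorr") <- f
  out
}
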