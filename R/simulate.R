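#' Simulate a heteroscedastic piecewise-constant QC series
#'
#' Emulates a long-run instrument QC signal: a piecewise-constant mean
#' (stable operating periods separated by abrupt system changes) distorted
#' by white Gaussian noise whose variance differs between segments.
#' Change-point positions are drawn uniformly over all placements honouring
#' `min_seg_len` (via the standard gap-reduction bijection, so the draw is
#' exactly uniform, not rejection-approximate). Segment means are drawn
#' uniformly from `mean_range`, with adjacent means redrawn until they
#' differ by at least `min_jump` so every nominal change point is a real
#' level shift. Per segment, an SNR in dB is drawn uniformly from
#' `snr_db_range` and the noise standard deviation is set so that
#' `10 * log10(mean^2 / sd^2)` equals it — segments therefore have unequal
#' noise variances (heteroscedasticity).
#'
#' The defaults reproduce the package's reference simulation conditions:
#' 106 points, 10 change points, per-segment SNR uniform on 1–10 dB,
#' positive metabolite-like means on (5, 15).
#'
#' @param n Series length (default 106).
#' @param n_changepoints Number of change points (default 10).
#' @param snr_db_range Length-2 numeric, per-segment SNR bounds in dB
#'   (default `c(1, 10)`).
#' @param mean_range Length-2 positive numeric, segment-mean bounds
#'   (default `c(5, 15)`). Must exclude 0: the SNR definition divides by
#'   the squared mean.
#' @param min_seg_len Minimum segment length (default 2).
#' @param min_jump Minimum absolute difference between adjacent segment
#'   means (default 2, i.e. 20% of the default mean range).
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @return An object of class `qcseg_sim`: a list with `values`,
#'   `true_change_points`, `segment_means`, `segment_sd`, `segment_snr_db`,
#'   `seed`, `n`. `tidy()` returns per-segment truth; `as_tibble()` the
#'   per-point series.
#' @examples
#' sim <- generate_series(seed = 1)
#' length(sim$values)              # 106
#' length(sim$true_change_points)  # 10
#' @export
generate_series <- function(n = 106L, n_changepoints = 10L,
                            snr_db_range = c(1, 10), mean_range = c(5, 15),
                            min_seg_len = 2L, min_jump = 2,
                            seed = NULL) {
  n <- as.integer(n)
  m <- as.integer(n_changepoints)
  L <- as.integer(min_seg_len)
  if ((m + 1L) * L > n) {
    stop("infeasible: (n_changepoints + 1) * min_seg_len exceeds n",
         call. = FALSE)
  }
  if (length(snr_db_range) != 2L || snr_db_range[1] > snr_db_range[2]) {
    stop("`snr_db_range` must be (low, high) with low <= high", call. = FALSE)
  }
  if (length(mean_range) != 2L || mean_range[1] > mean_range[2]) {
    stop("`mean_range` must be (low, high) with low <= high", call. = FALSE)
  }
  if (mean_range[1] <= 0 && mean_range[2] >= 0) {
    stop("`mean_range` must exclude 0: SNR is defined relative to the ",
         "squared segment mean", call. = FALSE)
  }
  if (min_jump < 0) stop("`min_jump` must be >= 0", call. = FALSE)
  if (min_jump > 0 && min_jump >= diff(range(mean_range))) {
    stop("`min_jump` must be smaller than the width of `mean_range`",
         call. = FALSE)
  }

  build <- function() {
    # change points: uniform over feasible placements.  p_i = q_i + (i-1)(L-1)
    # with q_i distinct in [L, n - L - (m-1)(L-1)] is a bijection between
    # feasible change-point vectors and plain m-subsets.
    cp <- if (m == 0L) integer(0) else {
      hi <- n - L - (m - 1L) * (L - 1L)
      q <- sort(sample(L:hi, m))
      as.integer(q + (seq_len(m) - 1L) * (L - 1L))
    }
    seg_len <- diff(c(0L, cp, n))

    means <- stats::runif(m + 1L, mean_range[1], mean_range[2])
    if (min_jump > 0 && m > 0L) {
      for (k in 2:(m + 1L)) {
        while (abs(means[k] - means[k - 1L]) < min_jump) {
          means[k] <- stats::runif(1L, mean_range[1], mean_range[2])
        }
      }
    }
    snr_db <- stats::runif(m + 1L, snr_db_range[1], snr_db_range[2])
    sds <- abs(means) * 10^(-snr_db / 20)
    values <- rep(means, seg_len) +
      stats::rnorm(n, 0, rep(sds, seg_len))
    list(values = values, cp = cp, means = means, sds = sds, snr_db = snr_db)
  }
  out <- if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())

  structure(
    list(
      values = out$values,
      true_change_points = out$cp,
      segment_means = out$means,
      segment_sd = out$sds,
      segment_snr_db = out$snr_db,
      seed = seed,
      n = n
    ),
    class = "qcseg_sim"
  )
}

#' @export
print.qcseg_sim <- function(x, ...) {
  cat("<qcseg_sim> n =", x$n, "with", length(x$true_change_points),
      "true change points\n")
  cat("positions:", paste(x$true_change_points, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as_tibble.qcseg_sim <- function(x, ...) {
  part <- true_partition(x)
  seg <- block_of(part)
  tibble::tibble(
    index = seq_len(x$n),
    value = x$values,
    segment = seg,
    true_mean = x$segment_means[seg],
    noise_sd = x$segment_sd[seg]
  )
}

#' @export
tidy.qcseg_sim <- function(x, ...) {
  part <- true_partition(x)
  tibble::tibble(
    segment = seq_len(part$n_blocks),
    start = part$blocks$start,
    end = part$blocks$end,
    length = part$blocks$length,
    mean = x$segment_means,
    noise_sd = x$segment_sd,
    snr_db = x$segment_snr_db
  )
}

#' Ground-truth partition of a simulated series
#'
#' @param sim A `qcseg_sim` from [generate_series()].
#' @return A `qcseg_partition` at the true change points.
#' @export
true_partition <- function(sim) {
  stopifnot(inherits(sim, "qcseg_sim"))
  new_partition(sim$true_change_points, sim$n)
}

#' Greedy binary segmentation baseline
#'
#' The classic fast heuristic: repeatedly split the block whose best single
#' split most reduces the total sum of squared errors, until `m` change
#' points are placed. Generally suboptimal relative to the exact dynamic
#' program — it is the comparison baseline in the benchmark, not a
#' recommended detector.
#'
#' @param values Numeric vector.
#' @param m Number of change points to place.
#' @param min_seg_len Minimum block length (default 2).
#' @return A `qcseg_partition`.
#' @export
greedy_binary_segmentation <- function(values, m, min_seg_len = 2L) {
  x <- check_values(values)
  m <- as.integer(m)
  L <- as.integer(min_seg_len)
  n <- length(x)
  if ((m + 1L) * L > n) {
    stop("infeasible: (m + 1) * min_seg_len exceeds series length",
         call. = FALSE)
  }
  ps <- prefix_stats(x)

  best_split <- function(start, end) {
    # best single split of block start..end; returns c(gain, split) or NULL
    lo <- start + L - 1L
    hi <- end - L
    if (lo > hi) return(NULL)
    s <- lo:hi
    gain <- segment_sse(ps, start, end) -
      (segment_sse(ps, start, s) + segment_sse(ps, s + 1L, end))
    i <- which.max(gain)
    c(gain[i], s[i])
  }

  bounds <- matrix(c(1L, n), 1L, 2L)
  cps <- integer(0)
  for (step in seq_len(m)) {
    cand <- apply(bounds, 1L, function(b) best_split(b[1L], b[2L]),
                  simplify = FALSE)
    ok <- !vapply(cand, is.null, logical(1))
    if (!any(ok)) {
      stop("greedy segmentation blocked: no feasible split for m = ", m,
           call. = FALSE)
    }
    gains <- vapply(cand, function(z) if (is.null(z)) -Inf else z[1L],
                    numeric(1))
    pick <- which.max(gains)
    split <- as.integer(cand[[pick]][2L])
    b <- bounds[pick, ]
    cps <- sort(c(cps, split))
    bounds <- rbind(bounds[-pick, , drop = FALSE],
                    c(b[1L], split), c(split + 1L, b[2L]))
  }
  new_partition(cps, n)
}

#' Error-versus-K benchmark over simulated datasets
#'
#' Generates `n_datasets` simulated series (one reproducible child seed per
#' dataset, spawned from the master seed), fits each requested method at
#' every change-point count in `m_range`, and records the mean squared
#' residual ([partition_error()]) of each fit. Methods are the seven DP
#' scorings plus `"greedy"` (binary segmentation). A method that fails on a
#' dataset (e.g. a degenerate `dp3` block) is logged to standard error and
#' excluded for that dataset, not fatal.
#'
#' @param n_datasets Number of simulated series (default 100).
#' @param m_range Change-point counts to scan (default `1:15`).
#' @param methods Character vector from `c(score_methods(), "greedy")`.
#' @param seed Master seed (default 42).
#' @param min_seg_len Minimum segment length for both simulation and fits.
#' @param ... Further arguments passed to [generate_series()].
#' @return An object of class `qcseg_benchmark`: a tibble with columns
#'   `dataset`, `method`, `m`, `error`; its `summary` attribute holds the
#'   mean error per `(method, m)` (also via [benchmark_summary()]).
#' @export
run_benchmark <- function(n_datasets = 100L, m_range = 1:15,
                          methods = c("dp2", "greedy"), seed = 42L,
                          min_seg_len = 2L, ...) {
  n_datasets <- as.integer(n_datasets)
  methods <- tolower(methods)
  bad <- setdiff(methods, c(score_methods(), "greedy"))
  if (length(bad)) {
    stop("unknown method(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  m_range <- sort(unique(as.integer(m_range)))

  empty <- tibble::tibble(dataset = integer(0), method = character(0),
                          m = integer(0), error = double(0))
  if (n_datasets < 1L) {
    return(structure(empty, summary = empty[c("method", "m", "error")],
                     class = c("qcseg_benchmark", class(empty))))
  }

  child_seeds <- withr::with_seed(as.integer(seed),
                                  sample.int(.Machine$integer.max, n_datasets))
  rows <- purrr::map(seq_len(n_datasets), function(d) {
    sim <- generate_series(min_seg_len = min_seg_len, seed = child_seeds[d], ...)
    purrr::map(methods, function(meth) {
      res <- tryCatch({
        if (meth == "greedy") {
          err <- purrr::map_dbl(m_range, function(m) {
            partition_error(sim$values,
                            greedy_binary_segmentation(sim$values, m,
                                                       min_seg_len))
          })
        } else {
          err <- error_curve(sim$values, m_range, meth, min_seg_len)$error
        }
        tibble::tibble(dataset = d, method = meth, m = m_range, error = err)
      }, error = function(e) {
        message("benchmark: dataset ", d, ", method ", meth,
                " skipped: ", conditionMessage(e))
        NULL
      })
      res
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  summ <- out |>
    dplyr::group_by(.data$method, .data$m) |>
    dplyr::summarise(error = mean(.data$error), .groups = "drop")
  structure(out, summary = summ,
            class = c("qcseg_benchmark", class(out)))
}

#' Mean benchmark error per method and change-point count
#'
#' @param benchmark A `qcseg_benchmark` from [run_benchmark()].
#' @return A tibble with columns `method`, `m`, `error`.
#' @export
benchmark_summary <- function(benchmark) {
  stopifnot(inherits(benchmark, "qcseg_benchmark"))
  attr(benchmark, "summary")
}
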