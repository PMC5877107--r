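#' Block-scoring methods
#'
#' The seven per-block cost functions available for segmentation. Writing
#' `n` for the block length, `xbar` for the within-block mean and `sigma`
#' for the within-block sample standard deviation (denominator `n - 1`):
#'
#' * `dp1` — sum of absolute deviations, `sum |x_i - xbar|`
#' * `dp2` — sum of squared deviations (SSE), `sum (x_i - xbar)^2`
#' * `dp3` — SSE divided by the block mean, `SSE / xbar`
#' * `dp4` — SSE divided by the block standard deviation, `SSE / sigma`
#' * `dp5` — standard deviation over range, `sigma / (max - min)`
#' * `dp6` — mean absolute deviation, `(1/n) sum |x_i - xbar|`
#' * `dp7` — mean squared deviation, `SSE / n`
#'
#' `dp2` is the default throughout the package: it is the Gaussian
#' maximum-likelihood cost for a piecewise-constant mean and gives the
#' smallest mean-squared residual attainable at any fixed number of blocks.
#'
#' Conventions for degenerate blocks: a constant block scores 0 under every
#' method (for `dp4` this is the 0/sigma limit, for `dp5` the 0/0 ratio of a
#' "perfect" segment). `dp4` and `dp5` need a block of length >= 2 for sigma
#' to exist. `dp3` on a non-constant block whose mean is <= 0 is an error:
#' metabolite levels are positive, so such a block marks corrupt input.
#'
#' @return `score_methods()` returns the character vector of method names.
#' @examples
#' score_methods()
#' @export
score_methods <- function() {
  c("dp1", "dp2", "dp3", "dp4", "dp5", "dp6", "dp7")
}

match_score_method <- function(method) {
  if (!is.character(method) || length(method) != 1L) {
    stop("`method` must be a single string, one of: ",
         paste(score_methods(), collapse = ", "), call. = FALSE)
  }
  m <- tolower(method)
  if (!m %in% score_methods()) {
    stop("unknown scoring method '", method, "'; use one of: ",
         paste(score_methods(), collapse = ", "), call. = FALSE)
  }
  m
}

#' Does a scoring method require blocks of length two or more?
#'
#' `dp4` and `dp5` divide by the within-block sample standard deviation,
#' which is undefined on a single point.
#'
#' @param method A method name from [score_methods()].
#' @return `TRUE` for `dp4` and `dp5`, otherwise `FALSE`.
#' @export
method_needs_sd <- function(method) {
  match_score_method(method) %in% c("dp4", "dp5")
}

check_values <- function(values, arg = "values") {
  if (!is.numeric(values) || length(values) < 1L) {
    stop("`", arg, "` must be a nonempty numeric vector", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("`", arg, "` contains non-finite entries", call. = FALSE)
  }
  as.numeric(values)
}

#' Cumulative sums for O(1) segment statistics
#'
#' Precomputes cumulative `sum(x)` and `sum(x^2)` so that the mean and the
#' sum of squared deviations (SSE) of any contiguous segment are recoverable
#' in constant time. Segment SSE uses the shortcut
#' `sum(x^2) - sum(x)^2 / n`, floored at zero to absorb the catastrophic
#' cancellation the shortcut can suffer on near-constant segments.
#'
#' @param values Numeric vector, all finite.
#' @return An object of class `qcseg_prefix`: a list with `n`, `csum`
#'   (cumulative sum, leading 0) and `csum2` (cumulative sum of squares,
#'   leading 0).
#' @examples
#' ps <- prefix_stats(c(1, 2, 3))
#' segment_sse(ps, 1, 3)   # 2
#' segment_mean(ps, 1, 3)  # 2
#' @export
prefix_stats <- function(values) {
  x <- check_values(values)
  structure(
    list(n = length(x), csum = c(0, cumsum(x)), csum2 = c(0, cumsum(x^2))),
    class = "qcseg_prefix"
  )
}

#' @param prefix A `qcseg_prefix` from [prefix_stats()].
#' @param start,end 1-based inclusive segment bounds.
#' @rdname prefix_stats
#' @export
segment_mean <- function(prefix, start, end) {
  (prefix$csum[end + 1L] - prefix$csum[start]) / (end - start + 1L)
}

#' @rdname prefix_stats
#' @export
segment_sse <- function(prefix, start, end) {
  n <- end - start + 1L
  s <- prefix$csum[end + 1L] - prefix$csum[start]
  s2 <- prefix$csum2[end + 1L] - prefix$csum2[start]
  pmax(s2 - s^2 / n, 0)
}

check_block <- function(n, start, end) {
  if (length(start) != 1L || length(end) != 1L ||
      start != as.integer(start) || end != as.integer(end)) {
    stop("block bounds must be single integers", call. = FALSE)
  }
  if (start < 1L || end > n || start > end) {
    stop("block [", start, ", ", end, "] out of bounds for series of length ",
         n, call. = FALSE)
  }
  invisible(TRUE)
}

#' Score one block of a series
#'
#' Evaluates a scoring function (see [score_methods()]) on the contiguous
#' block `values[start:end]`.
#'
#' @param values Numeric vector, all finite.
#' @param start,end 1-based inclusive block bounds.
#' @param method A method name from [score_methods()]. Default `"dp2"`.
#' @return A single nonnegative number.
#' @examples
#' block_score(c(1, 2, 3), 1, 3, "dp2")  # 2
#' block_score(c(1, 2, 3), 1, 3, "dp5")  # 0.5
#' @export
block_score <- function(values, start, end, method = "dp2") {
  x <- check_values(values)
  check_block(length(x), start, end)
  method <- match_score_method(method)
  xb <- x[start:end]
  n <- length(xb)
  if (method %in% c("dp4", "dp5") && n < 2L) {
    stop("method '", method, "' needs a block of length >= 2 (got length 1)",
         call. = FALSE)
  }
  m <- mean(xb)
  sse <- sum((xb - m)^2)
  switch(method,
    dp1 = sum(abs(xb - m)),
    dp2 = sse,
    dp3 = {
      if (sse == 0) 0
      else if (m <= 0) {
        stop("degenerate dp3 score: non-constant block with mean <= 0",
             call. = FALSE)
      } else sse / m
    },
    dp4 = if (sse == 0) 0 else sse / sqrt(sse / (n - 1L)),
    dp5 = {
      rng <- max(xb) - min(xb)
      if (rng == 0) 0 else sqrt(sse / (n - 1L)) / rng
    },
    dp6 = mean(abs(xb - m)),
    dp7 = sse / n
  )
}

# All-pairs block cost matrix: cost[i, j] = score of block i..j, Inf where
# j - i + 1 < min_seg_len.  SSE-derived methods are vectorised through the
# prefix shortcut; dp1/dp6 need the block mean inside an absolute value, so
# they fall back to a per-cell loop (N is ~100 in the QC use case).
segment_cost_matrix <- function(values, method = "dp2", min_seg_len = 1L) {
  x <- check_values(values)
  method <- match_score_method(method)
  n <- length(x)
  min_seg_len <- as.integer(min_seg_len)
  if (min_seg_len < 1L) stop("`min_seg_len` must be >= 1", call. = FALSE)
  if (method %in% c("dp4", "dp5") && min_seg_len < 2L) {
    stop("method '", method, "' requires `min_seg_len` >= 2", call. = FALSE)
  }

  cost <- matrix(Inf, n, n)
  ps <- prefix_stats(x)

  if (method %in% c("dp1", "dp6")) {
    for (i in seq_len(n)) {
      jmax <- n
      jmin <- i + min_seg_len - 1L
      if (jmin > jmax) next
      for (j in jmin:jmax) {
        xb <- x[i:j]
        sad <- sum(abs(xb - mean(xb)))
        cost[i, j] <- if (method == "dp1") sad else sad / (j - i + 1L)
      }
    }
    return(cost)
  }

  for (i in seq_len(n)) {
    jmin <- i + min_seg_len - 1L
    if (jmin > n) next
    j <- jmin:n
    len <- j - i + 1L
    sse <- segment_sse(ps, i, j)
    cost[i, j] <- switch(method,
      dp2 = sse,
      dp7 = sse / len,
      dp3 = {
        mu <- segment_mean(ps, i, j)
        bad <- mu <= 0 & sse > 0
        if (any(bad)) {
          stop("degenerate dp3 score: non-constant block with mean <= 0",
               call. = FALSE)
        }
        ifelse(sse == 0, 0, sse / mu)
      },
      dp4 = ifelse(sse == 0, 0, sse / sqrt(sse / (len - 1L))),
      dp5 = {
        rng <- cummax(x[i:n]) - cummin(x[i:n])
        rng <- rng[len]
        sdv <- sqrt(sse / (len - 1L))
        ifelse(rng == 0, 0, sdv / rng)
      }
    )
  }
  cost
}
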