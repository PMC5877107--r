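#' Build a partition object from change-point positions
#'
#' A partition splits indices `1..n` into `K` contiguous blocks. Change
#' points follow the field convention used throughout the package: each
#' change point is the 1-based index of the LAST observation of a block, so
#' `K - 1` change points define `K` blocks.
#'
#' @param change_points Strictly increasing integer vector (possibly empty)
#'   with all entries in `1..(n - 1)`.
#' @param n Series length.
#' @return An object of class `qcseg_partition`: a list with `n`,
#'   `change_points`, `n_blocks`, and a `blocks` tibble (`block`, `start`,
#'   `end`, `length`).
#' @examples
#' new_partition(c(3), 6)
#' @export
new_partition <- function(change_points, n) {
  n <- as.integer(n)
  cp <- as.integer(change_points)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (length(cp) > 0L) {
    if (any(cp < 1L) || any(cp >= n)) {
      stop("change points must lie in 1..(n - 1)", call. = FALSE)
    }
    if (any(diff(cp) <= 0L)) {
      stop("change points must be strictly increasing", call. = FALSE)
    }
  }
  start <- c(1L, cp + 1L)
  end <- c(cp, n)
  structure(
    list(
      n = n,
      change_points = cp,
      n_blocks = length(cp) + 1L,
      blocks = tibble::tibble(
        block = seq_along(start),
        start = start,
        end = end,
        length = end - start + 1L
      )
    ),
    class = "qcseg_partition"
  )
}

#' @export
print.qcseg_partition <- function(x, ...) {
  cat("<qcseg_partition> ", x$n_blocks, " block(s) over n = ", x$n, "\n",
      sep = "")
  if (length(x$change_points)) {
    cat("change points: ", paste(x$change_points, collapse = "; "), "\n",
        sep = "")
  } else {
    cat("no change points\n")
  }
  invisible(x)
}

#' @export
format.qcseg_partition <- function(x, ...) {
  paste0("partition(", paste(x$change_points, collapse = ";"), " | n=", x$n, ")")
}

#' Total score of a given partition
#'
#' Sums [block_score()] over the blocks of a partition. Used for
#' self-consistency checks and for scoring externally supplied partitions
#' (ground truth, baselines).
#'
#' @inheritParams block_score
#' @param partition A `qcseg_partition`.
#' @return A single number.
#' @export
partition_score <- function(values, partition, method = "dp2") {
  stopifnot(inherits(partition, "qcseg_partition"))
  x <- check_values(values)
  if (length(x) != partition$n) {
    stop("partition was built for n = ", partition$n,
         " but `values` has length ", length(x), call. = FALSE)
  }
  b <- partition$blocks
  sum(purrr::map2_dbl(b$start, b$end, ~ block_score(x, .x, .y, method)))
}

# Fill the Bellman table.  opt[k, j] is the optimal score of partitioning
# the prefix 1..j into k blocks of length >= min_seg_len; back[k, j] is the
# chosen split s (end of block k - 1).  Ties take the smallest split index.
dp_fill <- function(cost, k_max, min_seg_len = 1L) {
  n <- ncol(cost)
  L <- as.integer(min_seg_len)
  opt <- matrix(Inf, k_max, n)
  back <- matrix(NA_integer_, k_max, n)
  opt[1L, ] <- cost[1L, ]
  if (k_max >= 2L) {
    for (k in 2L:k_max) {
      jmin <- k * L
      if (jmin > n) break
      for (j in jmin:n) {
        s <- ((k - 1L) * L):(j - L)
        cand <- opt[k - 1L, s] + cost[s + 1L, j]
        best <- which.min(cand)          # first minimum = smallest split
        if (length(best)) {
          opt[k, j] <- cand[best]
          back[k, j] <- s[best]
        }
      }
    }
  }
  list(opt = opt, back = back, min_seg_len = L)
}

#' Recover a partition from a filled score table
#'
#' Follows the backpointers of the Bellman table from `(K, n)` down to the
#' first block. Re-scoring the returned partition reproduces `opt[K, n]`.
#'
#' @param table A score table as returned in the `table` element of
#'   [optimal_partition()] (fields `opt`, `back`, `min_seg_len`).
#' @param K Number of blocks to extract; the table must be filled for `K`.
#' @return A `qcseg_partition`.
#' @export
backtrack <- function(table, K) {
  K <- as.integer(K)
  n <- ncol(table$opt)
  if (K < 1L || K > nrow(table$opt)) {
    stop("table not filled for K = ", K, call. = FALSE)
  }
  if (!is.finite(table$opt[K, n])) {
    stop("table not filled (infeasible) for K = ", K, call. = FALSE)
  }
  cp <- integer(0)
  j <- n
  k <- K
  while (k > 1L) {
    s <- table$back[k, j]
    if (is.na(s)) stop("table not filled for K = ", K, call. = FALSE)
    cp <- c(s, cp)
    j <- s
    k <- k - 1L
  }
  new_partition(cp, n)
}

#' Optimal K-block partition by dynamic programming
#'
#' Minimises the cumulative block score `sum_k Q(B_k)` over all partitions
#' of the series into `K` contiguous blocks of length at least
#' `min_seg_len`, by exact dynamic programming (Bellman recursion over
#' prefix optima). Complexity is `O(K n^2)` time, which is instantaneous at
#' the n ~ 100 scale of longitudinal QC series.
#'
#' @param values Numeric vector, all finite.
#' @param K Number of blocks (number of change points + 1).
#' @param method A method name from [score_methods()]. Default `"dp2"`.
#' @param min_seg_len Minimum block length; must be >= 2 for the
#'   sigma-based methods `dp4` and `dp5`.
#' @return A list with `partition` (a `qcseg_partition`), `score` (the
#'   minimal total score) and `table` (the filled Bellman table: `opt`
#'   matrix of prefix optima, `back` matrix of split backpointers).
#' @examples
#' fit <- optimal_partition(c(1, 1, 1, 5, 5, 5), K = 2)
#' fit$partition$change_points  # 3
#' fit$score                    # 0
#' @export
optimal_partition <- function(values, K, method = "dp2", min_seg_len = 2L) {
  x <- check_values(values)
  method <- match_score_method(method)
  K <- as.integer(K)
  L <- as.integer(min_seg_len)
  n <- length(x)
  if (K < 1L) stop("`K` must be >= 1", call. = FALSE)
  if (L < 1L) stop("`min_seg_len` must be >= 1", call. = FALSE)
  if (method %in% c("dp4", "dp5") && L < 2L) {
    stop("method '", method, "' requires `min_seg_len` >= 2", call. = FALSE)
  }
  if (K * L > n) {
    stop("infeasible: K * min_seg_len = ", K * L,
         " exceeds series length ", n, call. = FALSE)
  }
  cost <- segment_cost_matrix(x, method, L)
  tab <- dp_fill(cost, K, L)
  part <- backtrack(tab, K)
  list(partition = part, score = tab$opt[K, n], table = tab)
}

#' Exhaustive-search partition (testing oracle)
#'
#' Enumerates every placement of `K - 1` change points honouring
#' `min_seg_len` and returns the minimum-score partition. This is the
#' definitional answer the dynamic program must reproduce; it exists purely
#' as an independent oracle and is limited to small problems.
#'
#' Ties are broken in favour of the lexicographically smallest change-point
#' vector (enumeration order; first strict minimum wins).
#'
#' @inheritParams optimal_partition
#' @param max_candidates Enumeration budget; exceeding it is an error.
#' @return A list with `partition` and `score`.
#' @export
brute_force_partition <- function(values, K, method = "dp2", min_seg_len = 2L,
                                  max_candidates = 1e6) {
  x <- check_values(values)
  method <- match_score_method(method)
  K <- as.integer(K)
  L <- as.integer(min_seg_len)
  n <- length(x)
  if (K * L > n) {
    stop("infeasible: K * min_seg_len = ", K * L,
         " exceeds series length ", n, call. = FALSE)
  }
  n_cand <- choose(n - 1L, K - 1L)
  if (n_cand > max_candidates) {
    stop("enumeration budget exceeded: ", n_cand, " candidate partitions",
         call. = FALSE)
  }
  cost <- segment_cost_matrix(x, method, L)
  if (K == 1L) {
    return(list(partition = new_partition(integer(0), n),
                score = cost[1L, n]))
  }
  combos <- utils::combn(n - 1L, K - 1L)   # columns in lexicographic order
  best_score <- Inf
  best_cp <- NULL
  for (c_idx in seq_len(ncol(combos))) {
    cp <- combos[, c_idx]
    start <- c(1L, cp + 1L)
    end <- c(cp, n)
    if (any(end - start + 1L < L)) next
    # accumulate block costs left to right in double precision, matching the
    # Bellman recursion's association order, so optima compare exactly
    sc <- 0
    for (b in seq_along(start)) sc <- sc + cost[start[b], end[b]]
    if (sc < best_score) {
      best_score <- sc
      best_cp <- cp
    }
  }
  if (is.null(best_cp)) {
    stop("no feasible partition under min_seg_len = ", L, call. = FALSE)
  }
  list(partition = new_partition(best_cp, n), score = best_score)
}
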