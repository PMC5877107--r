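test_that("partition objects validate their invariants", {
  p <- new_partition(c(3), 6)
  expect_s3_class(p, "qcseg_partition")
  expect_equal(p$blocks$start, c(1L, 4L))
  expect_equal(p$blocks$end, c(3L, 6L))
  expect_equal(p$n_blocks, 2L)
  expect_error(new_partition(c(6), 6), "1..\\(n - 1\\)")
  expect_error(new_partition(c(4, 2), 6), "strictly increasing")
  expect_error(new_partition(c(2, 2), 6), "strictly increasing")
})

test_that("textbook cases partition exactly", {
  fit <- optimal_partition(c(1, 1, 1, 5, 5, 5), K = 2)
  expect_equal(fit$partition$change_points, 3L)
  expect_equal(fit$score, 0)

  fit1 <- optimal_partition(c(3, 3, 3, 3), K = 1)
  expect_equal(fit1$partition$change_points, integer(0))
  expect_equal(fit1$score, 0)

  # enumerating the three splits of [1,2,6,7]: (0,14), (1), (14,0)
  fit2 <- optimal_partition(c(1, 2, 6, 7), K = 2, min_seg_len = 1)
  expect_equal(fit2$partition$change_points, 2L)
  expect_equal(fit2$score, 1)
})

test_that("infeasible configurations raise a feasibility error", {
  expect_error(optimal_partition(1:5, K = 3, min_seg_len = 2), "infeasible")
  expect_error(optimal_partition(1:5, K = 2, method = "dp4",
                                 min_seg_len = 1), "min_seg_len")
  expect_error(brute_force_partition(1:5, K = 3, min_seg_len = 2),
               "infeasible")
})

test_that("DP equals the exhaustive oracle for every method and K", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      n <- sample(8:12, 1)
      x <- runif(n, 1, 10)
      for (K in 2:4) {
        for (m in score_methods()) {
          L <- 2L
          dp <- optimal_partition(x, K, m, L)
          bf <- brute_force_partition(x, K, m, L)
          expect_identical(dp$score, bf$score,
                           label = sprintf("%s n=%d K=%d", m, n, K))
          expect_identical(dp$partition$change_points,
                           bf$partition$change_points)
        }
      }
    }
  })
})

test_that("the oracle is itself definitional: it scans every candidate", {
  # spot-check against a hand enumeration over all_partitions()
  x <- rand_pos_series(9, seed = 3)
  for (K in 2:3) {
    scores <- vapply(all_partitions(9, K, 1L), function(cp) {
      partition_score(x, new_partition(cp, 9), "dp2")
    }, numeric(1))
    bf <- brute_force_partition(x, K, "dp2", min_seg_len = 1)
    expect_equal(bf$score, min(scores))
  }
  expect_error(
    brute_force_partition(rand_pos_series(40, 1), 8, max_candidates = 100),
    "budget"
  )
})

test_that("backtracked partitions reproduce the tabulated optimum", {
  x <- rand_pos_series(30, seed = 11)
  fit <- optimal_partition(x, 4, "dp2")
  expect_equal(partition_score(x, fit$partition, "dp2"), fit$score,
               tolerance = 1e-9)
  # K = 1 from the same table
  p1 <- backtrack(fit$table, 1)
  expect_equal(p1$change_points, integer(0))
  p2 <- backtrack(fit$table, 2)
  expect_equal(partition_score(x, p2, "dp2"), fit$table$opt[2, 30],
               tolerance = 1e-9)
  expect_error(backtrack(fit$table, 9), "not filled")
})

test_that("the score table holds its structural invariants", {
  x <- rand_pos_series(25, seed = 21)
  fit <- optimal_partition(x, 5, "dp2", min_seg_len = 1)
  ps <- prefix_stats(x)
  # first row is the single-block prefix score
  expect_equal(fit$table$opt[1, ], segment_sse(ps, 1, 1:25), tolerance = 1e-9)
  # adding a block never worsens the optimum
  for (k in 1:4) {
    expect_lte(fit$table$opt[k + 1, 25], fit$table$opt[k, 25] + 1e-12)
  }
})

test_that("noiseless piecewise-constant data is recovered exactly", {
  x <- step_series(c(5, 7, 4, 6), c(2, 9, 4, 12))
  fit <- optimal_partition(x, 4, "dp2")
  expect_equal(fit$partition$change_points, c(5L, 12L, 16L))
  expect_equal(fit$score, 0)
})

test_that("reversing the series reverses the change points", {
  withr::with_seed(8, {
    for (rep in 1:5) {
      x <- runif(20, 1, 10)
      cp_fwd <- optimal_partition(x, 3, "dp2")$partition$change_points
      cp_rev <- optimal_partition(rev(x), 3, "dp2")$partition$change_points
      expect_equal(sort(20L - cp_fwd), sort(cp_rev))
    }
  })
})

test_that("optimum is non-increasing in K", {
  x <- rand_pos_series(40, seed = 13)
  fit <- optimal_partition(x, 8, "dp2")
  opt_n <- fit$table$opt[, 40]
  expect_true(all(diff(opt_n) <= 1e-12))
})
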