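test_that("mean squared residual matches hand-computed cases", {
  expect_equal(partition_error(c(1, 1, 5, 5), new_partition(2, 4)), 0)
  expect_equal(partition_error(c(1, 2, 6, 7), new_partition(2, 4)), 0.25)
  x <- rand_pos_series(30, seed = 4)
  # single block: the population variance (denominator n)
  expect_equal(partition_error(x, new_partition(integer(0), 30)),
               mean((x - mean(x))^2))
})

test_that("n * error equals the dp2 cumulative score of the same partition", {
  x <- rand_pos_series(60, seed = 15)
  withr::with_seed(16, {
    for (rep in 1:5) {
      cp <- sort(sample(2:58, 4))
      cp <- cp[c(TRUE, diff(cp) >= 2)]
      p <- new_partition(cp, 60)
      expect_equal(60 * partition_error(x, p), partition_score(x, p, "dp2"),
                   tolerance = 1e-9)
    }
  })
})

test_that("dp2 error curves are non-increasing and reach zero on clean data", {
  clean <- step_series(c(8, 8, 9), c(3, 10, 6))
  ec <- error_curve(clean, 1:6, "dp2")
  expect_equal(ec$error[ec$m == 2], 0)
  expect_true(all(ec$error[ec$m >= 2] < 1e-18))

  x <- withr::with_seed(1, rnorm(50))
  ec2 <- error_curve(x, 1:15, "dp2")
  expect_true(all(diff(ec2$error) <= 1e-12))

  ec3 <- error_curve(c(1, 2, 6, 7), 1, "dp2")
  expect_equal(ec3$error, 0.25)
})

test_that("the dp2 optimum dominates any other partition's error", {
  x <- rand_pos_series(40, seed = 23)
  for (K in c(3, 5)) {
    best <- optimal_partition(x, K, "dp2")$partition
    e_best <- partition_error(x, best)
    withr::with_seed(K, {
      for (rep in 1:50) {
        cp <- sort(sample(seq(2, 38, by = 2), K - 1))
        e_other <- partition_error(x, new_partition(cp, 40))
        expect_gte(e_other, e_best)
      }
    })
  }
})

test_that("BIC selects no change point on constant series", {
  sel <- bic_select(rep(5, 20))
  expect_equal(sel$m_hat, 0L)
  expect_true(sel$degenerate)
  expect_equal(sel$partition$change_points, integer(0))
})

test_that("BIC finds the single obvious level shift across seeds", {
  for (s in 1:20) {
    x <- withr::with_seed(s, c(rnorm(50, 0), rnorm(50, 10)))
    sel <- bic_select(x, m_max = 10)
    expect_equal(sel$m_hat, 1L, label = sprintf("seed %d", s))
    expect_lte(abs(sel$partition$change_points - 50), 1)
  }
})

test_that("BIC consistency: recovery probability grows with the jump", {
  hits <- 0L
  for (s in 1:100) {
    x <- withr::with_seed(1000 + s, c(rnorm(40, 0, 1), rnorm(40, 10, 1)))
    sel <- bic_select(x, m_max = 8)
    if (sel$m_hat == 1L) hits <- hits + 1L
  }
  expect_gte(hits / 100, 0.9)
})

test_that("rss is non-increasing in m and m_hat minimises the criterion", {
  x <- withr::with_seed(7, c(rnorm(30, 0), rnorm(30, 3), rnorm(30, 7)))
  sel <- bic_select(x, m_max = 8)
  expect_true(all(diff(sel$curve$rss) <= 1e-9))
  expect_equal(sel$curve$m[which.min(sel$curve$bic)], sel$m_hat)
})

test_that("bootstrap CIs have zero width on noiseless steps and are seeded", {
  x <- step_series(c(10, 10), c(2, 8))
  p <- optimal_partition(x, 2)$partition
  ci <- bootstrap_ci(x, p, n_boot = 200, seed = 1)
  expect_equal(ci$ci_low, ci$position)
  expect_equal(ci$ci_high, ci$position)

  y <- withr::with_seed(2, c(rnorm(30, 0, 0.1), rnorm(30, 10, 0.1)))
  py <- optimal_partition(y, 2)$partition
  ci1 <- bootstrap_ci(y, py, n_boot = 300, seed = 99)
  ci2 <- bootstrap_ci(y, py, n_boot = 300, seed = 99)
  expect_identical(ci1, ci2)
  expect_lte(ci1$ci_high - ci1$ci_low, 2)
  expect_true(ci1$ci_low <= ci1$position && ci1$position <= ci1$ci_high)
})

test_that("bootstrap CIs are equivariant under adding a constant", {
  y <- withr::with_seed(3, c(rnorm(25, 5, 0.5), rnorm(25, 9, 0.5)))
  p <- optimal_partition(y, 2)$partition
  ci_a <- bootstrap_ci(y, p, n_boot = 200, seed = 7)
  ci_b <- bootstrap_ci(y + 100, p, n_boot = 200, seed = 7)
  expect_identical(ci_a, ci_b)
})

test_that("interval statistics summarise each block and conserve the mean", {
  s <- interval_stats(c(1, 1, 5, 5), new_partition(2, 4))
  expect_equal(s$mean, c(1, 5))
  expect_equal(s$sd, c(0, 0))
  expect_equal(s$n, c(2L, 2L))

  s1 <- interval_stats(c(2, 3, 9), new_partition(2, 3))
  expect_equal(s1$sd[2], 0)   # single-point block: sd 0 by convention

  x <- rand_pos_series(37, seed = 31)
  p <- new_partition(c(5, 20, 30), 37)
  st <- interval_stats(x, p)
  expect_equal(sum(st$mean * st$n) / 37, mean(x), tolerance = 1e-9)

  dates <- as.Date("2006-04-03") + seq(0, 72, by = 2)
  std <- interval_stats(x, p, dates)
  expect_equal(std$date_start[1], dates[1])
  expect_equal(std$date_end[4], dates[37])
})

test_that("the change report carries flanking stats and correction percent", {
  r <- change_report(c(2, 2, 4, 4), new_partition(2, 4))
  expect_equal(r$mean_from, 2)
  expect_equal(r$mean_to, 4)
  expect_equal(r$correction_pct, 200)

  r2 <- change_report(rep(3, 10), new_partition(5, 10))
  expect_equal(r2$correction_pct, 100)

  r3 <- change_report(c(10, 10, 5, 5, 20, 20), new_partition(c(2, 4), 6))
  expect_equal(r3$correction_pct, c(50, 200))
  expect_equal(r3$median_before, c(10, 5))
  expect_equal(r3$median_after, c(5, 20))

  expect_error(change_report(c(0, 0, 5, 5), new_partition(2, 4)),
               "zero mean")

  r0 <- change_report(rand_pos_series(10, 2), new_partition(integer(0), 10))
  expect_equal(nrow(r0), 0L)
  expect_named(r0, c("ch_pt", "ci_low", "ci_high", "median_before",
                     "median_after", "mean_from", "mean_to",
                     "correction_pct"))
})
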