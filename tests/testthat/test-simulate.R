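test_that("simulated series have the reference structure", {
  sim <- generate_series(seed = 5)
  expect_equal(sim$n, 106L)
  expect_length(sim$values, 106)
  expect_length(sim$true_change_points, 10)
  expect_length(sim$segment_means, 11)
  part <- true_partition(sim)
  expect_equal(part$n_blocks, 11L)
  expect_true(all(part$blocks$length >= 2))
  expect_true(all(sim$segment_snr_db >= 1 & sim$segment_snr_db <= 10))
  expect_true(all(sim$segment_means >= 5 & sim$segment_means <= 15))
  expect_true(all(abs(diff(sim$segment_means)) >= 2))  # default min_jump
})

test_that("the same seed reproduces the series exactly", {
  a <- generate_series(seed = 123)
  b <- generate_series(seed = 123)
  expect_identical(a$values, b$values)
  expect_identical(a$true_change_points, b$true_change_points)
  c <- generate_series(seed = 124)
  expect_false(identical(a$values, c$values))
})

test_that("noise is heteroscedastic and tracks the per-segment SNR", {
  sim <- generate_series(seed = 9)
  expect_gt(length(unique(sim$segment_sd)), 1)
  expect_equal(10 * log10(sim$segment_means^2 / sim$segment_sd^2),
               sim$segment_snr_db, tolerance = 1e-9)
})

test_that("at very high SNR residual noise matches mean/1000 within 20%", {
  # snr 60 dB: sd = mean / 1000; pool within-segment residual sds over seeds
  ratios <- numeric(0)
  for (s in 1:50) {
    sim <- generate_series(n = 106, n_changepoints = 5,
                           snr_db_range = c(60, 60), seed = 7000 + s)
    part <- true_partition(sim)
    st <- interval_stats(sim$values, part)
    keep <- st$n >= 5
    ratios <- c(ratios, st$sd[keep] / (st$mean[keep] / 1000))
  }
  expect_lt(abs(mean(ratios) - 1), 0.2)
})

test_that("generator validates its feasibility and SNR preconditions", {
  expect_error(generate_series(n = 10, n_changepoints = 6, min_seg_len = 2),
               "infeasible")
  expect_error(generate_series(mean_range = c(-1, 5)), "exclude 0")
  expect_error(generate_series(snr_db_range = c(10, 1)), "low <= high")
})

test_that("simulated series tidiers expose the truth", {
  sim <- generate_series(seed = 17)
  td <- tidy(sim)
  expect_equal(nrow(td), 11L)
  expect_equal(sum(td$length), 106L)
  tb <- as_tibble(sim)
  expect_equal(nrow(tb), 106L)
  expect_equal(tb$value, sim$values)
  expect_equal(unique(tb$segment), 1:11)
})

test_that("greedy binary segmentation handles the canonical cases", {
  expect_equal(greedy_binary_segmentation(c(1, 1, 5, 5), 1)$change_points, 2L)
  clean <- step_series(c(6, 7, 7), c(1, 8, 3))
  expect_equal(greedy_binary_segmentation(clean, 2)$change_points, c(6L, 13L))
  expect_error(greedy_binary_segmentation(1:6, 5, min_seg_len = 2),
               "infeasible")
})

test_that("greedy is never better than the exact dp2 optimum", {
  withr::with_seed(71, {
    for (rep in 1:100) {
      x <- runif(30, 1, 10)
      m <- sample(1:5, 1)
      g <- partition_error(x, greedy_binary_segmentation(x, m))
      d <- partition_error(x, optimal_partition(x, m + 1, "dp2")$partition)
      expect_gte(g, d - 1e-12)
    }
  })
})

test_that("the true partition never beats the dp2 optimum at the same K", {
  for (s in 1:20) {
    sim <- generate_series(seed = 300 + s)
    truth <- partition_score(sim$values, true_partition(sim), "dp2")
    opt <- optimal_partition(sim$values, 11, "dp2")$score
    expect_gte(truth, opt - 1e-9)
  }
})

test_that("benchmarks aggregate per-method errors and keep dp2 lowest", {
  bench <- run_benchmark(n_datasets = 5, m_range = 1:6,
                         methods = c("dp2", "greedy"), seed = 99)
  expect_s3_class(bench, "qcseg_benchmark")
  expect_equal(nrow(bench), 5 * 6 * 2)
  summ <- benchmark_summary(bench)
  wide <- tidyr::pivot_wider(summ, names_from = "method",
                             values_from = "error")
  expect_true(all(wide$dp2 <= wide$greedy + 1e-12))
  # per-dataset dp2 curves non-increasing
  for (d in unique(bench$dataset)) {
    e <- bench$error[bench$dataset == d & bench$method == "dp2"]
    expect_true(all(diff(e) <= 1e-12))
  }
})

test_that("benchmark at m = truth and fixed 30 dB recovers the noise floor", {
  bench <- run_benchmark(n_datasets = 20, m_range = 10, methods = "dp2",
                         seed = 11, snr_db_range = c(30, 30))
  got <- mean(bench$error)
  # expected residual MSE if recovery were exact: mean within-segment variance
  seeds <- withr::with_seed(11L, sample.int(.Machine$integer.max, 20))
  expected <- mean(purrr::map_dbl(seeds, function(s) {
    sim <- generate_series(min_seg_len = 2, seed = s,
                           snr_db_range = c(30, 30))
    part <- true_partition(sim)
    sum(sim$segment_sd^2 * part$blocks$length) / sim$n
  }))
  expect_lt(abs(got - expected) / expected, 0.2)
})

test_that("an empty benchmark is a valid empty result", {
  bench <- run_benchmark(n_datasets = 0)
  expect_equal(nrow(bench), 0L)
  expect_equal(nrow(benchmark_summary(bench)), 0L)
})
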