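test_that("errant-breath flagging spares clean data and catches a gross spike", {
  # constant series: nothing to flag
  b <- breath_series(seq(0, 58, by = 2), rep(40, 30))
  expect_false(any(exclude_errant(b)$excluded))

  # one spike: exactly that breath flagged, values untouched
  v <- rep(40, 30); v[16] <- 400
  b <- breath_series(seq(0, 58, by = 2), v)
  out <- exclude_errant(b, window = 5, k = 3)
  expect_identical(which(out$excluded), 16L)
  expect_identical(out$reason[16], "errant")
  expect_identical(out$vo2, v)  # flag-only, raw values preserved

  # enormous k: identity
  expect_false(any(exclude_errant(b, window = 5, k = 1e9)$excluded))

  # series shorter than the window: warning, no-op
  short <- breath_series(c(0, 2, 4), c(40, 41, 39))
  expect_warning(out <- exclude_errant(short), "window")
  expect_false(any(out$excluded))

  expect_error(exclude_errant(b, window = 4), "odd")
  expect_error(exclude_errant(b, k = 0), "k")
})

test_that("errant flagging is idempotent", {
  spec <- vo2_model("off", "MONO_NO_TD")
  g <- generate_breaths(generator_config(spec, severe_off_truth, noise_sd = 2,
                                         errant_rate = 0.05, errant_magnitude = 10,
                                         seed = 301))
  once <- exclude_errant(g$breaths)
  twice <- exclude_errant(once)
  expect_identical(once$excluded, twice$excluded)
})

test_that("1-s interpolation is linear over non-excluded breaths", {
  b <- breath_series(c(0, 2, 5), c(10, 12, 18))
  u <- interpolate_1s(b)
  expect_equal(series_times(u), 0:5)
  expect_equal(u$vo2, c(10, 11, 12, 14, 16, 18))

  # breaths already on integer seconds are preserved exactly
  b2 <- breath_series(0:10, 30 + sin(0:10))
  expect_equal(interpolate_1s(b2)$vo2, 30 + sin(0:10))

  # excluded breaths contribute nothing
  b3 <- breath_series(c(0, 1, 2), c(10, 500, 12),
                      excluded = c(FALSE, TRUE, FALSE))
  expect_equal(interpolate_1s(b3)$vo2, c(10, 11, 12))

  expect_error(interpolate_1s(breath_series(0, 10)), "insufficient")
})

test_that("ensemble averaging takes the pointwise mean on the common span", {
  s <- uniform_series(0, 1, c(10, 11, 12, 13))
  same <- ensemble_average(list(s, s))
  expect_equal(same$vo2, s$vo2)

  shifted <- uniform_series(0, 1, s$vo2 + 4)
  expect_equal(ensemble_average(list(s, shifted))$vo2, s$vo2 + 2)

  # three series overlapping at a single shared second
  a <- uniform_series(0, 1, c(5, 1))
  b <- uniform_series(1, 1, c(2, 7))
  c3 <- uniform_series(1, 1, c(6, 9, 9))
  avg <- ensemble_average(list(a, b, c3))
  expect_equal(series_times(avg), 1)
  expect_equal(avg$vo2, 3)

  expect_error(ensemble_average(list()), "at least one")
  far <- uniform_series(100, 1, c(1, 2))
  expect_error(ensemble_average(list(a, far)), "intersection")
})

test_that("ensemble averaging of n replicates shrinks RMSE like 1/sqrt(n)", {
  spec <- vo2_model("off", "MONO_NO_TD")
  clean <- eval_vo2(spec, severe_off_truth, 0:180)
  rmse <- sapply(c(1, 4, 16), function(n) {
    reps <- lapply(seq_len(n), function(j) {
      g <- generate_uniform(generator_config(spec, severe_off_truth,
                                             noise_sd = 2, seed = 50 * n + j))
      g$series
    })
    sqrt(mean((ensemble_average(reps)$vo2 - clean)^2))
  })
  # expected ratios 1/2 and 1/4, within 20%
  expect_equal(rmse[2] / rmse[1], 0.5, tolerance = 0.2)
  expect_equal(rmse[3] / rmse[1], 0.25, tolerance = 0.2)
})

test_that("smoothing filters behave as centred rolling statistics", {
  flat <- uniform_series(0, 1, rep(42, 50))
  for (m in c("moving_average", "median", "breath_average")) {
    expect_equal(smooth_series(flat, m, 5)$vo2, flat$vo2)
  }
  spike <- uniform_series(0, 1, c(0, 0, 9, 0, 0))
  expect_equal(smooth_series(spike, "median", 3)$vo2, rep(0, 5))
  wig <- uniform_series(0, 1, c(3, 1, 4, 1, 5))
  expect_equal(smooth_series(wig, "moving_average", 1)$vo2, wig$vo2)
  expect_error(smooth_series(wig, "lowess", 3), "moving_average")
  expect_error(smooth_series(wig, "median", 0), "width")
})

test_that("peak VO2 is the mean of the last 30 seconds", {
  expect_equal(vo2peak_last30(uniform_series(0, 1, rep(50, 181))), 50)
  # linear ramp 40 -> 43 over the final 30 s (31 points): mean 41.5
  v <- c(rep(40, 150), seq(40, 43, by = 0.1))
  expect_equal(vo2peak_last30(uniform_series(0, 1, v)), 41.5)
  # exactly 30 s of data: mean of everything
  expect_equal(vo2peak_last30(uniform_series(0, 1, 1:31)), 16)
  expect_error(vo2peak_last30(uniform_series(0, 1, 1:20)), "30 s")
})

test_that("breath tables round-trip through the delimited reader", {
  b <- breath_series(c(0, 2.5, 5.1), c(10, 12.25, 18))
  path <- withr::local_tempfile(fileext = ".csv")
  write_breath_table(b, path, header = c(model = "demo"))
  back <- read_breath_table(path)
  expect_equal(back$t, b$t)
  expect_equal(back$vo2, b$vo2)

  # semicolon dialect with decimal commas
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time;vo2", "0;10,5", "2;12,25", "4;13,0"), path2)
  semi <- read_breath_table(path2)
  expect_equal(semi$vo2, c(10.5, 12.25, 13.0))

  # tab dialect
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time\tvo2", "0\t10", "2\t12"), path3)
  expect_equal(read_breath_table(path3)$vo2, c(10, 12))

  expect_error(read_breath_table(path, vo2_col = "nope"), "not found")
})

test_that("processed series writer embeds provenance as comment lines", {
  u <- uniform_series(0, 1, c(1, 2, 3), provenance = "demo-op")
  path <- withr::local_tempfile(fileext = ".csv")
  write_uniform_series(u, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# provenance: demo-op", lines)))
  expect_equal(utils::read.csv(path, comment.char = "#")$vo2, u$vo2)
})

test_that("exclusion plus interpolation recovers the clean curve", {
  spec <- vo2_model("off", "MONO_NO_TD")
  g <- generate_breaths(generator_config(spec, severe_off_truth, noise_sd = 0.5,
                                         errant_rate = 0.08, errant_magnitude = 20,
                                         seed = 99))
  u <- interpolate_1s(exclude_errant(g$breaths))
  clean <- eval_vo2(spec, severe_off_truth, series_times(u))
  # spikes removed: residual error at the noise/interpolation scale
  expect_lt(sqrt(mean((u$vo2 - clean)^2)), 3 * 0.5)
  # without exclusion the spikes dominate
  u_raw <- interpolate_1s(g$breaths)
  clean_raw <- eval_vo2(spec, severe_off_truth, series_times(u_raw))
  expect_gt(sqrt(mean((u_raw$vo2 - clean_raw)^2)),
            sqrt(mean((u$vo2 - clean)^2)))
})
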