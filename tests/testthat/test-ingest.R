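test_that("epoch CSV parsing validates schema, vocabulary and time order", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_tiny_epoch_csv(path, c("sitting", "walking", "sitting"), c(1, 5, 2))
  es <- read_epoch_csv(path)
  expect_s3_class(es, "epoch_series")
  expect_equal(nrow(es), 3L)
  expect_equal(es$category, c("sitting", "walking", "sitting"))

  write_tiny_epoch_csv(path, c("sitting", "jogging", "sitting"), c(1, 5, 2))
  expect_error(read_epoch_csv(path), "jogging.*row 2")

  df <- read.csv(path)
  write.csv(df[setdiff(names(df), "category")], path, row.names = FALSE)
  expect_error(read_epoch_csv(path), "missing column")

  t0 <- as.POSIXct("2024-03-04 08:00:00", tz = "UTC")
  write_tiny_epoch_csv(path, rep("sitting", 3), 1:3,
                       times = t0 + c(0, 10, 5))
  expect_error(read_epoch_csv(path), "non-monotone")
})

test_that("epoch CSV round trip is the identity on a gappy random series", {
  set.seed(71)
  n <- 1000
  t0 <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")
  # non-wear gaps: drop a contiguous block of the regular grid
  times <- (t0 + (0:(n + 199)) * 5)[-(401:600)][1:n]
  cats <- sample(activity_categories(), n, replace = TRUE)
  intens <- round(runif(n, 0, 50), 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tiny_epoch_csv(path, cats, intens, times = times)
  es <- read_epoch_csv(path)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_epoch_csv(es, path2)
  es2 <- read_epoch_csv(path2)
  expect_equal(es2$time, es$time)
  expect_equal(es2$category, es$category)
  expect_equal(es2$intensity, es$intensity)
  expect_identical(attr(es2, "subject_id"), attr(es, "subject_id"))
})

test_that("window aggregation computes fractions, counts and wear", {
  t0 <- as.POSIXct("2024-03-04 08:00:00", tz = "UTC")
  es <- epoch_series("s1", t0, rep("sitting", 180), rep(2, 180))
  ws <- aggregate_to_windows(es, 15)
  expect_equal(nrow(ws), 1L)
  expect_equal(ws$frac_sitting, 1.0)
  expect_equal(ws$wear_frac, 1.0)
  expect_equal(ws$count_sum, 360)

  es <- epoch_series("s1", t0, rep(c("walking", "sitting"), each = 90),
                     rep(1, 180))
  ws <- aggregate_to_windows(es, 15)
  expect_equal(ws$frac_walking, 0.5)
  expect_equal(ws$frac_sitting, 0.5)

  # 150 of 180 slots observed -> wear 5/6; fractions over all slots
  times <- t0 + (0:179) * 5
  keep <- -(61:90)
  es <- actidx:::new_epoch_series("s1", times[keep][1:150], rep("sitting", 150),
                                  rep(1, 150), "thigh", 5)
  ws <- aggregate_to_windows(es, 15)
  expect_equal(ws$wear_frac, 150 / 180)
  expect_equal(ws$frac_sitting + (1 - ws$wear_frac), 1)
})

test_that("aggregation conserves intensity and errors on bad input", {
  set.seed(5)
  t0 <- as.POSIXct("2024-03-04 08:03:20", tz = "UTC")  # unaligned start
  n <- 3000
  cats <- sample(activity_categories(), n, replace = TRUE)
  es <- epoch_series("s1", t0, cats, runif(n, 0, 10))
  ws <- aggregate_to_windows(es, 15)
  # retained = epochs inside the aggregated windows
  lo <- as.numeric(ws$window_start[1L])
  hi <- as.numeric(ws$window_start[nrow(ws)]) + 15 * 60
  retained <- as.numeric(es$time) >= lo & as.numeric(es$time) < hi
  expect_equal(sum(ws$count_sum), sum(es$intensity[retained]))
  fr <- as.matrix(ws[paste0("frac_", activity_categories())])
  expect_equal(unname(rowSums(fr)) + (1 - ws$wear_frac), rep(1, nrow(ws)))

  expect_error(aggregate_to_windows(es, 0.05), "multiple of the epoch length")
})

test_that("period slicing follows the 22:00 anchor and clock windows", {
  p <- group_profile("X", 20, 15)
  ws <- generate_subject_windows(p, 7, 11, "s1")
  expect_equal(n_full_periods(ws), 6L)
  full <- slice_period(ws, "full", 1)
  expect_equal(nrow(full), 96L)
  expect_equal(format(full$window_start[1L], "%H:%M"), "22:00")
  night <- slice_period(ws, "night", 1)
  day <- slice_period(ws, "day", 1)
  expect_equal(nrow(night), 24L)
  expect_equal(nrow(day), 48L)
  # sub-periods nest inside the full period without overlap
  expect_true(all(night$window_start %in% full$window_start))
  expect_true(all(day$window_start %in% full$window_start))
  expect_length(intersect(night$window_start, day$window_start), 0L)
  # night falls on the morning after the 22:00 anchor
  expect_equal(as.numeric(difftime(night$window_start[1L],
                                   full$window_start[1L], units = "hours")), 2)

  out <- slice_period(ws, "full", 40)
  expect_equal(nrow(out), 0L)
  expect_true(isTRUE(attr(out, "out_of_range")))
})

test_that("day validation applies the mean-wear rule", {
  counts <- rep(1, 96)
  ws <- one_period_windows(counts)
  expect_true(validate_day(ws))
  ws$wear_frac <- rep(0, 96)
  expect_false(validate_day(ws))
  # half the windows entirely absent -> mean wear 0.5 < 0.8
  half <- one_period_windows(counts)[1:48, ]
  attr(half, "subject_id") <- "s1"; attr(half, "window_length") <- 15
  class(half) <- c("window_series", "data.frame")
  expect_false(validate_day(half, 0.8))
  expect_true(validate_day(half, 0.5))
})

test_that("window CSV round trip preserves the series", {
  p <- group_profile("X", 20, 15)
  ws <- generate_subject_windows(p, 2, 3, "w1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_window_csv(ws, path)
  back <- read_window_csv(path)[["w1"]]
  expect_equal(back$count_sum, ws$count_sum, tolerance = 1e-8)
  expect_equal(back$frac_walking, ws$frac_walking, tolerance = 1e-8)
  expect_equal(back$window_start, ws$window_start)
})

test_that("manifest reading enforces the closed diagnosis set", {
  m <- tiny_manifest(c("a", "b"), c("AD", "HC"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest_csv(m, path)
  back <- read_manifest_csv(path)
  expect_equal(back$diagnosis, c("AD", "HC"))
  expect_type(back$antidepressant, "logical")
  m$diagnosis[2] <- "ALS"
  write_manifest_csv(m, path)
  expect_error(read_manifest_csv(path), "unknown diagnosis")
})
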