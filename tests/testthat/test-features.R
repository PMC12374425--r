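test_that("intra-daily variability matches hand evaluations and the oracle", {
  expect_equal(intradaily_variability(c(1, 2, 3, 4)), 0.8)
  # even-length alternations attain the maximum of 4, at any scale or offset
  expect_equal(intradaily_variability(c(0, 1, 0, 1)), 4.0)
  expect_equal(intradaily_variability(rep(c(3, 7), 5)), 4.0)
  expect_equal(intradaily_variability(rep(c(-2, 2), 8)), 4.0)
  expect_true(is.na(intradaily_variability(rep(5, 10))))
  expect_error(intradaily_variability(c(1, 2)), "at least 3")

  set.seed(42)
  for (r in 1:200) {
    x <- rnorm(sample(3:200, 1))
    expect_equal(intradaily_variability(x), iv_oracle(x), tolerance = 1e-12)
  }
})

test_that("IV is invariant to shifts and positive scalings", {
  set.seed(9)
  for (r in 1:25) {
    x <- runif(50)
    base <- intradaily_variability(x)
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 100)
    expect_equal(intradaily_variability(a * x + b), base, tolerance = 1e-10)
  }
})

test_that("IV of white noise concentrates near 2", {
  set.seed(101)
  ivs <- replicate(100, intradaily_variability(rnorm(96)))
  expect_gt(mean(ivs), 1.8)
  expect_lt(mean(ivs), 2.2)
})

test_that("threshold-exceedance percentages use strict inequality", {
  expect_equal(pct_windows_above(c(0.00, 0.06, 0.30, 0.20), 0.05), 75)
  expect_equal(pct_windows_above(rep(0, 10), 0.25), 0)
  expect_equal(pct_windows_above(rep(1, 4), 0.25), 100)
  expect_equal(pct_windows_above(c(0.05, 0.051), 0.05), 50)  # 0.05 not > 0.05
  expect_true(is.na(pct_windows_above(numeric(0), 0.05)))
})

test_that("M10/L5 equals the exhaustive search on random days", {
  set.seed(202)
  for (r in 1:200) {
    counts <- runif(96, 0, 100)
    got <- m10_l5(counts)
    want <- m10_l5_oracle(counts)
    expect_equal(got$m10, want$m10, tolerance = 1e-12)
    expect_equal(got$l5, want$l5, tolerance = 1e-12)
    expect_equal(got$m10_onset, want$m10_onset)
    expect_equal(got$l5_onset, want$l5_onset)
  }
})

test_that("M10/L5 saturation, ties and relative amplitude behave exactly", {
  counts <- rep(0, 96); counts[17:56] <- 55  # one contiguous 10-h span
  ind <- m10_l5(counts)
  expect_equal(ind$m10, 55)
  expect_equal(ind$l5, 0)
  expect_equal(relative_amplitude(ind$m10, ind$l5), 1)

  flat <- m10_l5(rep(7, 96))
  expect_equal(flat$m10, 7)
  expect_equal(flat$l5, 7)
  expect_equal(flat$m10_onset, 22)  # earliest start wins ties
  expect_equal(flat$l5_onset, 22)
  expect_equal(relative_amplitude(7, 7), 0)

  expect_equal(relative_amplitude(1135.4, 24.5), 0.9577550, tolerance = 1e-6)
  expect_true(is.na(relative_amplitude(0, 0)))
  expect_error(m10_l5(rep(1, 10)), "full 24-h")
})

test_that("RA increases monotonically as L5 decreases at fixed M10", {
  l5s <- seq(90, 0, by = -10)
  ras <- vapply(l5s, function(l) relative_amplitude(100, l), numeric(1))
  expect_true(all(diff(ras) > 0))
})

test_that("per-day extraction handles the all-sitting constant day", {
  ws <- one_period_windows(rep(30, 96), category = "sitting")
  fv <- extract_day_features(ws)
  expect_equal(unname(fv[c("full__sitting__mean", "night__sitting__mean",
                           "day__sitting__mean")]), c(1, 1, 1))
  expect_true(is.na(fv["full__sitting__iv"]))
  expect_true(is.na(fv["full__count__iv"]))
  expect_equal(unname(fv["full__count__ra"]), 0)
  expect_equal(unname(fv["full__count__mean_sitting"]), 30)
  expect_equal(unname(fv["full__sitting__pct25"]), 100)
})

test_that("the square-wave day yields RA 1 and period means by construction", {
  # active span = windows 17..56 i.e. 02:00-12:00 after the 22:00 anchor
  ws <- square_wave_day(level = 80, onset_window = 17)
  fv <- extract_day_features(ws)
  expect_equal(unname(fv["full__count__ra"]), 1)
  expect_equal(unname(fv["full__count__m10"]), 80)
  expect_equal(unname(fv["full__count__l5"]), 0)
  # night (00:00-06:00) = windows 9..32: 16 of 24 windows inside the span
  expect_equal(unname(fv["night__count__mean"]), 80 * 16 / 24)
  # day (09:00-21:00) = windows 45..92: 12 of 48 windows inside the span
  expect_equal(unname(fv["day__count__mean"]), 80 * 12 / 48)
  expect_equal(unname(fv["full__count__mean"]), 80 * 40 / 96)
})

test_that("the registry count identity holds for default and modified registries", {
  regs <- list(
    feature_registry(),
    feature_registry(include_events = FALSE),
    feature_registry(categories = c("sitting", "walking", "lying_rest"),
                     include_circadian = FALSE)
  )
  for (reg in regs) {
    per_period <- table(reg$period)
    expect_equal(length(registry_summary_names(reg)), 2L * nrow(reg))
    expect_equal(nrow(reg), sum(per_period))
    expect_false(anyDuplicated(reg$name) > 0)
  }
  expect_equal(nrow(regs[[1]]), 161L)
  expect_equal(length(registry_summary_names(regs[[1]])), 322L)
})

test_that("subject summarization averages days and uses unbiased variance", {
  v1 <- c(a = 1, b = 10)
  v2 <- c(a = 3, b = 10)
  s <- summarize_subject(list(v1, v2))
  expect_equal(unname(s["a__avg"]), 2)
  expect_equal(unname(s["a__var"]), 2)  # (1-2)^2 + (3-2)^2 / (2-1)
  expect_equal(unname(s["b__var"]), 0)
  expect_length(s, 4L)
  one <- summarize_subject(list(v1))
  expect_true(all(is.na(one[c("a__var", "b__var")])))
  expect_error(summarize_subject(list()), "no valid days")
})

test_that("cohort feature extraction excludes subjects without valid days", {
  p <- group_profile("HC", 30, 20)
  ws1 <- generate_subject_windows(p, 3, 1, "good")
  ws2 <- generate_subject_windows(p, 3, 2, "bad")
  ws2$wear_frac <- rep(0.1, nrow(ws2))
  ft <- extract_features(list(good = ws1, bad = ws2),
                         manifest = tiny_manifest(c("good", "bad"), c("HC", "HC")))
  expect_equal(ft$subject_id, "good")
  expect_equal(attr(ft, "excluded"), "bad")
  reg <- attr(ft, "registry")
  expect_true(all(registry_summary_names(reg) %in% names(ft)))
})

test_that("feature CSV round trip keeps values and registry sidecar", {
  p <- group_profile("HC", 30, 20)
  ft <- extract_features(list(s1 = generate_subject_windows(p, 3, 1, "s1")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(ft, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_feature_csv(path)
  expect_equal(back$full__count__mean__avg, ft$full__count__mean__avg,
               tolerance = 1e-8)
  expect_equal(nrow(attr(back, "registry")), nrow(attr(ft, "registry")))
})
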