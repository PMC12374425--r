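# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# epoch CSV text for a regular 5-s grid starting at `start`
write_tiny_epoch_csv <- function(path, categories, intensity,
                                 start = "2024-03-04T08:00:00",
                                 subject = "s1", site = "thigh",
                                 times = NULL) {
  t0 <- as.POSIXct(start, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  if (is.null(times)) times <- t0 + (seq_along(categories) - 1L) * 5
  df <- data.frame(subject_id = subject, sensor_site = site,
                   timestamp_iso8601 = format(times, "%Y-%m-%dT%H:%M:%S"),
                   category = categories, intensity = intensity)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# a window series of one full 22:00-anchored period from a count vector;
# all activity assigned to one category at full wear
one_period_windows <- function(counts, category = "sitting",
                               subject = "s1", window_length = 15,
                               start = "2024-03-04 22:00:00") {
  n <- length(counts)
  starts <- as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1L) * window_length * 60
  fr <- matrix(0, n, length(activity_categories()),
               dimnames = list(NULL, activity_categories()))
  fr[, category] <- 1
  window_series(subject, starts, fr, counts,
                sit_to_stand = rep(0, n), step_count = rep(0, n),
                wear_frac = rep(1, n), window_length = window_length)
}

# square-wave day: counts = level over one contiguous 10-h span, 0 elsewhere
square_wave_day <- function(level = 100, onset_window = 17) {
  counts <- rep(0, 96)
  counts[onset_window:(onset_window + 39L)] <- level
  one_period_windows(counts)
}

# direct transcription of the IV definition, kept free of the package's
# vectorized implementation
iv_oracle <- function(x) {
  n <- length(x)
  num <- 0
  for (i in 2:n) num <- num + (x[i] - x[i - 1])^2
  den <- 0
  xb <- sum(x) / n
  for (i in 1:n) den <- den + (xb - x[i])^2
  n * num / ((n - 1) * den)
}

# exhaustive M10/L5 search over every block start
m10_l5_oracle <- function(counts, window_length = 15, start_clock = 22) {
  per_hour <- 60 / window_length
  n <- length(counts)
  scan <- function(hours, pick) {
    len <- hours * per_hour
    best_val <- NULL; best_s <- NA
    for (s in 1:(n - len + 1)) {
      v <- mean(counts[s:(s + len - 1)])
      better <- if (is.null(best_val)) TRUE else
        if (pick == "max") v > best_val else v < best_val
      if (better) { best_val <- v; best_s <- s }
    }
    c(best_val, (start_clock + (best_s - 1) / per_hour) %% 24)
  }
  m <- scan(10, "max"); l <- scan(5, "min")
  list(m10 = m[1], m10_onset = m[2], l5 = l[1], l5_onset = l[2])
}

# a small manifest for hand-built window lists
tiny_manifest <- function(ids, dx) {
  data.frame(subject_id = ids, diagnosis = dx,
             age = 75, sex = rep(c("F", "M"), length.out = length(ids)),
             antidepressant = FALSE, antipsychotic = FALSE, hypnotic = FALSE,
             sedative_analgesic = FALSE, mmse = 27)
}
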