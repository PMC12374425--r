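#' Construct a window series
#'
#' A window series summarises an activity recording in clock-aligned windows
#' (15 minutes by default): per-category time fractions, the summed intensity
#' count, per-window event counts (sit-to-stand transitions, steps) and the
#' fraction of the window covered by valid wear.
#'
#' @param subject_id Subject identifier.
#' @param window_start POSIXct vector of window start times (strictly
#'   increasing, clock-aligned).
#' @param frac Data frame or matrix of per-category time fractions with one
#'   column per activity category (named `frac_<category>`, or bare category
#'   names which are prefixed automatically).
#' @param count_sum Numeric vector of summed intensity counts per window.
#' @param sit_to_stand,step_count Nonnegative per-window event counts.
#' @param wear_frac Fraction of each window with valid data, in `[0, 1]`.
#' @param window_length Window length in minutes (default 15).
#' @return An object of class `window_series`.
#' @export
window_series <- function(subject_id, window_start, frac, count_sum,
                          sit_to_stand, step_count, wear_frac,
                          window_length = 15) {
  frac <- as.data.frame(frac)
  bare <- names(frac) %in% activity_categories()
  names(frac)[bare] <- paste0("frac_", names(frac)[bare])
  expected <- paste0("frac_", activity_categories())
  missing <- setdiff(expected, names(frac))
  for (m in missing) frac[[m]] <- 0
  frac <- frac[expected]
  n <- length(window_start)
  stopifnot(nrow(frac) == n, length(count_sum) == n, length(wear_frac) == n)
  if (is.unsorted(window_start, strictly = TRUE)) {
    stop("window_start must be strictly increasing", call. = FALSE)
  }
  fsum <- rowSums(frac)
  if (any(frac < -1e-9) || any(fsum > 1 + 1e-9)) {
    stop("per-category fractions must be in [0,1] and sum to at most 1", call. = FALSE)
  }
  if (any(wear_frac < -1e-9 | wear_frac > 1 + 1e-9)) {
    stop("wear_frac must lie in [0,1]", call. = FALSE)
  }
  out <- data.frame(window_start = window_start,
                    wear_frac = pmin(pmax(wear_frac, 0), 1),
                    count_sum = as.numeric(count_sum),
                    sit_to_stand = as.numeric(sit_to_stand),
                    step_count = as.numeric(step_count))
  out <- cbind(out, frac)
  structure(out,
            subject_id = as.character(subject_id),
            window_length = as.numeric(window_length),
            class = c("window_series", "data.frame"))
}

#' @export
print.window_series <- function(x, ...) {
  cat(sprintf("<window_series> subject %s: %d windows of %g min from %s\n",
              attr(x, "subject_id"), nrow(x), attr(x, "window_length"),
              format(x$window_start[1L], "%Y-%m-%d %H:%M")))
  invisible(x)
}

#' Aggregate an epoch series to clock-aligned windows
#'
#' Windows are aligned to the local clock (starts at multiples of
#' `window_length` past midnight, e.g. ..., 21:45, 22:00, 22:15, ...). Leading
#' epochs before the first aligned boundary and any trailing partial window
#' are dropped. Missing epochs count as non-wear: `wear_frac` is the observed
#' share of the window's epoch slots, and category fractions are taken over
#' all slots, so per window the fractions plus the non-wear share sum to 1.
#'
#' Event signals are derived from the epoch stream: `sit_to_stand` counts
#' consecutive-epoch transitions from sitting into upright standing, and
#' `step_count` applies a nominal cadence per locomotor epoch (documented in
#' the methods vignette).
#'
#' @param epochs An [epoch_series()].
#' @param window_length Window length in minutes; must be a positive multiple
#'   of the epoch length.
#' @return A [window_series()].
#' @export
aggregate_to_windows <- function(epochs, window_length = 15) {
  stopifnot(inherits(epochs, "epoch_series"))
  if (nrow(epochs) == 0L) stop("empty epoch series", call. = FALSE)
  ep_len <- attr(epochs, "epoch_length")
  win_sec <- window_length * 60
  if (window_length <= 0 || win_sec %% ep_len != 0) {
    stop("window_length must be a positive multiple of the epoch length", call. = FALSE)
  }
  slots <- win_sec / ep_len

  t0 <- as.numeric(epochs$time[1L])
  midnight <- as.numeric(as.POSIXct(trunc(epochs$time[1L], "days")))
  first_start <- midnight + ceiling((t0 - midnight) / win_sec) * win_sec
  tnum <- as.numeric(epochs$time)
  keep <- tnum >= first_start
  if (!any(keep)) stop("recording shorter than one window", call. = FALSE)
  tnum <- tnum[keep]
  cat_v <- epochs$category[keep]
  int_v <- epochs$intensity[keep]

  idx <- floor((tnum - first_start) / win_sec)
  n_win <- floor((tnum[length(tnum)] - first_start + ep_len) / win_sec)
  if (n_win < 1L) stop("recording shorter than one window", call. = FALSE)
  full <- idx < n_win
  idx <- idx[full]; cat_v <- cat_v[full]; int_v <- int_v[full]; tnum <- tnum[full]

  fidx <- factor(idx, levels = 0:(n_win - 1L))
  observed <- as.integer(table(fidx))
  count_sum <- as.numeric(tapply(int_v, fidx, sum, default = 0))

  cats <- activity_categories()
  frac <- matrix(0, nrow = n_win, ncol = length(cats),
                 dimnames = list(NULL, cats))
  tab <- table(fidx, factor(cat_v, levels = cats))
  frac[,] <- as.matrix(tab) / slots

  # sit-to-stand: consecutive epochs (no wear gap) sitting -> upright_standing
  n <- length(idx)
  sts <- numeric(n_win)
  if (n > 1L) {
    consec <- diff(tnum) == ep_len
    trans <- consec & cat_v[-n] == "sitting" & cat_v[-1L] == "upright_standing"
    if (any(trans)) {
      tt <- table(factor(idx[-1L][trans], levels = 0:(n_win - 1L)))
      sts <- as.numeric(tt)
    }
  }

  cadence <- c(sporadic_walking = 4, walking = 8, moderate_intensity = 9,
               running = 12) * (ep_len / 5)
  steps_per_epoch <- cadence[cat_v]
  steps_per_epoch[is.na(steps_per_epoch)] <- 0
  steps <- as.numeric(tapply(steps_per_epoch, fidx, sum, default = 0))

  window_series(attr(epochs, "subject_id"),
                as.POSIXct(first_start + (0:(n_win - 1L)) * win_sec,
                           tz = "UTC", origin = "1970-01-01"),
                frac, count_sum, sts, steps,
                wear_frac = observed / slots,
                window_length = window_length)
}

#' Clock-time analysis periods
#'
#' The three analysis periods: the full 24-hour period anchored at 22:00
#' (10 PM to 10 PM next day), night (midnight to 6 AM) and day (9 AM to 9 PM).
#'
#' @param name One of `"full"`, `"night"`, `"day"`.
#' @return A list with `name`, `start_clock` and `end_clock` (hours past
#'   midnight) and `anchor_offset_days` (the civil-day offset of the period's
#'   start relative to the full period's 22:00 anchor).
#' @export
period_definition <- function(name = c("full", "night", "day")) {
  name <- match.arg(name)
  switch(name,
    full  = list(name = "full",  start_clock = 22, end_clock = 22, anchor_offset_days = 0),
    night = list(name = "night", start_clock = 0,  end_clock = 6,  anchor_offset_days = 1),
    day   = list(name = "day",   start_clock = 9,  end_clock = 21, anchor_offset_days = 1)
  )
}

#' Slice a window series to one analysis period of one civil day
#'
#' The full period for day `d` spans 22:00 of day `d` to 22:00 of day `d + 1`;
#' its night and day sub-periods fall on the morning and daytime of day
#' `d + 1`. Day index 1 anchors at 22:00 of the recording's first civil day.
#' Membership is decided by the window's start time (half-open interval), so
#' the slicing is deterministic at any window resolution.
#'
#' @param ws A [window_series()].
#' @param period A period name or [period_definition()].
#' @param civil_day_index 1-based index of the full period within the recording.
#' @return A [window_series()] restricted to the period; zero rows (with
#'   attribute `out_of_range = TRUE`) when the requested day lies outside the
#'   recording.
#' @export
slice_period <- function(ws, period = "full", civil_day_index = 1L) {
  stopifnot(inherits(ws, "window_series"))
  if (is.character(period)) period <- period_definition(period)
  day0 <- as.POSIXct(trunc(ws$window_start[1L], "days"))
  anchor <- day0 + (civil_day_index - 1L + period$anchor_offset_days) * 86400 +
    period$start_clock * 3600
  span_h <- (period$end_clock - period$start_clock) %% 24
  if (span_h == 0) span_h <- 24
  lo <- as.numeric(anchor)
  hi <- lo + span_h * 3600
  t <- as.numeric(ws$window_start)
  sel <- t >= lo & t < hi
  out <- ws[sel, , drop = FALSE]
  attr(out, "subject_id") <- attr(ws, "subject_id")
  attr(out, "window_length") <- attr(ws, "window_length")
  class(out) <- class(ws)
  if (!any(sel)) attr(out, "out_of_range") <- TRUE
  out
}

#' Number of complete full periods in a recording
#'
#' @param ws A [window_series()].
#' @return Integer count of 22:00-to-22:00 periods entirely covered by the
#'   recording's window grid (by window start times).
#' @export
n_full_periods <- function(ws) {
  win_sec <- attr(ws, "window_length") * 60
  expected <- 86400 / win_sec
  d <- 0L
  repeat {
    sl <- slice_period(ws, "full", d + 1L)
    if (nrow(sl) < expected) break
    d <- d + 1L
  }
  d
}

#' Validate one full period for feature extraction
#'
#' @param ws A [window_series()] holding one full period.
#' @param min_wear Minimum mean wear fraction (default 0.8). The mean is taken
#'   over all expected windows of the period, so entirely absent windows count
#'   as zero wear.
#' @return `TRUE` if the period has enough valid wear to enter feature
#'   summarisation.
#' @export
validate_day <- function(ws, min_wear = 0.8) {
  expected <- 86400 / (attr(ws, "window_length") * 60)
  sum(ws$wear_frac) / expected >= min_wear
}

#' Write / read a window series CSV
#'
#' Columns: `subject_id,window_start,wear_frac,count_sum,sit_to_stand,`
#' `step_count,frac_<category>...`. [read_window_csv()] accepts files holding
#' several subjects and returns a named list of window series.
#'
#' @param ws A [window_series()] or list of them.
#' @param path CSV path.
#' @return `path` invisibly for the writer; a named list of
#'   [window_series()] for the reader.
#' @export
write_window_csv <- function(ws, path) {
  if (inherits(ws, "window_series")) ws <- list(ws)
  rows <- lapply(ws, function(w) {
    cbind(data.frame(subject_id = attr(w, "subject_id"),
                     window_start = format(w$window_start, "%Y-%m-%dT%H:%M:%S")),
          as.data.frame(w)[setdiff(names(w), "window_start")])
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_window_csv
#' @param window_length Window length in minutes of the stored series.
#' @export
read_window_csv <- function(path, window_length = 15) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "window_start", "wear_frac", "count_sum",
                "sit_to_stand", "step_count", paste0("frac_", activity_categories()))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("window CSV schema error: missing column(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- lapply(split(df, df$subject_id), function(d) {
    window_series(d$subject_id[1L],
                  as.POSIXct(d$window_start, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S"),
                  d[paste0("frac_", activity_categories())],
                  d$count_sum, d$sit_to_stand, d$step_count, d$wear_frac,
                  window_length = window_length)
  })
  out[unique(df$subject_id)]
}
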