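#' Intra-daily variability
#'
#' Fragmentation index of a rest--activity series: the ratio of the mean
#' squared successive difference to the overall variance,
#' \deqn{IV = \frac{n \sum_{i=2}^{n}(x_i - x_{i-1})^2}{(n-1)\sum_{i=1}^{n}(\bar x - x_i)^2}.}
#' A smooth consolidated rhythm gives values near 0, white noise gives values
#' near 2, and rapid alternation approaches the maximum of 4 (attained by an
#' even-length 0/1 alternating sequence).
#'
#' @param x Numeric sequence (at least 3 values). `NA`s are dropped with the
#'   remaining values kept in order.
#' @return The IV as a dimensionless number; `NA` for a constant sequence
#'   (zero variance makes the index undefined).
#' @export
intradaily_variability <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stop("intradaily_variability needs at least 3 values", call. = FALSE)
  denom <- (n - 1) * sum((x - mean(x))^2)
  if (denom == 0) return(NA_real_)
  n * sum(diff(x)^2) / denom
}

#' Percentage of windows above a time-fraction threshold
#'
#' @param fracs Per-window time fractions in `[0, 1]`.
#' @param threshold Fraction threshold; exceedance is strict (`>`).
#' @return Percentage of windows strictly above the threshold, or `NA` for
#'   empty input.
#' @export
pct_windows_above <- function(fracs, threshold) {
  fracs <- fracs[!is.na(fracs)]
  if (length(fracs) == 0L) return(NA_real_)
  100 * mean(fracs > threshold)
}

#' M10 and L5: most and least active contiguous hours
#'
#' Scans all contiguous 10-hour (M10) and 5-hour (L5) blocks of a single
#' 24-hour period, stepping one window at a time without wrapping past the
#' period boundary, and returns the extreme block means together with the
#' clock time of the winning block's start. Ties go to the earliest start.
#'
#' @param counts Per-window intensity counts covering one full period, in
#'   window order; `NA` marks absent windows (at most 10% may be missing).
#' @param window_length Window length in minutes.
#' @param start_clock Clock hour of the first window (default 22, the
#'   10 PM anchor of the full period).
#' @return List with `m10`, `m10_onset`, `l5`, `l5_onset` (onsets as clock
#'   hours in `[0, 24)`).
#' @export
m10_l5 <- function(counts, window_length = 15, start_clock = 22) {
  per_hour <- 60 / window_length
  n <- length(counts)
  if (n * window_length < 24 * 60) stop("m10_l5 requires a full 24-h period", call. = FALSE)
  if (mean(is.na(counts)) > 0.1) {
    return(list(m10 = NA_real_, m10_onset = NA_real_,
                l5 = NA_real_, l5_onset = NA_real_))
  }
  block_stat <- function(hours, pick) {
    len <- as.integer(hours * per_hour)
    if (len > n) stop("period shorter than block", call. = FALSE)
    means <- vapply(seq_len(n - len + 1L), function(s) {
      mean(counts[s:(s + len - 1L)], na.rm = TRUE)
    }, numeric(1))
    s <- if (pick == "max") which.max(means) else which.min(means)
    onset <- (start_clock + (s - 1L) * window_length / 60) %% 24
    c(means[s], onset)
  }
  m <- block_stat(10, "max")
  l <- block_stat(5, "min")
  list(m10 = m[1L], m10_onset = m[2L], l5 = l[1L], l5_onset = l[2L])
}

#' Relative amplitude of the rest--activity rhythm
#'
#' @param m10,l5 Mean counts of the most active 10 and least active 5 hours,
#'   with `m10 >= l5 >= 0`.
#' @return `(m10 - l5) / (m10 + l5)` in `[0, 1]`; `NA` when both are zero
#'   (or either is missing).
#' @export
relative_amplitude <- function(m10, l5) {
  if (is.na(m10) || is.na(l5)) return(NA_real_)
  if (m10 + l5 == 0) return(NA_real_)
  (m10 - l5) / (m10 + l5)
}
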