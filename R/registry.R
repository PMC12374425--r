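#' Feature registry
#'
#' The ordered catalogue of per-day features. For every analysis period
#' (full 22:00--22:00, night 00:00--06:00, day 09:00--21:00):
#' * each activity category's window time-fraction series yields its mean,
#'   the percentage of windows above 5/10/25% time in the category, and the
#'   intra-daily variability of the fraction sequence;
#' * the intensity-count series yields its mean, its mean during windows whose
#'   modal category is sitting, and its IV; in the full period only, also
#'   M10 and L5 with their onset times and the relative amplitude;
#' * each event signal (sit-to-stand, steps) yields its mean and IV.
#'
#' Per-subject summary features apply `avg` and `var` across valid days to
#' every per-day feature, so the summary count is exactly twice the per-day
#' count (322 = 2 x 161 for the default registry).
#'
#' @param categories Activity categories to include (default all nine).
#' @param include_events Include the sit-to-stand and step-count signals.
#' @param include_circadian Include M10/L5/onsets/RA (full period only).
#' @return Data frame with columns `period`, `signal`, `stat` and canonical
#'   `name` (`<period>__<signal>__<stat>`), of class `feature_registry`.
#' @export
feature_registry <- function(categories = activity_categories(),
                             include_events = TRUE,
                             include_circadian = TRUE) {
  stopifnot(all(categories %in% activity_categories()))
  periods <- c("full", "night", "day")
  rows <- list()
  add <- function(period, signal, stat) {
    rows[[length(rows) + 1L]] <<- data.frame(period = period, signal = signal,
                                             stat = stat)
  }
  for (p in periods) {
    for (cat in categories) {
      for (s in c("mean", "pct5", "pct10", "pct25", "iv")) add(p, cat, s)
    }
    for (s in c("mean", "mean_sitting", "iv")) add(p, "count", s)
    if (p == "full" && include_circadian) {
      for (s in c("m10", "m10_onset", "l5", "l5_onset", "ra")) add(p, "count", s)
    }
    if (include_events) {
      for (ev in event_signals()) for (s in c("mean", "iv")) add(p, ev, s)
    }
  }
  reg <- do.call(rbind, rows)
  reg$name <- paste(reg$period, reg$signal, reg$stat, sep = "__")
  stopifnot(!anyDuplicated(reg$name))
  structure(reg, class = c("feature_registry", "data.frame"))
}

#' Summary feature names of a registry
#'
#' @param registry A [feature_registry()].
#' @return Character vector of the `__avg` and `__var` summary names, in
#'   registry order (all averages first, then all variances).
#' @export
registry_summary_names <- function(registry) {
  c(paste0(registry$name, "__avg"), paste0(registry$name, "__var"))
}
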