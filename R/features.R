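# Per-day feature extraction and per-subject summarization.

# Lay a sliced period onto its expected window grid; absent windows become NA.
period_grid <- function(ws_full, period, window_length) {
  per_day <- 86400 / (window_length * 60)
  pd <- if (is.character(period)) period_definition(period) else period
  span_h <- (pd$end_clock - pd$start_clock) %% 24
  if (span_h == 0) span_h <- 24
  n_expected <- span_h * 3600 / (window_length * 60)
  if (nrow(ws_full) == 0L) return(NULL)
  anchor <- as.numeric(ws_full$window_start[1L])
  # ws_full starts at the 22:00 anchor of its period
  offset_h <- (pd$start_clock - 22) %% 24
  lo <- anchor + offset_h * 3600
  idx <- (as.numeric(ws_full$window_start) - lo) / (window_length * 60)
  sel <- idx >= 0 & idx < n_expected
  grid_rows <- rep(NA_integer_, n_expected)
  grid_rows[idx[sel] + 1L] <- which(sel)
  list(rows = grid_rows, n = n_expected)
}

# Modal category of each window: the category with the largest time fraction
# (ties to canonical order); NA when no category time was observed.
modal_category <- function(ws) {
  fr <- as.matrix(ws[paste0("frac_", activity_categories())])
  if (nrow(fr) == 0L) return(character(0))
  top <- max.col(fr, ties.method = "first")
  out <- activity_categories()[top]
  out[rowSums(fr) == 0] <- NA_character_
  out
}

#' Extract the per-day feature vector for one full period
#'
#' Computes every registry feature on one validated 22:00--22:00 period:
#' category time-fraction statistics, intensity-count statistics (including
#' the mean during sitting-modal windows and, for the full period, M10/L5
#' with onsets and relative amplitude) and event-signal statistics, each over
#' the full, night and day clock periods. Absent windows enter as missing and
#' are ignored by the statistics; IV is computed over the observed windows in
#' order.
#'
#' @param ws A [window_series()] holding exactly one full period (as returned
#'   by [slice_period()]), already validated with [validate_day()].
#' @param registry A [feature_registry()].
#' @return Named numeric vector in registry order.
#' @export
extract_day_features <- function(ws, registry = feature_registry()) {
  stopifnot(inherits(ws, "window_series"))
  if (nrow(ws) == 0L) stop("cannot extract features from an empty day", call. = FALSE)
  wl <- attr(ws, "window_length")
  modal <- modal_category(ws)

  out <- numeric(nrow(registry))
  names(out) <- registry$name

  safe_iv <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 3L) return(NA_real_)
    intradaily_variability(x)
  }

  for (p in unique(registry$period)) {
    g <- period_grid(ws, p, wl)
    rows <- g$rows
    pres <- !is.na(rows)
    sub <- ws[rows[pres], , drop = FALSE]
    reg_p <- registry[registry$period == p, , drop = FALSE]
    counts <- rep(NA_real_, g$n); counts[pres] <- sub$count_sum
    modal_p <- rep(NA_character_, g$n); modal_p[pres] <- modal[rows[pres]]
    circ <- NULL  # M10/L5 cache, shared by the five circadian stats
    for (r in seq_len(nrow(reg_p))) {
      sig <- reg_p$signal[r]; st <- reg_p$stat[r]
      val <- if (sig %in% activity_categories()) {
        x <- rep(NA_real_, g$n); x[pres] <- sub[[paste0("frac_", sig)]]
        switch(st,
               mean  = if (any(pres)) mean(x, na.rm = TRUE) else NA_real_,
               pct5  = pct_windows_above(x, 0.05),
               pct10 = pct_windows_above(x, 0.10),
               pct25 = pct_windows_above(x, 0.25),
               iv    = safe_iv(x))
      } else if (sig == "count") {
        switch(st,
               mean = if (any(pres)) mean(counts, na.rm = TRUE) else NA_real_,
               mean_sitting = {
                 sitw <- !is.na(modal_p) & modal_p == "sitting"
                 if (any(sitw)) mean(counts[sitw], na.rm = TRUE) else NA_real_
               },
               iv = safe_iv(counts),
               m10 = , m10_onset = , l5 = , l5_onset = , ra = {
                 if (is.null(circ)) {
                   circ <- m10_l5(counts, window_length = wl, start_clock = 22)
                 }
                 switch(st, m10 = circ$m10, m10_onset = circ$m10_onset,
                        l5 = circ$l5, l5_onset = circ$l5_onset,
                        ra = relative_amplitude(circ$m10, circ$l5))
               })
      } else {  # event signals
        x <- rep(NA_real_, g$n); x[pres] <- sub[[sig]]
        switch(st,
               mean = if (any(pres)) mean(x, na.rm = TRUE) else NA_real_,
               iv = safe_iv(x))
      }
      out[reg_p$name[r]] <- val
    }
  }
  out
}

#' Summarize per-day feature vectors into one subject row
#'
#' Each per-day feature is summarized by its average across valid days
#' (ignoring missing day values) and its unbiased (n-1) variance. Variances
#' need at least two non-missing days and are `NA` otherwise.
#'
#' @param day_vectors List of named per-day vectors from
#'   [extract_day_features()] (at least one).
#' @return Named numeric vector of length `2 * length(day_vectors[[1]])`
#'   with `__avg` then `__var` suffixes.
#' @export
summarize_subject <- function(day_vectors) {
  if (length(day_vectors) == 0L) stop("no valid days to summarize", call. = FALSE)
  m <- do.call(rbind, day_vectors)
  avg <- colMeans(m, na.rm = TRUE)
  avg[is.nan(avg)] <- NA_real_
  vr <- apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2L) NA_real_ else stats::var(col)
  })
  out <- c(avg, vr)
  names(out) <- c(paste0(colnames(m), "__avg"), paste0(colnames(m), "__var"))
  out
}

#' Build the subjects-by-features table for a cohort
#'
#' Splits each subject's window series into complete full periods, drops
#' periods failing the wear criterion, extracts per-day features and
#' summarizes them by average and variance across days. Subjects with no
#' valid day are excluded (recorded in the `excluded` attribute); subjects
#' with a single valid day keep `NA` variances and are flagged.
#'
#' @param windows_list Named list of [window_series()], one per subject.
#' @param manifest Manifest data frame (see [read_manifest_csv()]); joined on
#'   `subject_id` when supplied.
#' @param registry A [feature_registry()].
#' @param min_wear Minimum mean wear fraction per day (default 0.8).
#' @return Data frame of class `feature_table`: `subject_id`, summary feature
#'   columns in registry order, then any manifest columns. Attributes:
#'   `registry`, `excluded` (subject ids with zero valid days),
#'   `single_day` (subject ids with exactly one valid day), `n_days` (named
#'   vector of valid-day counts).
#' @export
extract_features <- function(windows_list, manifest = NULL,
                             registry = feature_registry(), min_wear = 0.8) {
  stopifnot(length(windows_list) > 0L)
  excluded <- character(0)
  single_day <- character(0)
  n_days <- integer(0)
  rows <- list()
  for (ws in windows_list) {
    sid <- attr(ws, "subject_id")
    nd <- n_full_periods(ws)
    days <- list()
    for (d in seq_len(nd)) {
      day <- slice_period(ws, "full", d)
      if (validate_day(day, min_wear)) {
        days[[length(days) + 1L]] <- extract_day_features(day, registry)
      }
    }
    n_days[sid] <- length(days)
    if (length(days) == 0L) {
      excluded <- c(excluded, sid)
      next
    }
    if (length(days) == 1L) single_day <- c(single_day, sid)
    rows[[sid]] <- summarize_subject(days)
  }
  if (length(rows) == 0L) stop("no subject has a valid day", call. = FALSE)
  ft <- as.data.frame(do.call(rbind, rows))
  ft <- cbind(data.frame(subject_id = names(rows), stringsAsFactors = FALSE), ft)
  rownames(ft) <- NULL
  if (!is.null(manifest)) {
    ft <- merge(ft, manifest, by = "subject_id", sort = FALSE)
  }
  structure(ft, registry = registry, excluded = excluded,
            single_day = single_day, n_days = n_days,
            class = c("feature_table", "data.frame"))
}

#' Write / read a feature table CSV with a JSON registry sidecar
#'
#' The CSV holds `subject_id` followed by registry-ordered summary features
#' and manifest columns; `<path>.json` records the registry definition and
#' package version so a table is self-describing.
#'
#' @param ft A `feature_table` from [extract_features()].
#' @param path Output CSV path.
#' @return `path` invisibly; the reader returns the data frame with the
#'   registry re-attached when the sidecar is present.
#' @export
write_feature_csv <- function(ft, path) {
  utils::write.csv(as.data.frame(ft), path, row.names = FALSE)
  reg <- attr(ft, "registry")
  sidecar <- list(
    package = "actidx",
    version = as.character(utils::packageVersion("actidx")),
    registry = as.data.frame(reg)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  sidecar <- paste0(path, ".json")
  reg <- NULL
  if (file.exists(sidecar)) {
    reg <- as.data.frame(jsonlite::read_json(sidecar, simplifyVector = TRUE)$registry)
    class(reg) <- c("feature_registry", "data.frame")
  }
  structure(df, registry = reg, class = c("feature_table", "data.frame"))
}
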