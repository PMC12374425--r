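#' Construct an epoch series
#'
#' An epoch series is the per-subject, per-sensor record of classified
#' 5-second epochs: one activity category and one nonnegative intensity count
#' per epoch, on a regular grid starting at `start_time`. Timestamps are
#' timezone-naive local clock times (represented internally as UTC POSIXct;
#' daylight-saving arithmetic is deliberately out of scope).
#'
#' @param subject_id Subject identifier string.
#' @param start_time POSIXct (or ISO-8601 string) of the first epoch.
#' @param category Character vector of activity categories, one per epoch.
#' @param intensity Nonnegative numeric vector of intensity counts (unitless).
#' @param sensor_site `"thigh"` (default) or `"chest"`.
#' @param epoch_length Epoch duration in seconds (default 5).
#' @return An object of class `epoch_series`: a data frame with columns
#'   `time`, `category`, `intensity` and attributes `subject_id`,
#'   `sensor_site`, `epoch_length`.
#' @export
epoch_series <- function(subject_id, start_time, category, intensity,
                         sensor_site = c("thigh", "chest"), epoch_length = 5) {
  sensor_site <- match.arg(sensor_site)
  if (length(category) != length(intensity)) {
    stop("category and intensity must have equal length", call. = FALSE)
  }
  if (length(category) == 0L) stop("empty epoch series", call. = FALSE)
  if (any(intensity < 0)) stop("intensity counts must be nonnegative", call. = FALSE)
  assert_category(category)
  start_time <- as_naive_time(start_time)
  n <- length(category)
  new_epoch_series(subject_id, start_time + (seq_len(n) - 1L) * epoch_length,
                   category, intensity, sensor_site, epoch_length)
}

# internal constructor with explicit timestamps; gaps in the grid encode
# non-wear, so times need only be strictly increasing
new_epoch_series <- function(subject_id, time, category, intensity,
                             sensor_site, epoch_length) {
  if (is.unsorted(time, strictly = TRUE)) {
    stop("epoch timestamps must be strictly increasing", call. = FALSE)
  }
  out <- data.frame(time = time, category = category,
                    intensity = as.numeric(intensity))
  structure(out,
            subject_id = as.character(subject_id),
            sensor_site = sensor_site,
            epoch_length = as.numeric(epoch_length),
            class = c("epoch_series", "data.frame"))
}

as_naive_time <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, "%Y-%m-%d %H:%M:%S"), tz = "UTC"))
  as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> subject %s, %s sensor: %d epochs of %gs from %s\n",
              attr(x, "subject_id"), attr(x, "sensor_site"), nrow(x),
              attr(x, "epoch_length"), format(x$time[1L], "%Y-%m-%d %H:%M:%S")))
  invisible(x)
}

#' Read an epoch-level activity CSV
#'
#' Expected header: `subject_id,sensor_site,timestamp_iso8601,category,intensity`
#' with one row per epoch. Rows out of time order are rejected, not silently
#' sorted, so that upstream export problems surface.
#'
#' @param path CSV file path.
#' @param epoch_length Epoch duration in seconds (default 5).
#' @return An [epoch_series()].
#' @export
read_epoch_csv <- function(path, epoch_length = 5) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("subject_id", "sensor_site", "timestamp_iso8601", "category", "intensity")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("epoch CSV schema error: missing column(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("epoch CSV contains no rows", call. = FALSE)
  if (length(unique(df$subject_id)) != 1L || length(unique(df$sensor_site)) != 1L) {
    stop("epoch CSV must contain a single subject_id and sensor_site", call. = FALSE)
  }
  assert_category(df$category)
  times <- as.POSIXct(df$timestamp_iso8601, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  if (anyNA(times)) {
    stop(sprintf("unparseable timestamp at row %d", which(is.na(times))[1L]), call. = FALSE)
  }
  dt <- diff(as.numeric(times))
  if (any(dt <= 0)) {
    stop(sprintf("non-monotone timestamps at row %d", which(dt <= 0)[1L] + 1L),
         call. = FALSE)
  }
  intensity <- suppressWarnings(as.numeric(df$intensity))
  if (anyNA(intensity) || any(intensity < 0)) {
    stop("intensity must be a nonnegative number in every row", call. = FALSE)
  }
  site <- match.arg(df$sensor_site[1L], c("thigh", "chest"))
  new_epoch_series(df$subject_id[1L], times, df$category, intensity,
                   sensor_site = site, epoch_length = epoch_length)
}

#' Write an epoch series to CSV
#'
#' Inverse of [read_epoch_csv()]; the round trip is the identity.
#'
#' @param es An [epoch_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(es, path) {
  stopifnot(inherits(es, "epoch_series"))
  df <- data.frame(
    subject_id = attr(es, "subject_id"),
    sensor_site = attr(es, "sensor_site"),
    timestamp_iso8601 = format(es$time, "%Y-%m-%dT%H:%M:%S"),
    category = es$category,
    intensity = es$intensity
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a subject manifest CSV
#'
#' Columns: `subject_id,diagnosis,age,sex,antidepressant,antipsychotic,`
#' `hypnotic,sedative_analgesic,mmse`. Diagnoses come from the closed set
#' AD, DLB, MixedAD, VCD, HC.
#'
#' @param path Manifest CSV path.
#' @return Data frame with typed columns (logical medication flags).
#' @export
read_manifest_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "diagnosis", "age", "sex", "antidepressant",
                "antipsychotic", "hypnotic", "sedative_analgesic", "mmse")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("manifest schema error: missing column(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  validate_manifest(df)
}

validate_manifest <- function(df) {
  bad <- setdiff(unique(df$diagnosis), diagnosis_levels())
  if (length(bad) > 0L) {
    stop(sprintf("unknown diagnosis label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (any(df$age <= 0)) stop("age must be positive", call. = FALSE)
  if (anyDuplicated(df$subject_id)) stop("duplicate subject_id in manifest", call. = FALSE)
  for (flag in c("antidepressant", "antipsychotic", "hypnotic", "sedative_analgesic")) {
    df[[flag]] <- as.logical(df[[flag]])
  }
  df
}

#' Diagnosis labels
#' @return Character vector of the five diagnostic groups.
#' @export
diagnosis_levels <- function() c("AD", "DLB", "MixedAD", "VCD", "HC")

#' Write a subject manifest CSV
#' @param manifest Data frame as returned by [read_manifest_csv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest_csv <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
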