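#' Activity category vocabulary
#'
#' The closed set of behaviour labels assigned to each 5-second epoch by the
#' sensor system's activity classifier: postures (upright standing, sitting,
#' lying rest, lying movement), locomotion (sporadic walking, walking, running,
#' moderate intensity i.e. brisk walking) and cycling. Two event-type signals,
#' sit-to-stand transitions and step counts, are attached to 15-minute windows
#' rather than to epochs.
#'
#' @return Character vector of the nine category names, in canonical order.
#' @export
activity_categories <- function() {
  c("upright_standing", "sporadic_walking", "walking", "running",
    "moderate_intensity", "lying_rest", "lying_movement", "sitting", "cycling")
}

#' Window-level event signals
#'
#' @return Character vector naming the per-window event-count signals.
#' @export
event_signals <- function() c("sit_to_stand", "step_count")

# categories counted as locomotion when deriving step counts from epochs
walking_like_categories <- function() {
  c("sporadic_walking", "walking", "running", "moderate_intensity")
}

assert_category <- function(x, context = "category") {
  bad <- which(!x %in% activity_categories())
  if (length(bad) > 0L) {
    stop(sprintf("unknown %s '%s' at row %d", context, x[bad[1L]], bad[1L]),
         call. = FALSE)
  }
  invisible(x)
}
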