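# Synthetic rest--activity cohort generator.
#
# The generative model works at the window level (15 minutes by default).
# A deterministic circadian drive (mesor + 24-h cosine + optional afternoon
# Gaussian bump) sets both the expected intensity and the rest/active gate;
# a two-state disruption chain driven by frag_rate fragments the gate;
# nighttime wake bouts are injected at a Poisson rate per night. Categories
# are drawn conditionally on the behavioural state, walking in geometric
# bouts, and window intensity counts are drawn conditionally on the emitted
# category mix so that composition and counts stay consistent. Epoch-level
# series are an exact refinement of the window structure.

#' Group-level generative profile
#'
#' @param name Group label (one of the diagnosis labels, or any string).
#' @param mesor Mean intensity count per 15-minute window (unitless).
#' @param amplitude Peak-to-mesor amplitude of the 24-h cosine drive
#'   (must not exceed `mesor`).
#' @param acrophase Clock hour of the cosine peak (default 14).
#' @param afternoon_bump Length-3 numeric `c(height, center_hour, width_hours)`
#'   Gaussian bump added to the drive; `c(0, 17, 1.5)` disables it. By default
#'   only the healthy-control preset carries a nonzero bump.
#' @param frag_rate Per-window probability of entering a state disruption
#'   (rest during the active block or vice versa); drives rhythm
#'   fragmentation and hence IV.
#' @param night_wake_rate Expected number of injected active windows per
#'   night (00:00--06:00).
#' @param category_mix List with elements `rest` and `active`: named
#'   probability vectors over activity categories, each summing to 1.
#' @param walk_bout_mean Mean length (windows) of contiguous walking bouts.
#' @param noise_sd SD of the multiplicative log-normal noise on counts.
#' @return A `group_profile` list.
#' @export
group_profile <- function(name, mesor, amplitude, acrophase = 14,
                          afternoon_bump = c(0, 17, 1.5),
                          frag_rate = 0.15, night_wake_rate = 1,
                          category_mix = default_category_mix(),
                          walk_bout_mean = 2, noise_sd = 0.35) {
  stopifnot(mesor - amplitude >= 0, frag_rate >= 0, night_wake_rate >= 0,
            length(afternoon_bump) == 3L, walk_bout_mean >= 1)
  for (st in c("rest", "active")) {
    mix <- category_mix[[st]]
    stopifnot(all(names(mix) %in% activity_categories()),
              abs(sum(mix) - 1) < 1e-8, all(mix >= 0))
  }
  structure(list(name = name, mesor = mesor, amplitude = amplitude,
                 acrophase = acrophase, afternoon_bump = afternoon_bump,
                 frag_rate = frag_rate, night_wake_rate = night_wake_rate,
                 category_mix = category_mix, walk_bout_mean = walk_bout_mean,
                 noise_sd = noise_sd),
            class = "group_profile")
}

#' Default rest/active category mixes
#'
#' @param walking Total probability mass on walking-type categories in the
#'   active state.
#' @param cycling Probability of cycling in the active state.
#' @return List with `rest` and `active` probability vectors.
#' @export
default_category_mix <- function(walking = 0.30, cycling = 0.01) {
  rest <- c(lying_rest = 0.92, lying_movement = 0.05, sitting = 0.03)
  upright <- 1 - walking - cycling
  active <- c(sitting = upright * 0.55, upright_standing = upright * 0.45,
              sporadic_walking = walking * 0.45, walking = walking * 0.40,
              moderate_intensity = walking * 0.12, running = walking * 0.03,
              cycling = cycling)
  list(rest = rest / sum(rest), active = active / sum(active))
}

# relative intensity weight of each category (unit mean under sitting)
category_intensity_weight <- function() {
  c(lying_rest = 0.05, lying_movement = 0.35, sitting = 1.0,
    upright_standing = 2.2, sporadic_walking = 4.5, walking = 7.5,
    moderate_intensity = 11.0, running = 16.0, cycling = 9.0)
}

circadian_drive <- function(profile, hours) {
  bump <- profile$afternoon_bump
  d <- profile$mesor +
    profile$amplitude * cos(2 * pi * (hours - profile$acrophase) / 24)
  if (bump[1] != 0) {
    dd <- (hours - bump[2] + 12) %% 24 - 12
    d <- d + bump[1] * exp(-0.5 * (dd / bump[3])^2)
  }
  pmax(d, 0)
}

# deterministic rest/active gate plus the frag_rate disruption chain
simulate_states <- function(profile, hours) {
  drive <- circadian_drive(profile, hours)
  rng <- range(drive)
  w <- if (diff(rng) < 1e-12) rep(0.5, length(drive)) else
    (drive - rng[1]) / diff(rng)
  gate <- as.integer(w >= 0.5)
  n <- length(hours)
  e <- integer(n)
  u <- stats::runif(n)
  state <- 0L
  for (t in seq_len(n)) {
    state <- if (state == 0L) as.integer(u[t] < profile$frag_rate)
             else as.integer(u[t] >= 0.5)  # mean disruption bout: 2 windows
    e[t] <- state
  }
  st <- as.integer(xor(gate == 1L, e == 1L))
  # nighttime wake injections
  night <- hours >= 0 & hours < 6
  if (profile$night_wake_rate > 0 && any(night)) {
    nights <- cumsum(c(TRUE, diff(night) == 1))  # night-bout index
    for (b in unique(nights[night])) {
      idx <- which(night & nights == b)
      k <- stats::rpois(1, profile$night_wake_rate)
      if (k > 0) st[sample(idx, min(k, length(idx)))] <- 1L
    }
  }
  list(state = st, drive = drive)
}

# draw per-window modal categories with geometric walking bouts
simulate_categories <- function(profile, state) {
  n <- length(state)
  cats <- character(n)
  mix_rest <- profile$category_mix$rest
  mix_active <- profile$category_mix$active
  walk_cont_p <- 1 - 1 / profile$walk_bout_mean
  bout <- FALSE
  for (t in seq_len(n)) {
    if (state[t] == 0L) {
      bout <- FALSE
      cats[t] <- sample(names(mix_rest), 1L, prob = mix_rest)
    } else if (bout && stats::runif(1) < walk_cont_p) {
      cats[t] <- "walking"
    } else {
      cats[t] <- sample(names(mix_active), 1L, prob = mix_active)
      bout <- cats[t] %in% c("walking", "sporadic_walking")
    }
  }
  cats
}

#' Simulate one subject as a window series
#'
#' @param profile A [group_profile()].
#' @param days Number of recording days (>= 1).
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @param subject_id Subject identifier.
#' @param window_length Window length in minutes (default 15).
#' @param start_date Date of the first midnight of the recording.
#' @return A [window_series()] covering `days` civil days from midnight.
#' @export
generate_subject_windows <- function(profile, days, seed,
                                     subject_id = profile$name,
                                     window_length = 15,
                                     start_date = "2024-03-04") {
  if (days < 1) stop("days must be at least 1", call. = FALSE)
  set.seed(seed)
  per_day <- 86400 / (window_length * 60)
  n <- days * per_day
  start <- as.POSIXct(paste0(start_date, " 00:00:00"), tz = "UTC")
  starts <- start + (seq_len(n) - 1L) * window_length * 60
  hours <- (((seq_len(n) - 1L) + 0.5) * window_length / 60) %% 24

  sim <- simulate_states(profile, hours)
  cats <- simulate_categories(profile, sim$state)

  wgt <- category_intensity_weight()
  cmix <- profile$category_mix
  # normalize so a window's expected count matches the drive when the
  # category mix equals the state-conditional average
  wbar <- sum(cmix$active * wgt[names(cmix$active)])

  modal_frac <- stats::runif(n, 0.75, 0.95)
  filler <- ifelse(sim$state == 1L, "sitting", "lying_rest")
  filler[filler == cats] <- ifelse(sim$state[filler == cats] == 1L,
                                   "upright_standing", "lying_movement")
  fr <- matrix(0, nrow = n, ncol = length(activity_categories()),
               dimnames = list(NULL, activity_categories()))
  fr[cbind(seq_len(n), match(cats, colnames(fr)))] <- modal_frac
  fr[cbind(seq_len(n), match(filler, colnames(fr)))] <-
    fr[cbind(seq_len(n), match(filler, colnames(fr)))] + (1 - modal_frac)

  relwgt <- as.numeric(fr %*% wgt[colnames(fr)]) / wbar
  noise <- exp(stats::rnorm(n, -profile$noise_sd^2 / 2, profile$noise_sd))
  counts <- pmax(0, sim$drive * relwgt * noise)

  sts <- stats::rpois(n, 1.5 * sim$state * fr[, "sitting"] * 4)
  spm <- c(sporadic_walking = 55, walking = 95, moderate_intensity = 110,
           running = 150)
  walk_frac <- fr[, names(spm), drop = FALSE]
  steps <- round(as.numeric(walk_frac %*% spm) * window_length)

  window_series(subject_id, starts, fr, counts, sts, steps,
                wear_frac = rep(1, n), window_length = window_length)
}

#' Simulate one subject as an epoch series
#'
#' Generates the window-level structure with [generate_subject_windows()]
#' (same seed, identical structure) and refines each window into 5-second
#' epochs: category epochs proportional to the window's fractions, intensity
#' distributed over epochs proportionally to each category's intensity
#' weight so that re-aggregation recovers the window counts.
#'
#' @inheritParams generate_subject_windows
#' @param epoch_length Epoch length in seconds (default 5).
#' @return An [epoch_series()].
#' @export
generate_subject <- function(profile, days, seed, subject_id = profile$name,
                             window_length = 15, epoch_length = 5,
                             start_date = "2024-03-04") {
  ws <- generate_subject_windows(profile, days, seed, subject_id,
                                 window_length, start_date)
  slots <- window_length * 60 / epoch_length
  fr <- as.matrix(ws[paste0("frac_", activity_categories())])
  n <- nrow(ws)
  wgt <- category_intensity_weight()
  cats_all <- character(n * slots)
  int_all <- numeric(n * slots)
  for (t in seq_len(n)) {
    alloc <- round(fr[t, ] * slots)
    # fix rounding so the window is exactly filled
    excess <- sum(alloc) - slots
    if (excess != 0) {
      j <- which.max(alloc)
      alloc[j] <- alloc[j] - excess
    }
    cats <- rep(activity_categories(), times = alloc)
    w <- wgt[cats]
    int_all[((t - 1) * slots + 1):(t * slots)] <- ws$count_sum[t] * w / sum(w)
    cats_all[((t - 1) * slots + 1):(t * slots)] <- cats
  }
  epoch_series(subject_id, ws$window_start[1L], cats_all, int_all,
               sensor_site = "thigh", epoch_length = epoch_length)
}

# deterministic sub-seed; stays well below 2^31
derive_seed <- function(master, index) {
  ((master %% 100000) * 10007 + index * 101 + 17) %% 2147483629
}

#' Cohort configuration
#'
#' @param profiles Named list of [group_profile()]s; names are group labels.
#' @param n Named integer vector of group sizes (same names as `profiles`).
#' @param days Recording days per subject (default 7).
#' @param window_length Window length in minutes.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @param covariates Optional named list (per group) of lists with
#'   `age_mean`, `age_sd`, `prop_female`, `mmse_mean`, `mmse_sd` and
#'   medication prevalences; defaults mirror a memory-clinic cohort.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(profiles, n, days = 7, window_length = 15,
                          seed = 1, covariates = NULL) {
  if (anyDuplicated(names(profiles))) stop("duplicate group names", call. = FALSE)
  stopifnot(all(names(n) %in% names(profiles)), all(n >= 1))
  structure(list(profiles = profiles, n = n, days = days,
                 window_length = window_length, seed = seed,
                 covariates = covariates),
            class = "cohort_config")
}

default_covariates <- function(group) {
  base <- list(age_mean = 75, age_sd = 7, prop_female = 0.45,
               mmse_mean = 26, mmse_sd = 3,
               antidepressant = 0.1, antipsychotic = 0.02,
               hypnotic = 0.01, sedative_analgesic = 0.02)
  tweaks <- list(
    HC = list(age_mean = 71.1, age_sd = 7.8, prop_female = 0.625,
              mmse_mean = 29.1, mmse_sd = 1.1, antidepressant = 0.06),
    AD = list(age_mean = 75.3, age_sd = 7.1, prop_female = 0.471,
              mmse_mean = 25.5, mmse_sd = 2.7),
    DLB = list(age_mean = 76.2, age_sd = 6.4, prop_female = 0.138,
               mmse_mean = 26.2, mmse_sd = 2.9, antidepressant = 0.14),
    MixedAD = list(age_mean = 81.8, age_sd = 3.3, prop_female = 0.5,
                   mmse_mean = 22.6, mmse_sd = 2.8),
    VCD = list(age_mean = 78.5, age_sd = 5.9, prop_female = 0.333,
               mmse_mean = 26.5, mmse_sd = 2.9, antidepressant = 0.2)
  )
  if (group %in% names(tweaks)) utils::modifyList(base, tweaks[[group]]) else base
}

#' Generate a synthetic cohort
#'
#' Subjects are generated independently with per-subject seeds derived from
#' the master seed, so the output is reproducible and insensitive to
#' generation order. Manifest covariates (age, sex, medication flags, MMSE)
#' are drawn from the per-group covariate model.
#'
#' @param config A [cohort_config()].
#' @param mode `"windows"` (default) to return window series, `"epochs"` for
#'   epoch series.
#' @return List with `data` (named list of series) and `manifest`.
#' @export
generate_cohort <- function(config, mode = c("windows", "epochs")) {
  mode <- match.arg(mode)
  rows <- list()
  data <- list()
  idx <- 0L
  for (g in names(config$n)) {
    prof <- config$profiles[[g]]
    cov <- if (!is.null(config$covariates[[g]])) config$covariates[[g]]
           else default_covariates(g)
    for (i in seq_len(config$n[[g]])) {
      idx <- idx + 1L
      sid <- sprintf("S%03d_%s", idx, g)
      sseed <- derive_seed(config$seed, idx)
      data[[sid]] <- if (mode == "windows") {
        generate_subject_windows(prof, config$days, sseed, subject_id = sid,
                                 window_length = config$window_length)
      } else {
        generate_subject(prof, config$days, sseed, subject_id = sid,
                         window_length = config$window_length)
      }
      set.seed(derive_seed(config$seed, idx) + 1)
      rows[[sid]] <- data.frame(
        subject_id = sid, diagnosis = g,
        age = round(max(50, stats::rnorm(1, cov$age_mean, cov$age_sd))),
        sex = ifelse(stats::runif(1) < cov$prop_female, "F", "M"),
        antidepressant = stats::runif(1) < cov$antidepressant,
        antipsychotic = stats::runif(1) < cov$antipsychotic,
        hypnotic = stats::runif(1) < cov$hypnotic,
        sedative_analgesic = stats::runif(1) < cov$sedative_analgesic,
        mmse = min(30L, max(0L, round(stats::rnorm(1, cov$mmse_mean, cov$mmse_sd))))
      )
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  list(data = data, manifest = validate_manifest(manifest))
}

#' Preset cohort emulating the study's group-level activity structure
#'
#' Encodes the direction and coarse magnitude of the published group
#' contrasts as generative targets: overall intensity ordered
#' HC > AD > DLB > MixedAD/VCD; elevated least-active-5-hour activity (more
#' nighttime wake, weaker amplitude) in DLB and the cerebrovascular groups;
#' more fragmented rhythm (higher frag_rate, shorter walking bouts) in
#' non-AD dementias; and a late-afternoon activity bump present only in
#' healthy controls. These are generative means for a synthetic cohort, not
#' a fit to any clinical dataset.
#'
#' @param n Named group sizes; defaults to the study's sizes
#'   (AD 70, DLB 29, MixedAD 8, VCD 15, HC 48).
#' @param days,window_length,seed Passed to [cohort_config()].
#' @return A [cohort_config()].
#' @export
cohort_preset_table2 <- function(n = c(AD = 70, DLB = 29, MixedAD = 8,
                                       VCD = 15, HC = 48),
                                 days = 7, window_length = 15, seed = 1) {
  profiles <- list(
    HC = group_profile("HC", mesor = 39.1, amplitude = 30,
                       afternoon_bump = c(18, 16.5, 1.5),
                       frag_rate = 0.10, night_wake_rate = 1.0,
                       category_mix = default_category_mix(walking = 0.34, cycling = 0.02),
                       walk_bout_mean = 3, noise_sd = 0.35),
    AD = group_profile("AD", mesor = 31.7, amplitude = 24,
                       frag_rate = 0.13, night_wake_rate = 1.3,
                       category_mix = default_category_mix(walking = 0.32, cycling = 0.01),
                       walk_bout_mean = 2.5, noise_sd = 0.35),
    DLB = group_profile("DLB", mesor = 29.1, amplitude = 17,
                        frag_rate = 0.30, night_wake_rate = 5.0,
                        category_mix = default_category_mix(walking = 0.26, cycling = 0.03),
                        walk_bout_mean = 1.5, noise_sd = 0.40),
    MixedAD = group_profile("MixedAD", mesor = 19.5, amplitude = 11,
                            frag_rate = 0.30, night_wake_rate = 4.5,
                            category_mix = default_category_mix(walking = 0.22, cycling = 0.002),
                            walk_bout_mean = 1.4, noise_sd = 0.40),
    VCD = group_profile("VCD", mesor = 21.4, amplitude = 12,
                        frag_rate = 0.28, night_wake_rate = 4.5,
                        category_mix = default_category_mix(walking = 0.22, cycling = 0.005),
                        walk_bout_mean = 1.5, noise_sd = 0.40)
  )
  cohort_config(profiles[names(n)], n, days = days,
                window_length = window_length, seed = seed)
}

#' Analytic expected mean window count in the no-noise limit
#'
#' Used by tests to check that the realized overall intensity tracks the
#' profile's drive after the rest/active duty-cycle correction. Ignores
#' nighttime wake injections (a small upward correction).
#'
#' @param profile A [group_profile()].
#' @param window_length Window length in minutes.
#' @return Expected mean count per window over a 24-h day.
#' @export
expected_mean_count <- function(profile, window_length = 15) {
  per_day <- 86400 / (window_length * 60)
  hours <- ((seq_len(per_day) - 1L) + 0.5) * window_length / 60
  drive <- circadian_drive(profile, hours)
  rng <- range(drive)
  w <- if (diff(rng) < 1e-12) rep(0.5, length(drive)) else
    (drive - rng[1]) / diff(rng)
  gate <- as.numeric(w >= 0.5)
  p_dis <- profile$frag_rate / (profile$frag_rate + 0.5)
  p_active <- gate * (1 - p_dis) + (1 - gate) * p_dis

  wgt <- category_intensity_weight()
  wbar <- sum(profile$category_mix$active * wgt[names(profile$category_mix$active)])
  mf <- 0.85  # mean modal fraction
  mix_mean <- function(mix, fill) {
    mf * sum(mix * wgt[names(mix)]) + (1 - mf) * wgt[[fill]]
  }
  r_active <- mix_mean(profile$category_mix$active, "sitting") / wbar
  r_rest <- mix_mean(profile$category_mix$rest, "lying_rest") / wbar
  mean(drive * (p_active * r_active + (1 - p_active) * r_rest))
}
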