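# Descriptive group-comparison layer: Kruskal-Wallis tables, smoothed
# group-average 24-h intensity curves, actograms and the output-probability
# confounder probe.

#' Kruskal--Wallis rank-sum test
#'
#' Tie-corrected rank-based H with the chi-square approximation on
#' `groups - 1` degrees of freedom (delegates to [stats::kruskal.test()]).
#' The degenerate all-constant input returns H = 0, p = 1 rather than NaN.
#'
#' @param values Numeric observations (missing values dropped).
#' @param groups Group labels, same length as `values`.
#' @return List with `H`, `p` and `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.character(groups)
  ok <- !is.na(values)
  empty <- setdiff(unique(groups), unique(groups[ok]))
  if (length(empty) > 0L) {
    stop(sprintf("group '%s' has no non-missing values", empty[1L]), call. = FALSE)
  }
  values <- values[ok]; groups <- groups[ok]
  ng <- length(unique(groups))
  if (ng < 2L) stop("at least 2 groups required", call. = FALSE)
  if (length(unique(values)) == 1L) {
    return(list(H = 0, p = 1, df = ng - 1L))
  }
  kt <- stats::kruskal.test(values, factor(groups))
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Group comparison table over features
#'
#' Per feature: mean and SD within each diagnostic group plus the
#' Kruskal--Wallis H and p-value across groups. No multiplicity correction
#' is applied (the screen is descriptive).
#'
#' @param ft A `feature_table` with a `diagnosis` column.
#' @param features Feature column names (default: all registry summary
#'   averages).
#' @return Data frame: one row per feature with `<group>_mean`, `<group>_sd`
#'   columns, `H` and `p`.
#' @export
group_comparison_table <- function(ft, features = NULL) {
  stopifnot("diagnosis" %in% names(ft))
  if (is.null(features)) {
    reg <- attr(ft, "registry")
    features <- if (!is.null(reg)) {
      intersect(paste0(reg$name, "__avg"), names(ft))
    } else {
      grep("__avg$", names(ft), value = TRUE)
    }
  }
  groups <- sort(unique(ft$diagnosis))
  rows <- lapply(features, function(f) {
    v <- ft[[f]]
    row <- list(feature = f)
    for (g in groups) {
      vg <- v[ft$diagnosis == g]
      row[[paste0(g, "_mean")]] <- mean(vg, na.rm = TRUE)
      row[[paste0(g, "_sd")]] <- stats::sd(vg[!is.na(vg)])
    }
    kw <- kruskal_wallis(v, ft$diagnosis)
    row$H <- kw$H; row$p <- kw$p
    as.data.frame(row)
  })
  do.call(rbind, rows)
}

#' Daily minutes per activity category, per group
#'
#' Mirrors the descriptive table of time spent per category: per subject the
#' mean daily minutes in each category (running and cycling as minutes per
#' week), then per-group mean and SD with a Kruskal--Wallis p-value.
#'
#' @param windows_list Named list of [window_series()].
#' @param manifest Manifest with `subject_id` and `diagnosis`.
#' @return Data frame with one row per category.
#' @export
activity_minutes_table <- function(windows_list, manifest) {
  per_subject <- lapply(windows_list, function(ws) {
    wl <- attr(ws, "window_length")
    fr <- as.matrix(ws[paste0("frac_", activity_categories())])
    daily_min <- colMeans(fr) * 1440
    c(daily_min, sit_to_stand = mean(ws$sit_to_stand) * 1440 / wl)
  })
  m <- do.call(rbind, per_subject)
  colnames(m) <- sub("^frac_", "", colnames(m))
  weekly <- c("running", "cycling")
  m[, weekly] <- m[, weekly] * 7
  dx <- manifest$diagnosis[match(rownames(m), manifest$subject_id)]
  groups <- sort(unique(dx))
  rows <- lapply(colnames(m), function(cat) {
    unit <- if (cat %in% weekly) "min/week" else
      if (cat == "sit_to_stand") "n/day" else "min/day"
    row <- list(category = cat, unit = unit)
    for (g in groups) {
      vg <- m[dx == g, cat]
      row[[paste0(g, "_mean")]] <- mean(vg)
      row[[paste0(g, "_sd")]] <- stats::sd(vg)
    }
    row$p <- if (length(groups) >= 2L) kruskal_wallis(m[, cat], dx)$p else NA_real_
    as.data.frame(row)
  })
  do.call(rbind, rows)
}

# circular centered 1-h moving average at 15-min resolution: weights
# (1/2, 1, 1, 1, 1/2)/4 so exactly one hour of windows surrounds each point
# and the daily mean is conserved
smooth_hour_circular <- function(x, window_length = 15) {
  k <- 60 / window_length  # windows per hour
  half <- k / 2
  offs <- seq(-ceiling(half), ceiling(half))
  wts <- ifelse(abs(offs) <= half - 0.5, 1, pmax(0, half + 0.5 - abs(offs)))
  wts <- wts / sum(wts)
  n <- length(x)
  out <- numeric(n)
  for (j in seq_along(offs)) {
    out <- out + wts[j] * x[((seq_len(n) - 1 + offs[j]) %% n) + 1]
  }
  out
}

#' Group-average smoothed 24-hour intensity curve
#'
#' Per clock window, the mean intensity count over all of each subject's
#' days, smoothed by a centered one-hour circular moving average; the group
#' curve is the mean over subjects with a standard-error band across
#' subjects.
#'
#' @param windows_list Named list of [window_series()] (15-minute
#'   resolution).
#' @param manifest Manifest with `subject_id` and `diagnosis`.
#' @return Data frame with `group`, `clock_hour`, `mean`, `se`, `n`.
#' @export
group_mean_curve <- function(windows_list, manifest) {
  dx <- manifest$diagnosis[match(names(windows_list), manifest$subject_id)]
  if (anyNA(dx)) stop("subjects missing from manifest", call. = FALSE)
  wl <- attr(windows_list[[1L]], "window_length")
  per_day <- 86400 / (wl * 60)
  profile_of <- function(ws) {
    day0 <- as.numeric(as.POSIXct(trunc(ws$window_start[1L], "days")))
    slot <- floor(((as.numeric(ws$window_start) - day0) %% 86400) / (wl * 60))
    prof <- tapply(ws$count_sum, factor(slot, levels = 0:(per_day - 1L)),
                   mean, na.rm = TRUE)
    smooth_hour_circular(as.numeric(prof), wl)
  }
  profiles <- t(vapply(windows_list, profile_of, numeric(per_day)))
  out <- list()
  for (g in sort(unique(dx))) {
    pg <- profiles[dx == g, , drop = FALSE]
    if (nrow(pg) == 0L) stop(sprintf("empty group %s", g), call. = FALSE)
    out[[g]] <- data.frame(
      group = g,
      clock_hour = (0:(per_day - 1L)) * wl / 60,
      mean = colMeans(pg),
      se = if (nrow(pg) == 1L) 0 else apply(pg, 2, stats::sd) / sqrt(nrow(pg)),
      n = nrow(pg))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plot group-average 24-hour intensity curves
#'
#' @param curve Output of [group_mean_curve()].
#' @return A ggplot object (mean lines with SE ribbons).
#' @export
plot_group_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = clock_hour, y = mean,
                                      color = group, fill = group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - se, ymax = mean + se),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 4)) +
    ggplot2::labs(x = "Clock time (h)", y = "Mean intensity count / window",
                  color = "Group", fill = "Group") +
    ggplot2::theme_minimal()
}

#' Confounder probe on classifier output probabilities
#'
#' Ordinary least-squares regression of the out-of-fold probability on age,
#' sex and medication flags within one subgroup (healthy controls or the
#' pooled disease groups), to check whether demographic or medication
#' differences rather than activity structure drive the classifier output.
#' Constant or collinear covariates are dropped with a warning. The response
#' can optionally be logit-transformed.
#'
#' @param probs Out-of-fold probabilities, one per manifest row (named by
#'   subject or aligned with `manifest`).
#' @param manifest Manifest data frame.
#' @param subgroup `"HC"` or `"disease"`.
#' @param logit Regress on `log(p / (1 - p))` instead of `p`.
#' @return Data frame of coefficients with estimate, SE, t and p columns.
#' @export
confounder_probe <- function(probs, manifest, subgroup = c("disease", "HC"),
                             logit = FALSE) {
  subgroup <- match.arg(subgroup)
  sel <- if (subgroup == "HC") manifest$diagnosis == "HC" else
    manifest$diagnosis != "HC"
  if (sum(sel) < 2L) stop("subgroup has fewer than 2 subjects", call. = FALSE)
  df <- manifest[sel, , drop = FALSE]
  df$prob <- probs[sel]
  if (logit) {
    eps <- 1e-6
    p <- pmin(pmax(df$prob, eps), 1 - eps)
    df$prob <- log(p / (1 - p))
  }
  covars <- c("age", "sex", "antidepressant", "antipsychotic", "hypnotic",
              "sedative_analgesic")
  usable <- covars[vapply(covars, function(cv) {
    length(unique(df[[cv]])) > 1L
  }, logical(1))]
  dropped <- setdiff(covars, usable)
  if (length(dropped) > 0L) {
    warning(sprintf("constant covariate(s) dropped: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  if (length(usable) == 0L) stop("no usable covariates", call. = FALSE)
  fml <- stats::as.formula(paste("prob ~", paste(usable, collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)$coefficients
  out <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                    t = sm[, 3], p = sm[, 4])
  rownames(out) <- NULL
  out
}

#' Render an actogram
#'
#' One row per civil day, colored by each window's modal activity category,
#' with deterministic colors keyed by category name.
#'
#' @param ws A [window_series()] covering at least one day.
#' @param out Optional image path (PNG/SVG by extension); when `NULL` the
#'   ggplot object is returned without writing.
#' @param width,height Device size in inches.
#' @return The ggplot object (invisibly when written to file).
#' @export
render_actogram <- function(ws, out = NULL, width = 8, height = 4) {
  stopifnot(inherits(ws, "window_series"))
  wl <- attr(ws, "window_length")
  day0 <- as.numeric(as.POSIXct(trunc(ws$window_start[1L], "days")))
  tnum <- as.numeric(ws$window_start)
  df <- data.frame(
    day = floor((tnum - day0) / 86400) + 1,
    clock_hour = ((tnum - day0) %% 86400) / 3600,
    category = modal_category(ws))
  df <- df[!is.na(df$category), , drop = FALSE]
  pal <- c(upright_standing = "#66c2a5", sporadic_walking = "#fc8d62",
           walking = "#e41a1c", running = "#7b3294", moderate_intensity = "#d95f02",
           lying_rest = "#313695", lying_movement = "#74add1",
           sitting = "#ffd92f", cycling = "#a6d854")
  gp <- ggplot2::ggplot(df, ggplot2::aes(x = clock_hour, y = factor(-day),
                                         fill = category)) +
    ggplot2::geom_tile(width = wl / 60, height = 0.9) +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::scale_y_discrete(labels = function(l) paste("day", -as.numeric(l))) +
    ggplot2::labs(x = "Clock time (h)", y = NULL, fill = "Category",
                  title = sprintf("Actogram: %s", attr(ws, "subject_id"))) +
    ggplot2::theme_minimal()
  if (!is.null(out)) {
    ggplot2::ggsave(out, gp, width = width, height = height, dpi = 150)
    return(invisible(gp))
  }
  gp
}
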