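# Diagnostic classifier: mRMR-filtered sequential forward selection with
# unregularized logistic regression inside nested leave-one-out
# cross-validation, plus threshold optimization and exact-binomial
# performance reporting.

#' Classification task definitions
#'
#' Maps manifest diagnoses onto the binary contrasts: `AD_vs_HC` (positive
#' AD), `HC_vs_disease` (positive = any of AD/DLB/MixedAD/VCD),
#' `AD_vs_DLB` (positive DLB) and `AD_vs_CVD` (positive = the merged
#' cerebrovascular class MixedAD + VCD). Diagnoses on neither side are
#' excluded from the task.
#'
#' @param name Task name.
#' @return List with `name`, `positive` (label and diagnosis set) and
#'   `negative` (diagnosis set).
#' @export
task_definition <- function(name = c("AD_vs_HC", "HC_vs_disease",
                                     "AD_vs_DLB", "AD_vs_CVD")) {
  name <- match.arg(name)
  switch(name,
    AD_vs_HC = list(name = name, positive = "AD",
                    positive_dx = "AD", negative_dx = "HC"),
    HC_vs_disease = list(name = name, positive = "disease",
                         positive_dx = c("AD", "DLB", "MixedAD", "VCD"),
                         negative_dx = "HC"),
    AD_vs_DLB = list(name = name, positive = "DLB",
                     positive_dx = "DLB", negative_dx = "AD"),
    AD_vs_CVD = list(name = name, positive = "CVD",
                     positive_dx = c("MixedAD", "VCD"), negative_dx = "AD"))
}

#' Build the design matrix and labels for a task
#'
#' @param ft A `feature_table` from [extract_features()] including a
#'   `diagnosis` column.
#' @param task A task name or [task_definition()].
#' @param drop_incomplete Drop feature columns with any missing value and
#'   subjects flagged as single-day (default `TRUE`).
#' @return List with `X` (numeric matrix, subjects x features), `y` (0/1,
#'   1 = positive class), `subject_id`, `task`.
#' @export
task_data <- function(ft, task, drop_incomplete = TRUE) {
  if (is.character(task)) task <- task_definition(task)
  stopifnot("diagnosis" %in% names(ft))
  keep <- ft$diagnosis %in% c(task$positive_dx, task$negative_dx)
  if (drop_incomplete && length(attr(ft, "single_day")) > 0L) {
    keep <- keep & !(ft$subject_id %in% attr(ft, "single_day"))
  }
  sub <- ft[keep, , drop = FALSE]
  reg <- attr(ft, "registry")
  feat_cols <- if (!is.null(reg)) {
    intersect(registry_summary_names(reg), names(sub))
  } else {
    grep("__(avg|var)$", names(sub), value = TRUE)
  }
  X <- as.matrix(sub[feat_cols])
  storage.mode(X) <- "double"
  if (drop_incomplete) X <- X[, colSums(is.na(X)) == 0L, drop = FALSE]
  y <- as.integer(sub$diagnosis %in% task$positive_dx)
  list(X = X, y = y, subject_id = sub$subject_id, task = task)
}

standardize_train <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' Greedy mRMR feature ranking (MID scheme)
#'
#' Ranks features by mutual information with the label penalized by mean
#' mutual information with the already-selected set: the first feature
#' maximizes relevance MI(f; y); each next maximizes
#' MI(f; y) - mean MI(f; s) over selected s. MI is estimated after
#' equal-frequency discretization of each feature into 3 bins. Ties break
#' deterministically to the earlier column (registry order). Constant
#' features get zero relevance, never NaN.
#'
#' @param X Numeric feature matrix (no missing values).
#' @param y Binary labels (0/1).
#' @param k Number of features to rank (positive, at most `ncol(X)`).
#' @param nbins Discretization bins (default 3).
#' @return Integer vector of column indices in rank order (named when `X`
#'   has column names).
#' @export
mrmr_rank <- function(X, y, k, nbins = 3) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (anyNA(X)) stop("mrmr_rank requires complete features", call. = FALSE)
  k <- min(k, ncol(X))
  D <- cpp_discretize(as.matrix(X), nbins)
  idx <- cpp_mrmr(D, as.integer(y), k, nbins)
  if (!is.null(colnames(X))) names(idx) <- colnames(X)[idx]
  idx
}

#' Sequential forward selection by inner leave-one-out accuracy
#'
#' Starting from the empty model, repeatedly adds the candidate feature that
#' maximizes leave-one-out accuracy of an unregularized logistic fit on the
#' current set plus the candidate; stops when no candidate strictly improves
#' the accuracy or when `max_features` is reached. Ties go to the earlier
#' candidate, so with mRMR-ordered candidates the ranking is the
#' tie-breaker. The empty-model reference is the majority-class rate.
#'
#' @param X_train Standardized numeric matrix.
#' @param y_train Binary labels (0/1).
#' @param candidates Integer column indices in preference order.
#' @param max_features Selection cap (default 10).
#' @param cap Absolute bound on coefficients under separation (default 15,
#'   on the standardized scale).
#' @return Integer vector of selected column indices, in selection order
#'   (possibly empty).
#' @export
sfs_select <- function(X_train, y_train, candidates, max_features = 10,
                       cap = 15) {
  base_acc <- max(mean(y_train), 1 - mean(y_train))
  sel <- cpp_sfs(as.matrix(X_train), as.numeric(y_train),
                 as.integer(candidates), as.integer(max_features),
                 cap, base_acc)
  if (!is.null(colnames(X_train))) names(sel) <- colnames(X_train)[sel]
  sel
}

fit_logistic <- function(X, y, cap = 15) {
  fit <- cpp_fit_logistic(as.matrix(X), as.numeric(y), cap = cap)
  names(fit$beta) <- c("(intercept)", colnames(X))
  fit
}

#' Nested leave-one-out cross-validated prediction
#'
#' For each subject, the remaining N-1 define the training fold: features are
#' standardized with training statistics only, ranked by [mrmr_rank()]
#' (default k = 30), pruned by [sfs_select()] (inner leave-one-out, cap 10)
#' and an unregularized logistic model is fitted on the selection; the
#' held-out subject's probability is predicted from that model. All model
#' selection is therefore redone inside every fold and the held-out subject
#' never influences its own model.
#'
#' @param X Numeric feature matrix with column names (subjects x features).
#' @param y Binary labels (0/1).
#' @param mrmr_k mRMR pre-filter size (default 30).
#' @param sfs_max SFS cap (default 10).
#' @param cap Coefficient cap under separation (default 15).
#' @param subject_id Optional subject identifiers.
#' @param task Optional [task_definition()] echoed into the result.
#' @return A `classification_result`: list with `probs` (out-of-fold
#'   probability per subject), `y`, `folds` (per-fold selected feature
#'   names, coefficients, standardization parameters, separation flag),
#'   `feature_names`, `config`.
#' @export
nested_loocv_predict <- function(X, y, mrmr_k = 30, sfs_max = 10, cap = 15,
                                 subject_id = NULL, task = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  if (min(table(y)) < 2L) stop("each class needs at least 2 subjects", call. = FALSE)
  probs <- numeric(n)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    std <- standardize_train(Xtr)
    ranked <- mrmr_rank(std$X, ytr, k = mrmr_k)
    sel <- sfs_select(std$X, ytr, ranked, max_features = sfs_max, cap = cap)
    if (length(sel) == 0L) {
      # empty model: intercept-only maximum likelihood
      probs[i] <- mean(ytr)
      folds[[i]] <- list(features = character(0),
                         beta = stats::setNames(log(mean(ytr) / (1 - mean(ytr))),
                                                "(intercept)"),
                         center = numeric(0), scale = numeric(0),
                         capped = FALSE)
      next
    }
    fit <- fit_logistic(std$X[, sel, drop = FALSE], ytr, cap = cap)
    xi <- (X[i, sel] - std$center[sel]) / std$scale[sel]
    eta <- fit$beta[1L] + sum(fit$beta[-1L] * xi)
    probs[i] <- 1 / (1 + exp(-eta))
    folds[[i]] <- list(features = colnames(X)[sel], beta = fit$beta,
                       center = std$center[sel], scale = std$scale[sel],
                       capped = fit$capped)
  }
  structure(list(probs = probs, y = y, folds = folds,
                 feature_names = colnames(X), subject_id = subject_id,
                 task = task,
                 config = list(mrmr_k = mrmr_k, sfs_max = sfs_max, cap = cap,
                               scheme = "nested_loocv")),
            class = "classification_result")
}

#' Deliberately leaky leave-one-out variant (negative control)
#'
#' Performs feature selection once on ALL subjects (standardization, mRMR and
#' SFS see the full cohort) and only refits coefficients inside the
#' leave-one-out loop. This is the classic selection-leakage mistake; it is
#' exported solely so the leakage regression test can demonstrate the
#' optimistic bias against [nested_loocv_predict()]. Never use it to report
#' performance.
#'
#' @inheritParams nested_loocv_predict
#' @return A `classification_result` with `config$scheme = "leaky_loocv"`.
#' @export
leaky_loocv_predict <- function(X, y, mrmr_k = 30, sfs_max = 10, cap = 15) {
  X <- as.matrix(X)
  y <- as.integer(y)
  std <- standardize_train(X)
  ranked <- mrmr_rank(std$X, y, k = mrmr_k)
  sel <- sfs_select(std$X, y, ranked, max_features = sfs_max, cap = cap)
  if (length(sel) == 0L) sel <- ranked[1L]
  loo <- cpp_loo_predict(std$X[, sel, drop = FALSE], as.numeric(y),
                         seq_along(sel), cap)
  structure(list(probs = loo$probs, y = y,
                 folds = list(list(features = colnames(X)[sel])),
                 feature_names = colnames(X), subject_id = NULL, task = NULL,
                 config = list(mrmr_k = mrmr_k, sfs_max = sfs_max, cap = cap,
                               scheme = "leaky_loocv")),
            class = "classification_result")
}

#' Single-feature leave-one-out baseline
#'
#' Leave-one-out logistic regression on one standardized feature (by default
#' the average intensity count over the 24-hour period), the comparator for
#' the full feature-selection classifier.
#'
#' @param x Numeric feature vector (one value per subject; not constant).
#' @param y Binary labels (0/1).
#' @param cap Coefficient cap (default 15).
#' @return A `classification_result` with `config$scheme =
#'   "single_feature_loocv"`.
#' @export
single_feature_baseline <- function(x, y, cap = 15) {
  x <- as.numeric(x)
  y <- as.integer(y)
  if (stats::sd(x) == 0) stop("single feature is constant", call. = FALSE)
  n <- length(x)
  probs <- numeric(n)
  for (i in seq_len(n)) {
    xtr <- x[-i]
    ctr <- mean(xtr); scl <- stats::sd(xtr)
    fit <- cpp_fit_logistic(matrix((xtr - ctr) / scl, ncol = 1),
                            as.numeric(y[-i]), cap = cap)
    eta <- fit$beta[1L] + fit$beta[2L] * (x[i] - ctr) / scl
    probs[i] <- 1 / (1 + exp(-eta))
  }
  structure(list(probs = probs, y = y, folds = NULL,
                 feature_names = "single_feature", subject_id = NULL,
                 task = NULL, config = list(scheme = "single_feature_loocv")),
            class = "classification_result")
}

#' Optimal ROC threshold: point closest to (0, 1)
#'
#' Scans the midpoints between sorted distinct out-of-fold probabilities
#' (plus 0 and 1) and returns the threshold minimizing the Euclidean
#' distance \eqn{\sqrt{(1-sens)^2 + (1-spec)^2}} to the ideal corner of ROC
#' space. Ties go to the lower threshold.
#'
#' @param probs Out-of-fold probabilities in `[0, 1]`.
#' @param y Binary labels (0/1), both classes present.
#' @return The optimal probability threshold.
#' @export
optimal_threshold <- function(probs, y) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  p <- sort(unique(probs))
  cand <- unique(c(0, if (length(p) > 1L) (p[-1L] + p[-length(p)]) / 2, 1))
  dist <- vapply(cand, function(th) {
    pred <- probs > th
    sens <- sum(pred & y == 1L) / sum(y == 1L)
    spec <- sum(!pred & y == 0L) / sum(y == 0L)
    sqrt((1 - sens)^2 + (1 - spec)^2)
  }, numeric(1))
  cand[which.min(dist)]  # which.min takes the first, i.e. lowest threshold
}

#' Exact binomial (Clopper--Pearson) confidence interval
#'
#' @param k Number of successes (`0 <= k <= n`).
#' @param n Number of trials (positive).
#' @param alpha Two-sided level (default 0.05 for a 95% interval).
#' @return Numeric `c(lower, upper)` on the proportion scale: lower is the
#'   `alpha/2` Beta(k, n-k+1) quantile (0 when k = 0), upper the
#'   `1 - alpha/2` Beta(k+1, n-k) quantile (1 when k = n).
#' @export
clopper_pearson <- function(k, n, alpha = 0.05) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Diagnostic performance metrics with exact-binomial intervals
#'
#' Thresholds the out-of-fold probabilities (positive when `prob >
#' threshold`), tabulates the confusion counts and reports sensitivity,
#' specificity, accuracy, precision and the F1 score
#' (\eqn{2 \cdot precision \cdot sensitivity / (precision + sensitivity)}),
#' all as percentages. The proportion-type metrics carry 95%
#' Clopper--Pearson intervals on their respective denominators (positives,
#' negatives, all, predicted positives); F1 is not a binomial proportion and
#' is reported without an interval.
#'
#' @param probs Out-of-fold probabilities.
#' @param y Binary labels (0/1), both classes present.
#' @param threshold Probability cut (default 0.5).
#' @param alpha Interval level (default 0.05).
#' @return A `performance_report` list with `counts` (TP, FP, TN, FN),
#'   `metrics` (percent values), `ci` (percent bounds) and `threshold`.
#' @export
performance_metrics <- function(probs, y, threshold = 0.5, alpha = 0.05) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  pred <- probs > threshold
  tp <- sum(pred & y == 1L); fp <- sum(pred & y == 0L)
  tn <- sum(!pred & y == 0L); fn <- sum(!pred & y == 1L)
  n <- length(y)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / n
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  f1 <- if (is.na(prec) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  ci <- list(
    sensitivity = 100 * clopper_pearson(tp, tp + fn, alpha),
    specificity = 100 * clopper_pearson(tn, tn + fp, alpha),
    accuracy = 100 * clopper_pearson(tp + tn, n, alpha),
    precision = if (tp + fp == 0) c(lower = NA_real_, upper = NA_real_) else
      100 * clopper_pearson(tp, tp + fp, alpha)
  )
  structure(list(
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
    metrics = c(sensitivity = 100 * sens, specificity = 100 * spec,
                accuracy = 100 * acc, precision = 100 * prec, f1 = 100 * f1),
    ci = ci, threshold = threshold, alpha = alpha),
    class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("Performance at threshold %.3f (counts TP %d FP %d TN %d FN %d)\n",
              x$threshold, x$counts["TP"], x$counts["FP"], x$counts["TN"],
              x$counts["FN"]))
  for (m in names(x$metrics)) {
    v <- x$metrics[[m]]
    if (m %in% names(x$ci)) {
      cat(sprintf("  %-12s %5.1f%% (95%% CI %.1f-%.1f)\n", m, v,
                  x$ci[[m]]["lower"], x$ci[[m]]["upper"]))
    } else {
      cat(sprintf("  %-12s %5.1f%%\n", m, v))
    }
  }
  invisible(x)
}

#' F1 score from precision and sensitivity
#'
#' @param precision,sensitivity Percentages (or fractions; the scale is
#'   preserved).
#' @return Harmonic mean of the two, on the input scale.
#' @export
f1_score <- function(precision, sensitivity) {
  2 * precision * sensitivity / (precision + sensitivity)
}

#' Feature importance: average absolute coefficients across folds
#'
#' For each feature, the mean over outer folds of the absolute standardized
#' logistic coefficient, with folds where the feature was not selected
#' contributing 0. Returned in descending importance.
#'
#' @param result A `classification_result` from [nested_loocv_predict()].
#' @return Data frame with `feature` and `importance`, sorted descending;
#'   features never selected have importance 0.
#' @export
feature_importance <- function(result) {
  stopifnot(inherits(result, "classification_result"))
  feats <- result$feature_names
  total <- stats::setNames(numeric(length(feats)), feats)
  nf <- length(result$folds)
  for (fold in result$folds) {
    if (length(fold$features) == 0L) next
    coefs <- fold$beta[-1L]  # drop intercept
    total[fold$features] <- total[fold$features] + abs(coefs)
  }
  imp <- total / nf
  out <- data.frame(feature = names(imp), importance = as.numeric(imp))
  out[order(-out$importance, out$feature), , drop = FALSE]
}
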