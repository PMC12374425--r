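# independent reference implementations used as oracles ----------------------

ref_discretize <- function(x, nbins = 3) {
  q <- quantile(x, probs = seq_len(nbins - 1) / nbins, type = 7, names = FALSE)
  findInterval(x, q, left.open = TRUE)
}

ref_mi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    pij <- tab[i, j]
    if (pij > 0) mi <- mi + (pij / n) * log(pij * n / (sum(tab[i, ]) * sum(tab[, j])))
  }
  max(mi, 0)
}

ref_mrmr <- function(X, y, k) {
  D <- apply(X, 2, ref_discretize)
  p <- ncol(X)
  rel <- vapply(1:p, function(j) ref_mi(D[, j], y), numeric(1))
  selected <- integer(0)
  for (step in 1:k) {
    remaining <- setdiff(1:p, selected)
    score <- vapply(remaining, function(j) {
      red <- if (length(selected) == 0) 0 else
        mean(vapply(selected, function(s) ref_mi(D[, j], D[, s]), numeric(1)))
      rel[j] - red
    }, numeric(1))
    selected <- c(selected, remaining[which.max(score)])
  }
  selected
}

# ----------------------------------------------------------------------------

test_that("mRMR ranks a label-identical feature first and penalizes copies", {
  set.seed(17)
  y <- rep(0:1, each = 10)
  X <- cbind(A = y + 0, B = rnorm(20), C = rnorm(20))
  expect_equal(unname(mrmr_rank(X, y, k = 3)[1]), 1L)

  # brute-force greedy oracle on a 6-feature, 20-sample matrix
  X2 <- cbind(X, D = y + 0, E = rnorm(20), F = y + rnorm(20, sd = 0.6))
  got <- mrmr_rank(X2, y, k = 6)
  want <- ref_mrmr(X2, y, 6)
  expect_equal(unname(got), want)
  # the exact copy of the top feature is fully redundant: its incremental
  # score after selecting the original drops below its raw relevance
  D <- actidx:::cpp_discretize(X2, 3L)
  rel_copy <- ref_mi(D[, 4], y)
  red_copy <- ref_mi(D[, 4], D[, 1])
  expect_lt(rel_copy - red_copy, rel_copy)
  expect_equal(red_copy, rel_copy, tolerance = 1e-12)  # MI(A;A) = MI(A;y) here

  expect_error(mrmr_rank(X, y, k = 0), "positive")
  # constant feature: zero relevance, no NaN, still ranked
  X3 <- cbind(X, K = rep(1, 20))
  expect_length(mrmr_rank(X3, y, k = 4), 4L)
})

test_that("the logistic IRLS fit agrees with glm on well-separated-free data", {
  set.seed(23)
  n <- 80
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  eta <- 0.4 + 0.9 * X[, 1] - 0.7 * X[, 2]
  y <- rbinom(n, 1, plogis(eta))
  fit <- actidx:::fit_logistic(X, y)
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_false(fit$capped)
})

test_that("separation is handled by a finite coefficient cap", {
  y <- rep(0:1, each = 10)
  X <- cbind(s = as.numeric(y))  # perfectly separating
  fit <- actidx:::fit_logistic(X, y, cap = 15)
  expect_true(fit$capped)
  expect_true(all(is.finite(fit$beta)))
  expect_lte(max(abs(fit$beta)), 15)
})

test_that("C++ leave-one-out accuracy matches a glm-based reimplementation", {
  set.seed(31)
  n <- 30
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(0.8 * X[, 1]))
  got <- cpp_loo_accuracy(X, as.numeric(y), 1:2, 15)
  preds <- vapply(1:n, function(i) {
    f <- suppressWarnings(glm(y[-i] ~ X[-i, ], family = binomial()))
    eta <- coef(f)[1] + sum(coef(f)[-1] * X[i, ])
    as.integer(plogis(eta) > 0.5)
  }, integer(1))
  expect_equal(got, mean(preds == y))
})

test_that("forward selection finds separators, honors caps and stops on noise", {
  set.seed(41)
  n <- 30
  y <- rep(0:1, each = n / 2)
  X <- cbind(matrix(rnorm(n * 5), n, 5), sep = y + rnorm(n, sd = 0.05))
  colnames(X) <- c(paste0("n", 1:5), "sep")
  Xs <- scale(X)
  sel <- sfs_select(Xs, y, candidates = 1:6)
  expect_equal(unname(sel[1]), 6L)
  expect_lte(length(sel), 2L)

  # three informative features but a cap of two
  X2 <- cbind(f1 = y + rnorm(n, sd = .4), f2 = y + rnorm(n, sd = .4),
              f3 = y + rnorm(n, sd = .4), f4 = rnorm(n))
  sel2 <- sfs_select(scale(X2), y, candidates = 1:4, max_features = 2)
  expect_lte(length(sel2), 2L)

  # pure noise with a pipeline-sized candidate set: selection terminates
  # well before the cap (chance improvements peter out quickly)
  lens <- vapply(1:20, function(s) {
    set.seed(900 + s)
    Xn <- matrix(rnorm(40 * 30), 40, 30)
    length(sfs_select(scale(Xn), rep(0:1, each = 20), candidates = 1:30,
                      max_features = 10))
  }, numeric(1))
  expect_lte(mean(lens), 5)
  expect_lt(max(lens), 10)
})

test_that("nested LOOCV is airtight bookkeeping with one probability per subject", {
  set.seed(53)
  n <- 24
  y <- rep(0:1, each = n / 2)
  X <- cbind(lab = y + rnorm(n, sd = 0.01), matrix(rnorm(n * 6), n, 6))
  colnames(X) <- c("lab", paste0("z", 1:6))
  res <- nested_loocv_predict(X, y, mrmr_k = 5, sfs_max = 3)
  expect_length(res$probs, n)
  expect_length(res$folds, n)
  # a label-copy feature gives perfect out-of-fold classification
  expect_true(all((res$probs > 0.5) == (y == 1)))
  pm <- performance_metrics(res$probs, res$y, 0.5)
  expect_equal(unname(pm$metrics["accuracy"]), 100)
  # deterministic rerun
  res2 <- nested_loocv_predict(X, y, mrmr_k = 5, sfs_max = 3)
  expect_identical(res$probs, res2$probs)
  # per-fold standardization reflects the training fold, not all subjects:
  # removing subject i shifts the training means of the label-copy feature
  # by sign of its class
  ctr <- vapply(res$folds, function(f) f$center[["lab"]], numeric(1))
  expect_lt(max(ctr[y == 1]), min(ctr[y == 0]))
})

test_that("the optimal ROC threshold matches brute-force enumeration", {
  y <- c(0, 0, 0, 1, 1, 1)
  p <- c(0.1, 0.4, 0.6, 0.35, 0.7, 0.9)
  th <- optimal_threshold(p, y)
  # exhaustive check over a fine grid: no threshold does better
  dist_at <- function(t) {
    pred <- p > t
    sens <- sum(pred & y == 1) / 3
    spec <- sum(!pred & y == 0) / 3
    sqrt((1 - sens)^2 + (1 - spec)^2)
  }
  grid <- seq(0, 1, by = 0.001)
  expect_lte(dist_at(th), min(vapply(grid, dist_at, numeric(1))) + 1e-12)
  # the enumerated optimum keeps the two high-probability positives and
  # rejects every negative: any cut in (0.6, 0.7] gives sens 2/3, spec 1
  expect_gt(th, 0.6)
  expect_lte(th, 0.7)
  expect_equal(dist_at(th), 1 / 3, tolerance = 1e-12)

  # perfectly separated: distance 0, sens = spec = 1
  th2 <- optimal_threshold(c(.1, .2, .8, .9), c(0, 0, 1, 1))
  pm <- performance_metrics(c(.1, .2, .8, .9), c(0, 0, 1, 1), th2)
  expect_equal(unname(pm$metrics["sensitivity"]), 100)
  expect_equal(unname(pm$metrics["specificity"]), 100)
  expect_error(optimal_threshold(c(.2, .8), c(1, 1)), "both classes")
})

test_that("performance metrics satisfy the confusion-matrix identities", {
  set.seed(61)
  for (r in 1:25) {
    n <- sample(20:60, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    probs <- runif(n)
    pm <- performance_metrics(probs, y, 0.5)
    cts <- pm$counts
    expect_equal(sum(cts), n)
    expect_equal(unname(pm$metrics["accuracy"]),
                 100 * (cts[["TP"]] + cts[["TN"]]) / n)
    if (!is.na(pm$metrics["precision"])) {
      expect_equal(unname(pm$metrics["precision"]),
                   100 * cts[["TP"]] / (cts[["TP"]] + cts[["FP"]]))
      prec <- pm$metrics[["precision"]]; sens <- pm$metrics[["sensitivity"]]
      if (prec + sens > 0) {
        expect_equal(unname(pm$metrics["f1"]), 2 * prec * sens / (prec + sens),
                     tolerance = 1e-12)
      }
    }
  }
  # harmonic-mean fixed point
  expect_equal(f1_score(70, 70), 70)
})

test_that("Clopper-Pearson matches closed forms, binom.test and symmetry", {
  ci <- clopper_pearson(0, 20)
  expect_equal(unname(ci["lower"]), 0)
  expect_equal(unname(ci["upper"]), 1 - 0.025^(1 / 20), tolerance = 1e-10)
  expect_equal(unname(clopper_pearson(20, 20)["upper"]), 1)
  expect_equal(unname(clopper_pearson(20, 20)["lower"]), 0.025^(1 / 20),
               tolerance = 1e-10)
  for (k in c(0, 3, 11, 25)) {
    got <- clopper_pearson(k, 25)
    ref <- binom.test(k, 25)$conf.int
    expect_equal(unname(got), as.numeric(ref), tolerance = 1e-9)
    flipped <- clopper_pearson(25 - k, 25)
    expect_equal(unname(got), unname(rev(1 - flipped)), tolerance = 1e-12)
  }
  expect_error(clopper_pearson(1, 0), "positive")
})

test_that("the single-feature baseline classifies a near-label feature", {
  set.seed(71)
  n <- 40
  y <- rep(0:1, each = n / 2)
  x <- y + rnorm(n, sd = 0.05)
  res <- single_feature_baseline(x, y)
  pm <- performance_metrics(res$probs, res$y, 0.5)
  expect_gte(pm$metrics[["accuracy"]], 97.5)
  expect_error(single_feature_baseline(rep(1, n), y), "constant")

  # ROC-ranked metrics are invariant to monotone transforms of the feature
  x2 <- exp(3 * x)
  res2 <- single_feature_baseline(x2, y)
  t1 <- optimal_threshold(res$probs, y)
  t2 <- optimal_threshold(res2$probs, y)
  m1 <- performance_metrics(res$probs, y, t1)$metrics
  m2 <- performance_metrics(res2$probs, y, t2)$metrics
  expect_equal(m1[c("sensitivity", "specificity")],
               m2[c("sensitivity", "specificity")])
})

test_that("a feature independent of the label stays near chance", {
  set.seed(83)
  accs <- vapply(1:10, function(s) {
    y <- rep(0:1, each = 20)
    res <- single_feature_baseline(rnorm(40), y)
    performance_metrics(res$probs, y, 0.5)$metrics[["accuracy"]]
  }, numeric(1))
  # 95% binomial band around 50% for n = 40, averaged over 10 replicates
  expect_gt(mean(accs), 27.5)
  expect_lt(mean(accs), 72.5)
})

test_that("feature importance averages absolute coefficients, zeros unselected", {
  fake <- structure(list(
    feature_names = c("a", "b", "c"),
    folds = c(
      replicate(5, list(features = "a",
                        beta = c("(intercept)" = 0, a = 1)), simplify = FALSE),
      replicate(5, list(features = c("a", "b"),
                        beta = c("(intercept)" = 0, a = -3, b = 2)),
                simplify = FALSE))),
    class = "classification_result")
  imp <- feature_importance(fake)
  expect_equal(imp$importance[imp$feature == "a"], 2)    # (5*1 + 5*3)/10
  expect_equal(imp$importance[imp$feature == "b"], 1)    # (5*0 + 5*2)/10
  expect_equal(imp$importance[imp$feature == "c"], 0)
  expect_equal(imp$feature[1], "a")
})

test_that("task definitions merge the cerebrovascular groups as specified", {
  td <- task_definition("AD_vs_CVD")
  expect_setequal(td$positive_dx, c("MixedAD", "VCD"))
  td2 <- task_definition("HC_vs_disease")
  expect_setequal(td2$positive_dx, c("AD", "DLB", "MixedAD", "VCD"))
  expect_equal(td2$negative_dx, "HC")
})
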