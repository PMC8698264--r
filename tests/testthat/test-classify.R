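test_that("confusion at threshold predicts positive strictly above it", {
  scores <- c(40, 35, 31, 31, 20, 10)
  labels <- c(1, 1, 1, 0, 0, 0)
  cm <- confusion_at_threshold(scores, labels, 31)
  # scores exactly at the threshold are predicted negative
  expect_identical(unlist(cm[c("tp", "fp", "tn", "fn")]),
                   c(tp = 2L, fp = 0L, tn = 3L, fn = 1L))

  expect_error(confusion_at_threshold(c(50, 60), c(1, 1), 31),
               "both classes")

  # all scores above threshold, all labels positive except impossible:
  # with both classes present and full separation, no misclassification
  cmab <- confusion_at_threshold(c(50, 60, 5), c(1, 1, 0), 31)
  expect_identical(cmab$fn, 0L)
  expect_identical(cmab$fp, 0L)

  set.seed(3)
  s <- runif(200); l <- rbinom(200, 1, 0.4); thr <- 0.5
  cm3 <- confusion_at_threshold(s, l, thr)
  ref <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (i in 1:200) {
    pos <- s[i] > thr
    key <- if (pos && l[i] == 1) "tp" else if (pos) "fp"
           else if (l[i] == 0) "tn" else "fn"
    ref[key] <- ref[key] + 1L
  }
  expect_identical(unlist(cm3[c("tp", "fp", "tn", "fn")]), ref)
})

test_that("metric battery: perfect classifier, class swap, undefined cells", {
  perfect <- classifier_metrics(confusion_matrix(12, 0, 99, 0))
  for (m in c("sensitivity", "specificity", "ppv", "npv", "f1",
              "mcc", "kappa"))
    expect_equal(perfect[[m]], 1)
  expect_identical(perfect$dor, Inf)

  cm <- confusion_matrix(11, 16, 83, 1)
  met <- classifier_metrics(cm)
  swapped <- classifier_metrics(confusion_matrix(83, 1, 11, 16))
  expect_equal(swapped$sensitivity, met$specificity)
  expect_equal(swapped$specificity, met$sensitivity)

  nopos <- classifier_metrics(confusion_matrix(0, 0, 10, 0))
  expect_true(is.na(nopos$sensitivity))
  expect_match(paste(nopos$undefined, collapse = ";"), "no positives")
})

test_that("MCC equals the Pearson correlation of indicator vectors", {
  set.seed(14)
  for (r in 1:20) {
    cm <- confusion_matrix(sample(0:20, 1) + 1, sample(0:20, 1),
                           sample(0:20, 1) + 1, sample(0:20, 1))
    pred <- c(rep(1, cm$tp), rep(1, cm$fp), rep(0, cm$tn), rep(0, cm$fn))
    truth <- c(rep(1, cm$tp), rep(0, cm$fp), rep(0, cm$tn), rep(1, cm$fn))
    mcc_ref <- suppressWarnings(cor(pred, truth))
    met <- classifier_metrics(cm)
    if (is.na(mcc_ref)) expect_true(is.na(met$mcc))
    else expect_equal(met$mcc, mcc_ref)
  }
})

test_that("AUC: separation, null, monotone invariance, external check", {
  expect_equal(roc_auc(c(5, 6, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0))$auc, 1)

  set.seed(15)
  s <- runif(4000); l <- rbinom(4000, 1, 0.5)
  expect_equal(roc_auc(s, l)$auc, 0.5, tolerance = 0.03)

  s2 <- rnorm(100); l2 <- rbinom(100, 1, plogis(s2))
  a1 <- roc_auc(s2, l2)$auc
  a2 <- roc_auc(exp(3 * s2), l2)$auc  # strictly monotone transform
  expect_equal(a1, a2)

  skip_if_not_installed("pROC")
  pr <- as.numeric(suppressMessages(pROC::auc(l2, s2,
                                              direction = "<")))
  expect_equal(a1, pr)
})

test_that("AUC equals the all-pairs U-statistic with ties at half", {
  set.seed(16)
  for (r in 1:10) {
    s <- sample(1:8, 40, replace = TRUE)  # heavy ties
    l <- rbinom(40, 1, 0.5)
    if (length(unique(l)) < 2) next
    pos <- s[l == 1]; neg <- s[l == 0]
    u <- 0
    for (p in pos) for (q in neg)
      u <- u + (p > q) + 0.5 * (p == q)
    expect_equal(roc_auc(s, l)$auc, u / (length(pos) * length(neg)))
  }
})

test_that("Youden threshold selection with tie and flat-curve rules", {
  # perfectly separated: J = 1 first reached at the top negative score
  roc <- roc_auc(c(1, 2, 10, 20, 21, 30), c(0, 0, 0, 1, 1, 1))
  expect_equal(select_threshold(roc), 10)

  # uninformative scores: flat curve, lowest threshold with a warning
  rocf <- roc_auc(c(1, 1, 1, 1), c(0, 1, 0, 1))
  expect_warning(thrf <- select_threshold(rocf), "flat ROC")
  expect_equal(thrf, 1)
})

test_that("predicted PPV follows Bayes' rule and its limits", {
  expect_equal(predicted_ppv(1, 1 - 0.1, 0.2), (0.2) / (0.2 + 0.1 * 0.8))
  expect_equal(predicted_ppv(0.8, 1, 0.05), 1)  # no false positives
  for (P in c(0.1, 0.37, 0.8))
    expect_equal(predicted_ppv(0.5, 0.5, P), P)  # uninformative test

  # strictly increasing in prevalence, sensitivity and specificity
  ps <- sapply(seq(0.05, 0.95, by = 0.1), function(P)
    predicted_ppv(0.9, 0.8, P))
  expect_true(all(diff(ps) > 0))
  expect_gt(predicted_ppv(0.95, 0.8, 0.3), predicted_ppv(0.9, 0.8, 0.3))
  expect_gt(predicted_ppv(0.9, 0.85, 0.3), predicted_ppv(0.9, 0.8, 0.3))

  expect_warning(out <- predicted_ppv(0, 1, 0.3), "undefined")
  expect_true(is.na(out))
})

test_that("stratified bootstrap is deterministic and degenerate-safe", {
  set.seed(18)
  s <- c(rnorm(30, 2), rnorm(40))
  l <- rep(c(1, 0), c(30, 40))
  ci1 <- bootstrap_ci("sensitivity", s, l, 1, B = 300, seed = 99)
  ci2 <- bootstrap_ci("sensitivity", s, l, 1, B = 300, seed = 99)
  expect_identical(ci1, ci2)
  ci3 <- bootstrap_ci("sensitivity", s, l, 1, B = 300, seed = 100)
  expect_false(identical(ci1[c("low", "high")], ci3[c("low", "high")]))

  # perfectly separated scores: every resample yields the same metric
  s0 <- c(rep(10, 20), rep(1, 20)); l0 <- rep(c(1, 0), each = 20)
  ci0 <- bootstrap_ci("sensitivity", s0, l0, 5, B = 200, seed = 1)
  expect_equal(ci0$low, ci0$high)
  expect_equal(ci0$point, 1)

  # RNG state of the caller is untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(bootstrap_ci("mcc", s, l, 1, B = 100, seed = 7))
  after <- runif(1)
  expect_identical(before, after)
})
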