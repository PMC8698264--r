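# Threshold-classifier evaluation: confusion matrix at a displaced-GM
# cutoff, the diagnostic metric battery, ROC/AUC, Youden threshold
# selection, stratified bootstrap CIs, and the prevalence-adjusted
# (Bayesian) predicted PPV.

#' Confusion matrix at a score threshold
#'
#' Predicts positive when `score > thr` (strictly: a score exactly at the
#' threshold is predicted negative, matching "risk increased when the
#' proportion exceeded the cutoff").
#'
#' @param scores numeric scores (e.g. displaced-GM proportion in %).
#' @param labels binary outcomes (0/1 or logical), both classes present.
#' @param thr decision threshold.
#' @return Object of class `confusion_matrix`: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_threshold <- function(scores, labels, thr) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes")
  pred <- scores > thr
  confusion_matrix(tp = sum(pred & labels == 1L),
                   fp = sum(pred & labels == 0L),
                   tn = sum(!pred & labels == 0L),
                   fn = sum(!pred & labels == 1L))
}

#' @rdname confusion_at_threshold
#' @param tp,fp,tn,fn nonnegative integer counts.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  cells <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells)))
    stop("confusion cells must be nonnegative integers")
  if (sum(cells) < 1) stop("empty confusion matrix")
  storage.mode(cells) <- "integer"
  structure(as.list(cells), class = "confusion_matrix")
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Diagnostic metric battery
#'
#' Sensitivity, specificity, PPV, NPV, F1, diagnostic odds ratio, Matthews
#' correlation coefficient and Cohen's kappa from a confusion matrix.
#' Ratios with zero denominators are reported as `NA` with the reason
#' listed in `undefined`, never silently as 0; the DOR is `+Inf` when only
#' its denominator cross-product is zero.
#'
#' @param cm a [confusion_matrix()].
#' @return Object of class `classifier_metrics`: named list of the eight
#'   metrics plus `n` and `undefined` (character vector of metrics that
#'   could not be computed, with reasons).
#' @export
classifier_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  n <- tp + fp + tn + fn
  undefined <- character(0)
  note <- function(metric, why) {
    undefined <<- c(undefined, sprintf("%s: %s", metric, why))
    NA_real_
  }
  se <- if (tp + fn == 0) note("sensitivity", "no positives")
        else tp / (tp + fn)
  sp <- if (tn + fp == 0) note("specificity", "no negatives")
        else tn / (tn + fp)
  ppv <- if (tp + fp == 0) note("ppv", "no positive predictions")
         else tp / (tp + fp)
  npv <- if (tn + fn == 0) note("npv", "no negative predictions")
         else tn / (tn + fn)
  f1 <- if (is.na(ppv) || is.na(se) || ppv + se == 0)
          note("f1", "precision + recall is zero or undefined")
        else 2 * ppv * se / (ppv + se)
  dor <- if (fp * fn == 0) {
           if (tp * tn == 0) note("dor", "0/0 cross products") else Inf
         } else (tp * tn) / (fp * fn)
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) note("mcc", "degenerate margin")
         else (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  po <- (tp + tn) / n
  pe <- (as.numeric(tp + fp) * (tp + fn) +
         as.numeric(fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) note("kappa", "chance agreement is 1")
           else (po - pe) / (1 - pe)
  structure(list(sensitivity = se, specificity = sp, ppv = ppv, npv = npv,
                 f1 = f1, dor = dor, mcc = mcc, kappa = kappa,
                 n = n, undefined = undefined),
            class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  vals <- unlist(x[c("sensitivity", "specificity", "ppv", "npv",
                     "f1", "dor", "mcc", "kappa")])
  cat("<classifier_metrics>\n")
  print(round(vals, 3))
  if (length(x$undefined))
    cat("undefined:", paste(x$undefined, collapse = "; "), "\n")
  invisible(x)
}

#' ROC curve and AUC
#'
#' Evaluates sensitivity and 1 - specificity at every distinct score
#' (prediction positive iff score > threshold). The AUC is the normalized
#' Mann-Whitney U statistic -- the probability that a random case outscores
#' a random control, ties counted 1/2 -- which equals the trapezoidal area
#' under the empirical ROC curve.
#'
#' @inheritParams confusion_at_threshold
#' @return Object of class `roc_result`: `thresholds` (increasing),
#'   `sensitivity`, `fpr` (parallel vectors), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes")
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  n1 <- length(pos); n0 <- length(neg)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) sum(pos > t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(neg > t) / n0, numeric(1))
  structure(list(thresholds = thr, sensitivity = sens, fpr = fpr,
                 auc = auc, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' Select an operating threshold on a ROC curve
#'
#' Youden's J (`sensitivity + specificity - 1`) maximization; among tied
#' maxima the lowest threshold is returned (with a warning when the curve
#' is entirely flat, i.e. the scores are uninformative).
#'
#' @param roc a [roc_auc()] result.
#' @param rule threshold rule; only `"youden"` is implemented.
#' @return The selected threshold (numeric scalar).
#' @export
select_threshold <- function(roc, rule = c("youden")) {
  rule <- match.arg(rule)
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$sensitivity - roc$fpr
  if (diff(range(j)) == 0)
    warning("flat ROC (uninformative scores): returning lowest threshold")
  roc$thresholds[which.max(j)]
}

#' Prevalence-adjusted predicted PPV
#'
#' Projects the sample sensitivity and specificity onto a target
#' population prevalence by Bayes' rule:
#' \deqn{PPV = Se \cdot P / (Se \cdot P + (1 - Sp)(1 - P))}
#'
#' @param se,sp sensitivity and specificity in \[0, 1\].
#' @param prevalence true condition prevalence `P` in (0, 1).
#' @return Predicted PPV; `NA` with a warning when the denominator is 0
#'   (`se = 0` and `sp = 1`).
#' @export
predicted_ppv <- function(se, sp, prevalence) {
  stopifnot(se >= 0, se <= 1, sp >= 0, sp <= 1,
            prevalence > 0, prevalence < 1)
  den <- se * prevalence + (1 - sp) * (1 - prevalence)
  if (den == 0) {
    warning("predicted PPV undefined: no positive predictions possible")
    return(NA_real_)
  }
  se * prevalence / den
}

metric_at_threshold <- function(pos, neg, thr, metric) {
  cm <- confusion_matrix(tp = sum(pos > thr), fn = sum(pos <= thr),
                         fp = sum(neg > thr), tn = sum(neg <= thr))
  classifier_metrics(cm)[[metric]]
}

#' Stratified bootstrap confidence interval for a classifier metric
#'
#' Percentile interval over `B` stratified resamples: cases and controls
#' are resampled with replacement within their own class, so every
#' resample keeps both classes. Fully deterministic given `seed`; the
#' caller's RNG state is left untouched.
#'
#' @param metric one of `"sensitivity"`, `"specificity"`, `"ppv"`,
#'   `"npv"`, `"f1"`, `"dor"`, `"mcc"`, `"kappa"`.
#' @inheritParams confusion_at_threshold
#' @param B number of bootstrap resamples (>= 100).
#' @param seed integer seed (mandatory).
#' @param conf_level interval level.
#' @return list with `low`, `high`, `point`, `B`, `metric`.
#' @export
bootstrap_ci <- function(metric, scores, labels, thr, B = 2000, seed,
                         conf_level = 0.95) {
  metric <- match.arg(metric, c("sensitivity", "specificity", "ppv",
                                "npv", "f1", "dor", "mcc", "kappa"))
  stopifnot(B >= 100, !missing(seed))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes")
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  point <- metric_at_threshold(pos, neg, thr, metric)
  stat <- with_local_seed(seed, {
    vapply(seq_len(B), function(b) {
      metric_at_threshold(sample(pos, replace = TRUE),
                          sample(neg, replace = TRUE), thr, metric)
    }, numeric(1))
  })
  alpha <- (1 - conf_level) / 2
  q <- stats::quantile(stat, c(alpha, 1 - alpha), na.rm = TRUE,
                       names = FALSE)
  list(low = q[1], high = q[2], point = point, B = B, metric = metric)
}

# Run expr under set.seed(seed) and restore the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
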