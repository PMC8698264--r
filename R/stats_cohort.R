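# Cohort group-comparison statistics: 2x2 odds ratios with Woolf CIs,
# Fisher's exact test, Wilcoxon rank-sum, univariate logistic regression,
# Hosmer-Lemeshow goodness of fit, calibration slope.

#' 2x2 contingency table
#'
#' Exposure-by-outcome counts: `a` exposed cases, `b` exposed controls,
#' `c` unexposed cases, `d` unexposed controls.
#'
#' @param a,b,c,d nonnegative integer counts; at least one nonzero.
#' @return Object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be nonnegative integers")
  if (sum(cells) == 0) stop("all-zero table")
  storage.mode(cells) <- "integer"
  structure(as.list(cells), class = "contingency_2x2")
}

as_2x2_matrix <- function(t) {
  matrix(c(t$a, t$c, t$b, t$d), nrow = 2,
         dimnames = list(exposure = c("exposed", "unexposed"),
                         outcome = c("case", "control")))
}

#' Odds ratio with 95% confidence interval
#'
#' Point estimate `(a*d)/(b*c)`. When all cells are positive the CI is the
#' Woolf (log-OR normal) interval
#' `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When the OR is
#' infinite (`b*c = 0`, `a*d > 0`) it is reported as `Inf` with the exact
#' conditional one-sided lower bound; a zero OR (`a*d = 0`, `b*c > 0`)
#' symmetrically gets an exact one-sided upper bound. The optional Haldane
#' correction adds 0.5 to every cell before the Woolf computation.
#'
#' @param t a [contingency_2x2()].
#' @param conf_level confidence level (default 0.95, z = 1.96).
#' @param haldane add 0.5 to all cells when any cell is zero.
#' @return Object of class `odds_ratio_result`: `or_point`, `ci_low`,
#'   `ci_high`, `conf_level`, `method`.
#' @export
odds_ratio <- function(t, conf_level = 0.95, haldane = FALSE) {
  stopifnot(inherits(t, "contingency_2x2"))
  a <- t$a; b <- t$b; cc <- t$c; d <- t$d
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  any_zero <- any(c(a, b, cc, d) == 0)
  if (haldane && any_zero) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    any_zero <- FALSE
  }
  if (!any_zero) {
    or <- (a * d) / (b * cc)
    se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
    ci <- exp(log(or) + c(-1, 1) * z * se)
    method <- if (haldane) "woolf-haldane" else "woolf"
    return(structure(list(or_point = or, ci_low = ci[1], ci_high = ci[2],
                          conf_level = conf_level, method = method),
                     class = "odds_ratio_result"))
  }
  num <- a * d; den <- b * cc
  if (num == 0 && den == 0)
    stop("odds ratio undefined: both cross products are zero")
  if (den == 0) {
    ft <- stats::fisher.test(as_2x2_matrix(t), alternative = "greater",
                             conf.level = conf_level)
    res <- list(or_point = Inf, ci_low = unname(ft$conf.int[1]),
                ci_high = Inf)
  } else {
    ft <- stats::fisher.test(as_2x2_matrix(t), alternative = "less",
                             conf.level = conf_level)
    res <- list(or_point = 0, ci_low = 0,
                ci_high = unname(ft$conf.int[2]))
  }
  structure(c(res, list(conf_level = conf_level,
                        method = "exact-conditional")),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR = %.3g (%.0f%% CI %.3g-%.3g) [%s]\n",
              x$or_point, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$method))
  invisible(x)
}

#' Fisher's exact test (two-sided)
#'
#' Two-sided p-value by summation of conditional hypergeometric
#' probabilities no larger than that of the observed table.
#'
#' @param t a [contingency_2x2()].
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  stats::fisher.test(as_2x2_matrix(t))$p.value
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with midranks for ties. The p-value is exact
#' when the smaller sample has at most `exact_max` observations and there
#' are no ties; otherwise a normal approximation with continuity
#' correction is used.
#'
#' @param x,y nonempty numeric samples.
#' @param exact_max largest small-sample size for which the exact
#'   distribution is enumerated (default 8).
#' @return list with `statistic` (Mann-Whitney U of `x`), `p_value`,
#'   `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 8) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && min(length(x), length(y)) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = use_exact)
}

#' Univariate / multivariable logistic regression
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) of a binary
#' outcome on one or more covariates, reporting per-unit odds ratios
#' `exp(slope)` with Wald confidence intervals. Complete or
#' quasi-complete separation is detected (fitted probabilities numerically
#' 0/1) and flagged; coefficients are still reported with a warning.
#'
#' @param x numeric vector, matrix or data.frame of covariates.
#' @param y binary outcome (0/1 or logical), both classes present.
#' @param conf_level Wald CI level.
#' @return Object of class `logistic_fit`: `coefficients` (incl.
#'   intercept), `or` (per-unit, slopes only), `or_ci` (matrix), `n`,
#'   `converged`, `separation`, `fit` (the glm object).
#' @export
fit_logistic <- function(x, y, conf_level = 0.95) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("outcome must contain both classes")
  df <- as.data.frame(x)
  if (is.null(colnames(x))) names(df) <- paste0("x", seq_along(df))
  df$.y <- y
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep)
    warning("separation detected: coefficients unreliable")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  slopes <- co[-1]
  ci <- cbind(low = exp(slopes - z * se[-1]),
              high = exp(slopes + z * se[-1]))
  structure(list(coefficients = co, se = se, or = exp(slopes),
                 or_ci = ci, n = length(y),
                 converged = fit$converged, separation = sep,
                 fit = fit),
            class = "logistic_fit")
}

#' Logistic pseudo-R-squared measures
#'
#' McFadden, Cox-Snell and Nagelkerke pseudo-R2 for a [fit_logistic()]
#' model. Which flavour a given report means is often unstated, so all
#' three are returned.
#'
#' @param fit a `logistic_fit`.
#' @return named numeric: `mcfadden`, `cox_snell`, `nagelkerke`.
#' @export
pseudo_r2 <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  g <- fit$fit
  ll_full <- as.numeric(stats::logLik(g))
  y <- g$y
  n <- fit$n
  pbar <- mean(y)
  ll_null <- sum(y) * log(pbar) + sum(1 - y) * log(1 - pbar)
  cs <- 1 - exp(2 * (ll_null - ll_full) / n)
  c(mcfadden = 1 - ll_full / ll_null,
    cox_snell = cs,
    nagelkerke = cs / (1 - exp(2 * ll_null / n)))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups observations into `g` equal-count groups by fitted probability
#' (deciles of risk for `g = 10`), keeping tied probabilities together,
#' and compares observed with expected event counts:
#' `chi2 = sum (O - E)^2 / (E (1 - E/n_g))`, df = groups - 2. Groups that
#' collapse because of ties are merged with a warning.
#'
#' @param p_hat fitted probabilities.
#' @param y binary outcomes.
#' @param g requested number of groups (default 10).
#' @return list with `chi2`, `df`, `p_value`, `g` (groups actually used),
#'   `table` (per-group n, observed, expected).
#' @export
hosmer_lemeshow <- function(p_hat, y, g = 10) {
  stopifnot(length(p_hat) == length(y), g >= 3, length(y) >= g)
  y <- as.integer(y)
  breaks <- unique(stats::quantile(p_hat, probs = seq(0, 1, length.out = g + 1),
                                   type = 7))
  if (length(breaks) < 3) {
    warning("fitted probabilities (nearly) constant: groups collapsed ",
            "to one after merging; test undefined")
    return(list(chi2 = NA_real_, df = NA_integer_, p_value = NA_real_,
                g = 1L, table = NULL))
  }
  if (length(breaks) < g + 1)
    warning("tied fitted probabilities: groups merged, using ",
            length(breaks) - 1, " groups")
  grp <- cut(p_hat, breaks = breaks, include.lowest = TRUE)
  ng <- tapply(y, grp, length)
  obs <- tapply(y, grp, sum)
  exp_ <- tapply(p_hat, grp, sum)
  keep <- !is.na(ng) & ng > 0
  ng <- ng[keep]; obs <- obs[keep]; exp_ <- exp_[keep]
  chi2 <- sum((obs - exp_)^2 / (exp_ * (1 - exp_ / ng)))
  df <- length(ng) - 2
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       g = length(ng),
       table = data.frame(n = as.vector(ng), observed = as.vector(obs),
                          expected = as.vector(exp_)))
}

#' Calibration slope
#'
#' Slope of the logistic regression of outcomes on the logit of the
#' fitted probabilities; 1 means perfect calibration, below 1 indicates
#' overfitted (too extreme) predictions. Probabilities at 0 or 1 are
#' clipped to `[1e-8, 1 - 1e-8]` with a warning.
#'
#' @param p_hat fitted probabilities.
#' @param y binary outcomes.
#' @return list with `slope`, `intercept`, `separation` flag.
#' @export
calibration_slope <- function(p_hat, y) {
  stopifnot(length(p_hat) == length(y))
  if (any(p_hat <= 0 | p_hat >= 1)) {
    warning("fitted probabilities at 0/1 clipped")
    p_hat <- pmin(pmax(p_hat, 1e-8), 1 - 1e-8)
  }
  if (length(unique(as.integer(y))) < 2L) {
    warning("constant outcome: calibration slope undefined (separation)")
    return(list(slope = NA_real_, intercept = NA_real_, separation = TRUE))
  }
  fit <- fit_logistic(data.frame(logit = stats::qlogis(p_hat)), y)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       separation = fit$separation)
}
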