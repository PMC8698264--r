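test_that("odds ratio point estimate, symmetry and Woolf CI behaviour", {
  t <- contingency_2x2(5, 5, 5, 5)
  or <- odds_ratio(t)
  expect_equal(or$or_point, 1)
  expect_lt(or$ci_low, 1); expect_gt(or$ci_high, 1)

  # exposure flip inverts the OR and mirrors the CI
  t1 <- contingency_2x2(7, 3, 2, 11)
  t2 <- contingency_2x2(2, 11, 7, 3)
  o1 <- odds_ratio(t1); o2 <- odds_ratio(t2)
  expect_equal(o2$or_point, 1 / o1$or_point)
  expect_equal(o2$ci_low, 1 / o1$ci_high)
  expect_equal(o2$ci_high, 1 / o1$ci_low)

  # scaling all cells up narrows the Woolf interval monotonically
  widths <- sapply(c(1, 2, 4, 8), function(k) {
    o <- odds_ratio(contingency_2x2(3 * k, 2 * k, 4 * k, 5 * k))
    log(o$ci_high) - log(o$ci_low)
  })
  expect_true(all(diff(widths) < 0))
})

test_that("zero-cell tables route to exact conditional bounds", {
  inf <- odds_ratio(contingency_2x2(11, 0, 1, 99))
  expect_identical(inf$or_point, Inf)
  expect_identical(inf$method, "exact-conditional")
  expect_true(is.finite(inf$ci_low) && inf$ci_low > 1)
  expect_identical(inf$ci_high, Inf)

  zero <- odds_ratio(contingency_2x2(0, 31, 12, 68))
  expect_identical(zero$or_point, 0)
  expect_identical(zero$ci_low, 0)
  expect_true(is.finite(zero$ci_high))

  expect_error(odds_ratio(contingency_2x2(0, 5, 0, 7)), "undefined")

  hald <- odds_ratio(contingency_2x2(11, 0, 1, 99), haldane = TRUE)
  expect_true(is.finite(hald$or_point))
  expect_identical(hald$method, "woolf-haldane")
})

test_that("fisher exact: degenerate tables and flip symmetry", {
  expect_equal(fisher_exact(contingency_2x2(0, 0, 12, 99)), 1)
  expect_equal(fisher_exact(contingency_2x2(10, 20, 5, 10)), 1)
  t <- contingency_2x2(8, 2, 3, 9)
  expect_equal(fisher_exact(t), fisher_exact(contingency_2x2(3, 9, 8, 2)))
  expect_equal(fisher_exact(t), fisher_exact(contingency_2x2(2, 8, 9, 3)))
})

test_that("wilcoxon rank-sum: identical, separated and permutation oracle", {
  x <- c(1.2, 3.4, 5.1, 7.8)
  expect_equal(wilcoxon_rank_sum(x, x)$p_value, 1, tolerance = 1e-8)

  # complete separation at 3 vs 3: exact two-sided p = 2/20
  w <- wilcoxon_rank_sum(c(10, 11, 12), c(1, 2, 3))
  expect_true(w$exact)
  expect_equal(w$p_value, 0.1)

  # n = 6 vs 6 against full enumeration of rank assignments
  set.seed(41)
  xs <- rnorm(6); ys <- rnorm(6) + 0.5
  w2 <- wilcoxon_rank_sum(xs, ys)
  r <- rank(c(xs, ys))
  obs_u <- sum(r[1:6]) - 6 * 7 / 2
  combs <- utils::combn(12, 6)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - 6 * 7 / 2)
  p_ref <- mean(abs(us - 18) >= abs(obs_u - 18))  # E[U] = n1 n2 / 2 = 18
  expect_true(w2$exact)
  expect_equal(w2$p_value, p_ref)
})

test_that("logistic regression recovers a known generating model", {
  set.seed(42)
  n <- 5000
  x <- rnorm(n, 25, 10)
  y <- rbinom(n, 1, plogis(-2 + 0.08 * x))
  fit <- fit_logistic(data.frame(x = x), y)
  expect_false(fit$separation)
  expect_lt(abs(unname(fit$coefficients["x"]) - 0.08), 0.01)
  expect_equal(unname(fit$or["x"]),
               exp(unname(fit$coefficients["x"])))

  # null model: slope near zero, OR near 1
  set.seed(43)
  y0 <- rbinom(n, 1, 0.3)
  fit0 <- fit_logistic(data.frame(x = x), y0)
  expect_lt(abs(unname(fit0$coefficients["x"])), 0.01)
  expect_true(fit0$or_ci[1, "low"] < 1 && fit0$or_ci[1, "high"] > 1)

  # deterministic threshold outcome: separation must be flagged
  ysep <- as.integer(x > 25)
  expect_warning(fsep <- fit_logistic(data.frame(x = x), ysep),
                 "separation")
  expect_true(fsep$separation)
  expect_error(fit_logistic(data.frame(x = x), rep(1, n)), "both classes")
})

test_that("Hosmer-Lemeshow: df formula, type-I behaviour, degenerate input", {
  set.seed(7)
  p <- runif(111, 0.05, 0.6)
  y <- rbinom(111, 1, p)
  hl <- hosmer_lemeshow(p, y, g = 10)
  expect_identical(hl$df, 8)
  expect_equal(hl$g, 10)
  expect_equal(hl$p_value, pchisq(hl$chi2, 8, lower.tail = FALSE))

  # calibrated model: rejection rate near the nominal level
  set.seed(8)
  rej <- mean(replicate(200, {
    pp <- runif(400, 0.1, 0.8)
    yy <- rbinom(400, 1, pp)
    hosmer_lemeshow(pp, yy)$p_value < 0.05
  }))
  expect_gt(rej, 0.005)
  expect_lt(rej, 0.12)

  expect_warning(hl0 <- hosmer_lemeshow(rep(0.3, 50), rbinom(50, 1, 0.3)),
                 "collapsed")
  expect_true(is.na(hl0$chi2))
})

test_that("calibration slope: perfect, shrunk, and degenerate cases", {
  set.seed(9)
  n <- 20000
  eta <- rnorm(n, 0, 1.5)
  y <- rbinom(n, 1, plogis(eta))
  expect_equal(calibration_slope(plogis(eta), y)$slope, 1,
               tolerance = 0.05)
  # doubling the logits halves the calibration slope (extreme inflated
  # logits trigger the separation warning from the refit; expected here)
  expect_equal(suppressWarnings(calibration_slope(plogis(2 * eta), y))$slope,
               0.5, tolerance = 0.05)

  expect_warning(cs <- calibration_slope(rep(0.4, 30), rep(1L, 30)),
                 "separation|constant")
  expect_true(cs$separation)
  # clipping to the open interval, then separation on the 3-point refit
  expect_warning(expect_warning(
    calibration_slope(c(0, 0.5, 1), c(0, 1, 1)), "clipped"),
    "separation")
})

test_that("pseudo-R2 flavours are coherent", {
  set.seed(10)
  x <- rnorm(500); y <- rbinom(500, 1, plogis(-0.5 + 1.2 * x))
  r2 <- pseudo_r2(fit_logistic(data.frame(x = x), y))
  expect_named(r2, c("mcfadden", "cox_snell", "nagelkerke"))
  expect_true(all(r2 > 0 & r2 < 1))
  expect_gt(r2["nagelkerke"], r2["cox_snell"])
})
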