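# Validation statistics: oracles and internal-consistency invariants.

test_that("absolute error is element-wise with label matching", {
  v1 <- c(A1 = 1, A2 = 2, A3 = -1)
  v2 <- c(A1 = 1, A2 = -1, A3 = 0.5)
  e <- absolute_error(v1, v2)
  expect_equal(as.vector(e), c(0, 3, 1.5))
  expect_named(attr(e, "summary"), c("median", "q1", "q3"))
  set.seed(3)
  a <- rnorm(30); b <- rnorm(30)
  names(a) <- names(b) <- paste0("E", 1:30)
  expect_equal(as.vector(absolute_error(a, b)), unname(abs(a - b)))
  expect_error(absolute_error(v1, v2[1:2]), "labels")
})

test_that("Brown-Forsythe matches a hand-computed ANOVA and car::leveneTest", {
  x <- c(1, 2, 5, 9)
  y <- c(3, 3.5, 4, 3.2)
  bf <- brown_forsythe(x, y)
  # hand oracle: one-way ANOVA on |x - median| via explicit sums of squares
  zx <- abs(x - median(x)); zy <- abs(y - median(y))
  z <- c(zx, zy); g <- rep(1:2, each = 4)
  ssb <- 4 * (mean(zx) - mean(z))^2 + 4 * (mean(zy) - mean(z))^2
  ssw <- sum((zx - mean(zx))^2) + sum((zy - mean(zy))^2)
  f_hand <- (ssb / 1) / (ssw / 6)
  expect_equal(bf$statistic, f_hand, tolerance = 1e-12)
  expect_equal(bf$p_value, pf(f_hand, 1, 6, lower.tail = FALSE))
  skip_if_not_installed("car")
  lt <- car::leveneTest(z_raw ~ grp,
                        data = data.frame(z_raw = c(x, y),
                                          grp = factor(g)),
                        center = median)
  expect_equal(bf$statistic, lt[1, "F value"], tolerance = 1e-10)
  expect_equal(bf$p_value, lt[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("Brown-Forsythe: identical samples give F = 0; degenerate input errors", {
  x <- c(1, 2, 3, 4)
  bf <- brown_forsythe(x, x)
  expect_equal(bf$statistic, 0)
  expect_equal(bf$p_value, 1)
  expect_error(brown_forsythe(c(1, 1, 1), c(2, 2, 2)), "degenerate")
})

test_that("Brown-Forsythe detects a 5-fold SD difference with high power", {
  rejections <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    brown_forsythe(rnorm(60, sd = 1), rnorm(60, sd = 5))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.95)
})

test_that("Wilcoxon signed-rank: frozen exact examples", {
  # all-positive ranks, n = 5: W = 15, exact two-sided p = 2/32
  w5 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(w5$statistic, 15)
  expect_equal(w5$p_value, 0.0625)
  expect_identical(w5$mode, "exact")
  # symmetric alternating differences: p = 1
  ws <- wilcoxon_signed_rank(rep(c(1, -1), 5))
  expect_equal(ws$p_value, 1)
  expect_error(wilcoxon_signed_rank(rep(0, 6)), "zero")
})

test_that("Wilcoxon exact mode equals brute-force sign-flip enumeration (n <= 12)", {
  for (n in c(4, 6, 8, 10, 12)) {
    set.seed(n)
    d <- round(rnorm(n, sd = 2), 1)
    d[d == 0] <- 0.1
    if (n >= 8) d[2] <- d[1]          # inject ties in |d|
    res <- wilcoxon_signed_rank(d)
    r <- rank(abs(d))
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wdist <- as.vector(signs %*% r)
    w <- sum(r[d > 0])
    p_brute <- min(1, 2 * min(mean(wdist <= w + 1e-9),
                              mean(wdist >= w - 1e-9)))
    expect_equal(res$p_value, p_brute, tolerance = 1e-12,
                 label = sprintf("n=%d", n))
  }
})

test_that("Wilcoxon normal approximation tracks the exact mode at n = 20", {
  set.seed(7)
  d <- rnorm(20, mean = 0.3)
  p_exact <- wilcoxon_signed_rank(d, exact_limit = 20)$p_value
  p_norm <- wilcoxon_signed_rank(d, exact_limit = 10)$p_value
  expect_lt(abs(p_exact - p_norm), 0.02)
  # cross-check against stats::wilcox.test where it supports exact mode
  set.seed(8)
  d2 <- rnorm(11)
  expect_equal(wilcoxon_signed_rank(d2)$p_value,
               wilcox.test(d2, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("Holm adjustment: frozen step-down examples and dominance", {
  h <- holm_bonferroni(c(0.01, 0.02, 0.04))
  expect_equal(h$p_adjusted, c(0.03, 0.04, 0.04))
  expect_true(all(h$reject))
  h2 <- holm_bonferroni(c(0.03, 0.03))
  expect_equal(h2$p_adjusted, c(0.06, 0.06))
  expect_false(any(h2$reject))
  h1 <- holm_bonferroni(0.04)
  expect_equal(h1$p_adjusted, 0.04)
  # dominance: adjusted >= raw; smallest rank bounded by Bonferroni m*p
  set.seed(12)
  p <- runif(9)
  hh <- holm_bonferroni(p)
  expect_true(all(hh$p_adjusted >= hh$p_raw))
  expect_lte(hh$p_adjusted[which.min(p)], min(1, 9 * min(p)))
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("regression report matches closed-form OLS and its invariants", {
  set.seed(21)
  x <- rnorm(40, sd = 2)
  y <- 1.5 * x + 0.3 + rnorm(40, sd = 0.5)
  rep_ <- regression_report(x, y)
  # closed-form oracle
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  res <- y - b0 - b1 * x
  se <- sqrt(sum(res^2) / 38 / sum((x - mean(x))^2))
  expect_equal(rep_$slope, b1)
  expect_equal(rep_$intercept, b0)
  expect_equal(rep_$slope_se, se)
  expect_equal(rep_$t, b1 / se)
  expect_equal(rep_$r_squared, cor(x, y)^2)
  # internal invariants: F = t^2, R^2 = r^2, df = (1, n-2)
  expect_equal(rep_$f, rep_$t^2, tolerance = 1e-8)
  expect_equal(rep_$r_squared, rep_$pearson_r^2, tolerance = 1e-10)
  expect_equal(rep_$df, c(1, 38))
  # trivial cases
  idr <- regression_report(x, x)
  expect_equal(idr$slope, 1)
  expect_equal(idr$pearson_r, 1)
  expect_equal(max(abs(idr$residuals)), 0, tolerance = 1e-12)
  dbl <- regression_report(x, 2 * x)
  expect_equal(dbl$slope, 2)
  expect_error(regression_report(rep(1, 5), rnorm(5)), "variance")
  expect_error(regression_report(1:2, 1:2), "n >= 3")
})

test_that("1 mA normalization commutes with regression slope rescaling", {
  expect_equal(normalize_to_unit_current(c(7e-3, 2e-3), 3.5), c(2e-3, 4e-3 / 7))
  expect_identical(normalize_to_unit_current(5, 1), 5)
  expect_error(normalize_to_unit_current(1, 0), "positive")
  set.seed(30)
  vs <- rnorm(30); vr <- 1.3 * vs + rnorm(30, sd = 0.1)
  I0 <- 3.5
  r_norm <- regression_report(vs / I0, vr / I0)
  r_raw <- regression_report(vs, vr)
  expect_equal(r_norm$slope, r_raw$slope, tolerance = 1e-12)
  expect_equal(r_norm$pearson_r, r_raw$pearson_r, tolerance = 1e-12)
})

test_that("squared residuals and their ECDF behave", {
  set.seed(40)
  x <- rnorm(20); y <- x + rnorm(20, sd = 0.2)
  rp <- regression_report(x, y)
  sq <- squared_residual_summary(rp)
  expect_equal(sq$squared_residuals, rp$residuals^2)
  expect_equal(sq$ecdf(max(sq$squared_residuals)), 1)
  perfect <- regression_report(x, 2 * x + 1)
  sp <- squared_residual_summary(perfect)
  expect_lt(max(sp$squared_residuals), 1e-28)
  expect_equal(sp$ecdf(1e-20), 1)
})
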