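# Model-validation statistics: absolute error, equality-of-variance and
# paired nonparametric tests with step-down multiplicity control, and the
# regression/correlation report comparing simulated to recorded voltages.

#' Per-electrode absolute error
#'
#' `|V_rec - V_sim|` over matched electrode labels; stimulating contacts
#' must be excluded by the caller (only passive contacts are validated).
#'
#' @param v_rec,v_sim named voltage vectors (volts) with identical label
#'   sets.
#' @return named vector of absolute errors with a `summary` attribute
#'   (median and IQR).
#' @export
absolute_error <- function(v_rec, v_sim) {
  if (is.null(names(v_rec)) || is.null(names(v_sim)) ||
        !setequal(names(v_rec), names(v_sim)) ||
        length(v_rec) != length(v_sim))
    stop("electrode labels of recorded and simulated voltages do not match",
         call. = FALSE)
  err <- abs(v_rec - v_sim[names(v_rec)])
  attr(err, "summary") <- c(median = stats::median(err),
                            q1 = unname(stats::quantile(err, 0.25)),
                            q3 = unname(stats::quantile(err, 0.75)))
  err
}

#' Brown-Forsythe test for equality of variances
#'
#' Median-centred absolute deviations compared by one-way ANOVA (the
#' robust Levene variant).
#'
#' @param x,y numeric samples (each n >= 2).
#' @return a `test_result`: list with `statistic` (F), `df`, `p_value`,
#'   `test`, `n`.
#' @export
brown_forsythe <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs n >= 2", call. = FALSE)
  zx <- abs(x - stats::median(x))
  zy <- abs(y - stats::median(y))
  if (stats::sd(zx) == 0 && stats::sd(zy) == 0)
    stop("degenerate samples: zero within-group deviation in both groups",
         call. = FALSE)
  z <- c(zx, zy)
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  ow <- stats::oneway.test(z ~ g, var.equal = TRUE)
  structure(
    list(statistic = unname(ow$statistic), df = unname(ow$parameter),
         p_value = unname(ow$p.value), test = "Brown-Forsythe",
         n = c(length(x), length(y))),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s: statistic %.4g, p = %.4g>\n", x$test, x$statistic,
              x$p_value))
  invisible(x)
}

# Exact null distribution of the signed-rank statistic W+ for given
# (possibly tied, half-integer) ranks: dynamic programme over doubled ranks.
signed_rank_null <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  maxw <- sum(r2)
  counts <- numeric(maxw + 1)
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(maxw + 1 - r)])
    counts <- counts + shifted
  }
  counts   # counts[w+1] = #assignments with 2*W+ == w
}

#' Wilcoxon signed-rank test
#'
#' Exact two-sided p by sign-assignment enumeration (dynamic programme,
#' handles ties by mean ranks) for n <= `exact_limit` non-zero
#' differences; normal approximation with tie correction and continuity
#' correction above. Zero differences are dropped (signed-rank
#' convention).
#'
#' @param diffs paired differences.
#' @param exact_limit maximum n for the exact mode (default 20).
#' @return a `test_result` with `statistic` (W+, the positive-rank sum),
#'   `p_value`, `n` (non-zero pairs), `mode` ("exact" or "normal").
#' @export
wilcoxon_signed_rank <- function(diffs, exact_limit = 20L) {
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0)
    stop("degenerate input: all paired differences are zero", call. = FALSE)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    counts <- signed_rank_null(r)
    total <- 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(counts[seq_len(w2 + 1)]) / total
    p_ge <- sum(counts[(w2 + 1):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    mode <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    mode <- "normal"
  }
  structure(
    list(statistic = w, p_value = p, test = "Wilcoxon signed-rank",
         n = n, mode = mode),
    class = "test_result"
  )
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p_values raw p values in \[0, 1\].
#' @param alpha family-wise error rate (default 0.05).
#' @return data.frame with `p_raw`, `p_adjusted` (monotone in rank order)
#'   and `reject`.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  adj <- stats::p.adjust(p_values, method = "holm")
  data.frame(p_raw = p_values, p_adjusted = adj, reject = adj < alpha)
}

#' Linear regression report: predicting recorded from simulated voltages
#'
#' Ordinary least squares with intercept, simulated voltage as the
#' predictor: a slope above 1 means the model under-predicts the recorded
#' voltages. Reports slope, its standard error, t and F statistics with
#' p values, R^2 and the Pearson correlation.
#'
#' @param v_sim predictor (simulated voltages, volts).
#' @param v_rec response (recorded voltages, volts).
#' @return a `regression_report`: list with `slope`, `intercept`,
#'   `slope_se`, `t`, `p_t`, `r_squared`, `f`, `df` (c(1, n-2)), `p_f`,
#'   `pearson_r`, `n`, and the residuals.
#' @export
regression_report <- function(v_sim, v_rec) {
  n <- length(v_sim)
  if (n < 3) stop("regression needs n >= 3", call. = FALSE)
  if (stats::var(v_sim) == 0)
    stop("zero predictor variance", call. = FALSE)
  fit <- stats::lm(v_rec ~ v_sim)
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      # exact fits (zero residuals) are legitimate here
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  co <- sm$coefficients
  fstat <- unname(sm$fstatistic)
  structure(
    list(slope = unname(co["v_sim", "Estimate"]),
         intercept = unname(co["(Intercept)", "Estimate"]),
         slope_se = unname(co["v_sim", "Std. Error"]),
         t = unname(co["v_sim", "t value"]),
         p_t = unname(co["v_sim", "Pr(>|t|)"]),
         r_squared = sm$r.squared,
         f = fstat[1], df = c(fstat[2], fstat[3]),
         p_f = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
         pearson_r = stats::cor(v_sim, v_rec),
         n = n, residuals = unname(stats::residuals(fit))),
    class = "regression_report"
  )
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf(
    "<regression_report: slope %.3f (SE %.3f), r = %.3f, R^2 = %.3f, F(%d,%d) = %.1f, n = %d>\n",
    x$slope, x$slope_se, x$pearson_r, x$r_squared, x$df[1], x$df[2], x$f, x$n))
  invisible(x)
}

#' Normalize voltages to a 1 mA stimulation amplitude
#'
#' Divides by the stimulation amplitude, presuming linear scaling, so data
#' recorded at different amplitudes pool on a common scale.
#'
#' @param voltages voltages (volts).
#' @param I0_mA stimulation amplitude (mA, > 0).
#' @return voltages that 1 mA stimulation would have produced.
#' @export
normalize_to_unit_current <- function(voltages, I0_mA) {
  if (I0_mA <= 0) stop("stimulation amplitude must be positive", call. = FALSE)
  voltages / I0_mA
}

#' Squared regression residuals and their empirical CDF
#'
#' @param report a [regression_report()].
#' @return list with `squared_residuals` and `ecdf` (a function).
#' @export
squared_residual_summary <- function(report) {
  sq <- report$residuals^2
  list(squared_residuals = sq, ecdf = stats::ecdf(sq))
}
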