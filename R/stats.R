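#' Container for one inferential result
#'
#' One row of a trial report table: the estimate (difference of means,
#' medians or proportions), its confidence interval, the p-value and a
#' note naming the method used.
#'
#' @param test_name Label of the test.
#' @param estimate Point estimate of the group difference.
#' @param ci_low,ci_high Confidence limits (same units as the estimate).
#' @param p_value Two-sided p-value.
#' @param method_notes Free-text note (e.g. which CI construction).
#' @return Object of class `stat_result`.
#' @export
stat_result <- function(test_name, estimate = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        method_notes = "") {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value must lie in [0, 1]", call. = FALSE)
  if (!is.na(ci_low) && !is.na(ci_high) && !is.na(estimate) &&
      (estimate < ci_low - 1e-8 || estimate > ci_high + 1e-8))
    stop("estimate must lie inside its confidence interval", call. = FALSE)
  structure(list(test_name = test_name, estimate = estimate,
                 ci_low = ci_low, ci_high = ci_high, p_value = p_value,
                 method_notes = method_notes),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  ci <- if (!is.na(x$ci_low)) sprintf(" (%.4g, %.4g)", x$ci_low, x$ci_high) else ""
  est <- if (!is.na(x$estimate)) sprintf("%.4g", x$estimate) else "-"
  cat(sprintf("%s: estimate %s%s, p = %.4g  [%s]\n",
              x$test_name, est, ci,
              x$p_value, x$method_notes))
  invisible(x)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
# of the combined midranks (handles ties); feasible for small groups.
mw_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(nx)])
  idx <- utils::combn(nx + ny, nx)
  stats_all <- colSums(matrix(r[idx], nrow = nx))
  mu <- mean(stats_all)
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9)
}

#' Mann-Whitney U test for two independent samples
#'
#' Two-sided comparison of distribution location. Groups of at least nine
#' use the tie-corrected normal approximation (no continuity correction);
#' smaller groups use exact enumeration of all rank assignments, which
#' remains valid under ties.
#'
#' @param x,y Numeric samples (non-empty).
#' @return A [stat_result()]; the estimate is the difference of sample
#'   medians (`y - x`), reported without a CI (see [hodges_lehmann()]).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("samples must be non-empty", call. = FALSE)
  exact <- min(length(x), length(y)) < 9
  p <- if (length(unique(c(x, y))) == 1L) {
    1  # fully degenerate: the two samples are identical constants
  } else if (exact) {
    mw_exact_p(x, y)
  } else {
    suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
  }
  stat_result("Mann-Whitney U",
              estimate = stats::median(y) - stats::median(x),
              p_value = p,
              method_notes = if (exact) "exact enumeration"
              else "normal approximation, tie-corrected")
}

#' Hodges-Lehmann estimate of a difference in medians
#'
#' The estimate is the median of all `length(x) * length(y)` pairwise
#' differences `y - x`; the confidence interval is the Moses construction
#' on the ordered pairwise differences, with critical values from the
#' exact Wilcoxon rank-sum distribution for moderate samples and the
#' normal approximation beyond that. The p-value is the Mann-Whitney
#' test's.
#'
#' @param x,y Numeric samples; the difference is oriented `y - x`.
#' @param conf Confidence level.
#' @return A [stat_result()].
#' @examples
#' hodges_lehmann(c(1, 2), c(2, 4))  # estimate 1.5
#' @export
hodges_lehmann <- function(x, y, conf = 0.95) {
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) stop("samples must be non-empty", call. = FALSE)
  d <- sort(outer(y, x, "-"))
  est <- stats::median(d)
  N <- m * n
  alpha <- 1 - conf
  if (N >= 3 && m <= 100 && n <= 100) {
    qu <- stats::qwilcox(alpha / 2, m, n)
    if (qu == 0) qu <- 1
    lo <- d[qu]
    hi <- d[N - qu + 1]
    note <- "Moses CI, exact rank-sum critical values"
  } else {
    k <- max(1, round(N / 2 - stats::qnorm(1 - alpha / 2) *
                        sqrt(N * (m + n + 1) / 12)))
    lo <- d[k]
    hi <- d[N + 1 - k]
    note <- "Moses CI, normal approximation"
  }
  stat_result("Hodges-Lehmann", estimate = est, ci_low = lo, ci_high = hi,
              p_value = mann_whitney(x, y)$p_value, method_notes = note)
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance two-sample t-test on reported group summaries, with the
#' confidence interval built from t critical values at the pooled degrees
#' of freedom (`n1 + n2 - 2`). The difference is oriented
#' `mean2 - mean1`.
#'
#' @param mean1,sd1,n1 Summary of group 1.
#' @param mean2,sd2,n2 Summary of group 2.
#' @param conf Confidence level.
#' @return A [stat_result()].
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                conf = 0.95) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("sds must be positive", call. = FALSE)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  se <- sp * sqrt(1 / n1 + 1 / n2)
  diff <- mean2 - mean1
  tstat <- diff / se
  p <- 2 * stats::pt(-abs(tstat), df)
  half <- stats::qt(1 - (1 - conf) / 2, df) * se
  stat_result("pooled t (summary)", estimate = diff,
              ci_low = diff - half, ci_high = diff + half, p_value = p,
              method_notes = sprintf("t critical values, df = %d", df))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson statistic on
#' 1 degree of freedom.
#'
#' @param a,b Events / non-events in group 1.
#' @param c,d Events / non-events in group 2.
#' @return A [stat_result()]; the estimate is the difference in event
#'   proportions (`group1 - group2`), on the percentage scale.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  tab <- check_2x2(a, b, c, d)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  stat_result("chi-square",
              estimate = 100 * (a / (a + b) - c / (c + d)),
              p_value = res$p.value,
              method_notes = "Pearson, 1 df, no continuity correction")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p as the sum of probabilities of all tables with point
#' probability not exceeding the observed one.
#'
#' @inheritParams chi_square_2x2
#' @return A [stat_result()].
#' @export
fisher_2x2 <- function(a, b, c, d) {
  tab <- check_2x2(a, b, c, d)
  res <- stats::fisher.test(tab)
  stat_result("Fisher exact",
              estimate = 100 * (a / (a + b) - c / (c + d)),
              p_value = res$p.value,
              method_notes = "two-sided, sum of tables with prob <= observed")
}

check_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers", call. = FALSE)
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has a zero margin", call. = FALSE)
  tab
}

#' Choose between chi-square and Fisher for a 2x2 table
#'
#' Fisher's exact test is selected when at least half of the expected
#' cell counts fall below 5, otherwise the chi-square test.
#'
#' @inheritParams chi_square_2x2
#' @return `"fisher"` or `"chi-square"`.
#' @export
select_test <- function(a, b, c, d) {
  tab <- check_2x2(a, b, c, d)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (mean(expected < 5) >= 0.5) "fisher" else "chi-square"
}

#' Difference in proportions with a continuity-corrected Wald interval
#'
#' Difference `x1/n1 - x2/n2` on the percentage scale, with
#' `diff +/- (z * SE_unpooled + 1/(2 n1) + 1/(2 n2))`.
#'
#' @param x1,n1 Events and size of group 1.
#' @param x2,n2 Events and size of group 2.
#' @param conf Confidence level.
#' @return A [stat_result()] (no p-value; pair with [select_test()]).
#' @export
proportion_diff_ci <- function(x1, n1, x2, n2, conf = 0.95) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive", call. = FALSE)
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop("event counts must lie in [0, n]", call. = FALSE)
  p1 <- x1 / n1; p2 <- x2 / n2
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  cc <- 1 / (2 * n1) + 1 / (2 * n2)
  half <- stats::qnorm(1 - (1 - conf) / 2) * se + cc
  stat_result("proportion difference",
              estimate = 100 * (p1 - p2),
              ci_low = 100 * (p1 - p2 - half),
              ci_high = 100 * (p1 - p2 + half),
              method_notes = "continuity-corrected Wald")
}

#' Design parameters for the trial's power calculation
#'
#' @param mu_intervention,mu_control Anticipated primary-outcome group
#'   means, mmHg.
#' @param sd Common standard deviation, mmHg.
#' @param alpha Two-sided type-I error.
#' @param power Target power.
#' @param dropout Anticipated dropout fraction.
#' @return Object of class `power_spec`.
#' @export
power_spec <- function(mu_intervention = 0.15, mu_control = 0.40,
                       sd = 0.32, alpha = 0.05, power = 0.80,
                       dropout = 0.10) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, sd > 0,
            dropout >= 0, dropout < 1)
  structure(list(mu_intervention = mu_intervention,
                 mu_control = mu_control, sd = sd, alpha = alpha,
                 power = power, dropout = dropout),
            class = "power_spec")
}

# power of the two-sided pooled t-test at equal per-group n
t_test_power <- function(n, delta, sd, alpha) {
  df <- 2 * n - 2
  if (df < 1) return(0)
  ncp <- abs(delta) / sd * sqrt(n / 2)
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp) + stats::pt(tcrit, df, ncp, lower.tail = FALSE)
}

#' Sample size for a two-sample comparison of means
#'
#' Smallest equal per-group size whose noncentral-t power for the
#' two-sided pooled t-test reaches the target.
#'
#' @param spec A [power_spec()].
#' @param n_max Search ceiling.
#' @return List with `n_per_group`, `n_total` and the achieved `power`.
#' @examples
#' sample_size_two_means(power_spec())  # n_total 54
#' @export
sample_size_two_means <- function(spec = power_spec(), n_max = 1e5) {
  stopifnot(inherits(spec, "power_spec"))
  delta <- spec$mu_control - spec$mu_intervention
  if (delta == 0) stop("zero effect size: power unreachable", call. = FALSE)
  for (n in 2:n_max) {
    pw <- t_test_power(n, delta, spec$sd, spec$alpha)
    if (pw >= spec$power)
      return(list(n_per_group = n, n_total = 2L * n, power = pw))
  }
  stop("target power unreachable within n_max", call. = FALSE)
}

#' Inflate a sample size for anticipated dropout
#'
#' Ceiling of `n_total / (1 - dropout)`, rounded up to the next even
#' integer to preserve 1:1 allocation.
#'
#' @param n_total Required completing sample size.
#' @param dropout Anticipated dropout fraction in `[0, 1)`.
#' @return Integer recruitment target.
#' @examples
#' inflate_for_dropout(54, 0.10)  # 60
#' @export
inflate_for_dropout <- function(n_total, dropout) {
  if (dropout < 0 || dropout >= 1)
    stop("dropout must lie in [0, 1)", call. = FALSE)
  n <- ceiling(n_total / (1 - dropout))
  as.integer(n + n %% 2)
}

#' Bonferroni adjustment over a comparison family
#'
#' @param p_values Unadjusted p-values.
#' @param family_size Number of comparisons in the family (at least the
#'   number of p-values supplied).
#' @param alpha Decision threshold applied to adjusted values.
#' @return Data frame with `p`, `p_adjusted`, `significant`.
#' @export
bonferroni <- function(p_values, family_size = length(p_values),
                       alpha = 0.05) {
  if (family_size < 1) stop("family_size must be >= 1", call. = FALSE)
  adj <- stats::p.adjust(p_values, method = "bonferroni", n = family_size)
  data.frame(p = p_values, p_adjusted = adj, significant = adj < alpha)
}
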