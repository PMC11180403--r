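test_that("exact Mann-Whitney matches enumeration conventions", {
  x <- c(3, 1, 4, 1, 5)
  expect_equal(mann_whitney(x, x)$p_value, 1)
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)

  # independent oracle: wilcox.test exact p on tie-free small samples
  set.seed(701)
  for (i in 1:25) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- rnorm(nx); y <- rnorm(ny, 0.5)
    expect_equal(mann_whitney(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("large-sample Mann-Whitney approximation tracks a permutation oracle", {
  set.seed(702)
  x <- rnorm(30, 0, 1)
  y <- round(rnorm(30, 0.45, 1), 1)  # rounding induces ties
  p_approx <- mann_whitney(x, y)$p_value
  r <- rank(c(x, y))
  obs <- sum(r[1:30])
  mu <- 30 * (60 + 1) / 2
  ws <- vapply(seq_len(1e5), function(i) sum(r[sample.int(60, 30)]), 0)
  p_mc <- mean(abs(ws - mu) >= abs(obs - mu) - 1e-9)
  expect_lt(abs(p_approx - p_mc), 0.005)
})

test_that("Hodges-Lehmann equals the all-pairs brute-force oracle", {
  # shift recovery
  x <- c(2, 9, 4, 7)
  expect_equal(hodges_lehmann(x, x + 3)$estimate, 3)
  # documented small example
  expect_equal(hodges_lehmann(c(1, 2), c(2, 4))$estimate, 1.5)

  set.seed(703)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30, 0.4)
    d <- c()
    for (xi in x) for (yj in y) d <- c(d, yj - xi)  # O(n^2) oracle
    expect_equal(hodges_lehmann(x, y)$estimate, median(d))
  }
})

test_that("Hodges-Lehmann interval matches the rank-sum reference construction", {
  set.seed(704)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(20, 0.3)
    ours <- hodges_lehmann(x, y)
    ref <- wilcox.test(y, x, conf.int = TRUE, exact = TRUE)
    expect_equal(ours$estimate, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(c(ours$ci_low, ours$ci_high), as.numeric(ref$conf.int),
                 tolerance = 1e-10)
  }
})

test_that("summary t-test reproduces printed trial rows", {
  expect_equal(t_test_from_summary(1, 1, 10, 1, 1, 10)$p_value, 1)

  age <- t_test_from_summary(60.17, 10.6, 30, 59.70, 10.3, 30)
  expect_equal(round(age$p_value, 2), 0.86)

  fb <- t_test_from_summary(1404.6, 1512.5, 30, 1810.7, 983.9, 30)
  expect_equal(round(fb$estimate, 1), 406.1)
  expect_equal(round(fb$ci_low, 1), -253.3)
  # printed upper limit 1065.6 came from unrounded data; the rounded
  # summaries support it to about +/- 0.15
  expect_lt(abs(fb$ci_high - 1065.6), 0.15)

  # cross-check against t.test on raw data with matching summaries
  set.seed(705)
  x <- rnorm(12); y <- rnorm(17, 1)
  ours <- t_test_from_summary(mean(x), sd(x), 12, mean(y), sd(y), 17)
  ref <- t.test(y, x, var.equal = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(c(ours$ci_low, ours$ci_high), as.numeric(ref$conf.int),
               tolerance = 1e-10)
})

test_that("2x2 tests reproduce printed trial rows and their invariants", {
  gi <- chi_square_2x2(6, 24, 14, 16)
  expect_equal(round(gi$p_value, 3), 0.028)

  dm <- fisher_2x2(3, 27, 6, 24)
  expect_equal(round(dm$p_value, 2), 0.47)

  bal <- chi_square_2x2(5, 5, 5, 5)
  expect_equal(bal$p_value, 1)

  # transpose invariance of the chi-square
  expect_equal(chi_square_2x2(6, 24, 14, 16)$p_value,
               chi_square_2x2(6, 14, 24, 16)$p_value)

  # Fisher p is at least the observed table's point probability
  set.seed(706)
  for (i in 1:25) {
    a <- rpois(1, 5); b <- rpois(1, 8) + 1; c <- rpois(1, 5); d <- rpois(1, 8) + 1
    if (a + c == 0) a <- 1
    p <- fisher_2x2(a, b, c, d)$p_value
    point <- dhyper(a, a + b, c + d, a + c)
    expect_gte(p + 1e-12, point)
  }
  expect_error(chi_square_2x2(0, 0, 2, 3), "margin")
})

test_that("the expected-count rule selects Fisher when half the cells are small", {
  expect_equal(select_test(3, 27, 6, 24), "fisher")     # expected 4.5 twice
  expect_equal(select_test(6, 24, 14, 16), "chi-square")
  expect_equal(select_test(15, 15, 15, 15), "chi-square")
})

test_that("proportion-difference intervals reproduce printed trial rows", {
  nic <- proportion_diff_ci(9, 30, 6, 30)
  expect_equal(round(nic$estimate, 1), 10.0)
  expect_equal(round(nic$ci_high, 1), 35.1)
  expect_equal(round(nic$ci_low, 1), -15.1)

  eph <- proportion_diff_ci(5, 30, 6, 30)
  expect_equal(round(eph$estimate, 1), -3.3)
  expect_equal(round(eph$ci_low, 1), -26.2)
  expect_equal(round(eph$ci_high, 1), 19.6)

  same <- proportion_diff_ci(7, 30, 7, 30)
  expect_equal(same$estimate, 0)
  expect_equal(same$ci_low, -same$ci_high)

  set.seed(707)
  for (i in 1:25) {
    n1 <- sample(10:50, 1); n2 <- sample(10:50, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    ci <- proportion_diff_ci(x1, n1, x2, n2)
    expect_lte(ci$ci_low, ci$estimate)
    expect_gte(ci$ci_high, ci$estimate)
    expect_equal(ci$estimate - ci$ci_low, ci$ci_high - ci$estimate,
                 tolerance = 1e-10)
  }
})

test_that("sample size search reproduces the trial design and its bounds", {
  spec <- power_spec()
  res <- sample_size_two_means(spec)
  expect_equal(res$n_total, 54L)
  expect_equal(inflate_for_dropout(res$n_total, spec$dropout), 60L)

  # power bracketing at the returned n
  expect_gte(res$power, spec$power)
  pw_below <- hpitrial:::t_test_power(res$n_per_group - 1,
                                      spec$mu_control - spec$mu_intervention,
                                      spec$sd, spec$alpha)
  expect_lt(pw_below, spec$power)

  # monotonicity: doubling the sd increases the requirement
  res2 <- sample_size_two_means(power_spec(sd = 0.64))
  expect_gt(res2$n_total, res$n_total)

  # normal-approximation closed form is a lower bound
  delta <- 0.25
  n_norm <- 2 * (qnorm(0.975) + qnorm(0.8))^2 * 0.32^2 / delta^2
  expect_gte(res$n_per_group, n_norm)

  # independent oracle
  ref <- power.t.test(delta = delta, sd = 0.32, sig.level = 0.05, power = 0.8)
  expect_equal(res$n_per_group, ceiling(ref$n))
})

test_that("dropout inflation rounds up to even totals", {
  expect_equal(inflate_for_dropout(54, 0), 54L)
  expect_equal(inflate_for_dropout(53, 0), 54L)  # parity for 1:1 allocation
  for (n in c(10, 24, 54)) expect_equal(inflate_for_dropout(n, 0.5), 2L * n)
  expect_error(inflate_for_dropout(54, 1), "dropout")
})

test_that("Bonferroni adjustment over the outcome family", {
  adj <- bonferroni(0.028, family_size = 10)
  expect_equal(adj$p_adjusted, 0.28)
  expect_false(adj$significant)
  adj2 <- bonferroni(0.001, family_size = 10)
  expect_true(adj2$significant)
  expect_equal(bonferroni(c(0.2, 0.9), family_size = 2)$p_adjusted,
               c(0.4, 1))
  expect_equal(bonferroni(0.3, family_size = 1)$p_adjusted, 0.3)
})
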