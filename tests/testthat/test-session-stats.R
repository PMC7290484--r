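test_that("identical sessions give the null-favouring degenerate result", {
  x <- c(1.2, 0.4, -0.3, 0.8, 1.1, 0.2, 0.9)
  cmp <- paired_compare(x, x, measure = "mb_score")
  expect_true(cmp$degenerate)
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_two_sided, 1)
  expect_gt(cmp$bf01, 1)
})

test_that("the default-prior t Bayes factor matches an independent
           quadrature oracle", {
  for (case in list(c(0, 25), c(1.3, 25), c(-2.1, 12), c(0.38, 25))) {
    expect_equal(bf01_paired_t(case[1], case[2]),
                 oracle_bf01_t(case[1], case[2]),
                 tolerance = 1e-6)
  }
  # wider prior scale too
  expect_equal(bf01_paired_t(1.1, 20, r_scale = 1),
               oracle_bf01_t(1.1, 20, r = 1), tolerance = 1e-6)
})

test_that("BF01 decreases in |t|, exceeds 1 at t = 0, and is continuous", {
  ts <- seq(0, 4, by = 0.25)
  for (n in c(5, 25, 60)) {
    bfs <- sapply(ts, bf01_paired_t, n = n)
    expect_true(all(diff(bfs) < 0))
    expect_gt(bfs[1], 1)
    expect_equal(bf01_paired_t(1e-9, n), bf01_paired_t(0, n),
                 tolerance = 1e-6)
    expect_equal(bf01_paired_t(-2, n), bf01_paired_t(2, n),
                 tolerance = 1e-8)
  }
})

test_that("evidence categories follow the BF01 > 3 / > 1 thresholds", {
  expect_equal(evidence_category(6.30), "positive evidence for null")
  expect_equal(evidence_category(2.52), "anecdotal for null")
  expect_equal(evidence_category(1.0), "favors alternative")
  expect_equal(evidence_category(0.2), "favors alternative")
  expect_error(evidence_category(0))
})

test_that("paired_compare agrees with stats:: building blocks and gates
           normality", {
  set.seed(31)
  x <- rnorm(20); y <- x + rnorm(20, 0.2, 0.5)
  cmp <- paired_compare(x, y)
  tt <- t.test(x, y, paired = TRUE)
  expect_equal(cmp$t_statistic, unname(tt$statistic))
  expect_equal(cmp$p_two_sided, tt$p.value)
  expect_equal(cmp$dof, 19)
  expect_equal(cmp$shapiro_p, shapiro.test(x - y)$p.value)
  expect_equal(cmp$wilcoxon_p, wilcox.test(x, y, paired = TRUE)$p.value)
  expect_error(paired_compare(1:3, 1:4), "equal length")
  expect_error(paired_compare(1:2, 2:3), "at least 3")
})

test_that("signed-rank p-values match exact enumeration for small n", {
  set.seed(7)
  for (i in 1:8) {
    n <- sample(6:10, 1)
    d <- round(rnorm(n, 0.3, 1), 3)
    d <- d[d != 0]
    if (length(d) < 3) next
    p_pkg <- wilcox.test(d, mu = 0)$p.value
    expect_equal(p_pkg, oracle_wilcoxon_exact_p(d), tolerance = 1e-12)
    # the z approximation has the sign of the median shift
    z <- twostepr:::wilcoxon_signed_rank_z(d)
    expect_equal(sign(z), sign(sum(rank(abs(d))[d > 0]) -
                                 length(d) * (length(d) + 1) / 4))
  }
})

test_that("correlations report exact closed-form r and sensible BFs", {
  x <- c(1.0, 2.0, 3.0, 5.0, 8.0)
  y <- c(2.1, 1.9, 3.5, 4.0, 7.9)
  res <- correlate_with_covariate(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$pearson_r, r_hand, tolerance = 1e-12)
  expect_equal(res$kendall_tau, unname(cor.test(x, y,
                                                method = "kendall")$estimate))

  res_id <- correlate_with_covariate(1:10, 1:10 * 2)
  expect_equal(res_id$pearson_r, 1)
  expect_equal(res_id$kendall_tau, 1)
  expect_lt(res_id$bf01_correlation, 1)
  expect_error(correlate_with_covariate(rep(1, 6), 1:6), "constant")
})

test_that("independent draws mostly favour the null correlation", {
  set.seed(5)
  bf <- replicate(40, {
    res <- correlate_with_covariate(rnorm(25), rnorm(25))
    res$bf01_correlation
  })
  expect_gt(mean(bf > 3), 0.5)
})

test_that("symptom comparisons pick the documented test branch", {
  expect_equal(symptom_compare(c(1, 2, 0, 3), c(1, 2, 0, 3))$p_two_sided, 1)
  one <- symptom_compare(rep(0, 8), c(2, 3, 1, 4, 2, 5, 1, 2))
  expect_equal(one$branch, "one_sample")
  expect_lt(one$p_two_sided, 0.05)
  none <- symptom_compare(rep(0, 5), rep(0, 5))
  expect_equal(none$branch, "none")
  expect_true(is.na(none$p_two_sided))
  paired <- symptom_compare(c(0, 1, 2, 0, 1, 3), c(2, 4, 3, 1, 5, 6))
  expect_equal(paired$branch, "paired")
  expect_equal(paired$p_two_sided,
               suppressWarnings(wilcox.test(c(0, 1, 2, 0, 1, 3),
                                            c(2, 4, 3, 1, 5, 6),
                                            paired = TRUE))$p.value)
})

test_that("null difference vectors keep the paired t near its nominal
           size", {
  set.seed(99)
  rej <- replicate(400, {
    d <- rnorm(25)
    t.test(d)$p.value < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})
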