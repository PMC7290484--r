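#' Default-prior Bayes factor for a paired/one-sample t contrast
#'
#' Computes BF01 — the marginal likelihood of the observed t statistic
#' under the null divided by its marginal likelihood under the
#' alternative — where the alternative places a zero-centred Cauchy prior
#' (scale `r_scale`, default `1/sqrt(2)`) on the standardized effect size.
#' The alternative's marginal is obtained by integrating the noncentral t
#' density over the prior.
#'
#' @param t_statistic Observed t value.
#' @param n Number of pairs (degrees of freedom `n - 1`).
#' @param r_scale Cauchy prior scale on the standardized effect size.
#' @return BF01 (> 1 favours the null).
#' @export
#' @examples
#' bf01_paired_t(0, 25)
bf01_paired_t <- function(t_statistic, n, r_scale = 1 / sqrt(2)) {
  stopifnot(n >= 2, r_scale > 0, is.finite(t_statistic))
  df <- n - 1
  m0 <- dt(t_statistic, df)
  integrand <- function(delta) {
    suppressWarnings(dt(t_statistic, df, ncp = delta * sqrt(n))) *
      stats::dcauchy(delta, 0, r_scale)
  }
  m1 <- integrate(integrand, -Inf, Inf, rel.tol = 1e-9,
                  stop.on.error = FALSE)$value
  m0 / m1
}

#' Default-prior Bayes factor for a Pearson correlation
#'
#' Jeffreys's test for the presence of a correlation: a uniform prior on
#' the population correlation rho over `[-1, 1]` against the point null
#' rho = 0, using Jeffreys's approximation to the sampling density of the
#' observed correlation `r`. Reported in the null-favouring direction.
#'
#' @param r Observed Pearson correlation.
#' @param n Sample size (>= 4).
#' @return BF01 (> 1 favours the null).
#' @export
bf01_correlation <- function(r, n) {
  stopifnot(n >= 4, is.finite(r), abs(r) <= 1)
  integrand <- function(rho) {
    (1 - rho^2)^((n - 1) / 2) * (1 - rho * r)^(-(2 * n - 3) / 2)
  }
  bf10 <- integrate(integrand, -1, 1, rel.tol = 1e-9,
                    stop.on.error = FALSE)$value / 2
  1 / bf10
}

wilcoxon_signed_rank_z <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(NA_real_)
  rk <- rank(abs(d))
  v <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  if (sigma2 <= 0) return(NA_real_)
  (v - mu) / sqrt(sigma2)
}

#' Paired sober-vs-hungover comparison of one measure
#'
#' The study's inferential recipe for each task measure: a paired t test
#' on the per-subject differences, a Shapiro-Wilk check of those
#' differences, a Wilcoxon signed-rank test (always computed; flagged as
#' required when the normality check fails at p < 0.05), and a
#' default-prior Bayes factor BF01 for the paired contrast from
#' [bf01_paired_t()].
#'
#' @param x_sober,x_hungover Per-subject measurements, equal length,
#'   pairwise complete, n >= 3.
#' @param measure Label carried into the result.
#' @param r_scale Cauchy prior scale for the Bayes factor.
#' @return An object of class `paired_comparison` with fields `measure`,
#'   `n`, `mean_diff`, `t_statistic`, `dof`, `p_two_sided`, `shapiro_w`,
#'   `shapiro_p`, `normality_ok`, `wilcoxon_z`, `wilcoxon_p`, `bf01`,
#'   `evidence`, and `degenerate` (TRUE when the differences have zero
#'   variance, leaving t undefined).
#' @export
paired_compare <- function(x_sober, x_hungover, measure = "measure",
                           r_scale = 1 / sqrt(2)) {
  if (length(x_sober) != length(x_hungover))
    stop("paired vectors must have equal length")
  keep <- complete.cases(x_sober, x_hungover)
  x <- as.numeric(x_sober[keep])
  y <- as.numeric(x_hungover[keep])
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  d <- x - y

  out <- list(measure = measure, n = n, mean_diff = mean(d),
              dof = n - 1L, degenerate = FALSE)
  if (sd(d) == 0) {
    out$degenerate <- TRUE
    if (all(d == 0)) {
      # identical sessions: no effect, the data are maximal null evidence
      out$t_statistic <- 0
      out$p_two_sided <- 1
      out$bf01 <- bf01_paired_t(0, n, r_scale)
    } else {
      out$t_statistic <- NA_real_
      out$p_two_sided <- NA_real_
      out$bf01 <- NA_real_
    }
    out$shapiro_w <- NA_real_
    out$shapiro_p <- NA_real_
    out$normality_ok <- NA
    out$wilcoxon_z <- NA_real_
    out$wilcoxon_p <- NA_real_
  } else {
    tt <- t.test(x, y, paired = TRUE)
    sw <- shapiro.test(d)
    wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
    out$t_statistic <- unname(tt$statistic)
    out$p_two_sided <- tt$p.value
    out$shapiro_w <- unname(sw$statistic)
    out$shapiro_p <- sw$p.value
    out$normality_ok <- sw$p.value >= 0.05
    out$wilcoxon_z <- wilcoxon_signed_rank_z(d)
    out$wilcoxon_p <- wt$p.value
    out$bf01 <- bf01_paired_t(out$t_statistic, n, r_scale)
  }
  out$evidence <- if (is.na(out$bf01)) NA_character_ else
    evidence_category(out$bf01)
  class(out) <- "paired_comparison"
  out
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired comparison: %s (n = %d)\n", x$measure, x$n))
  if (isTRUE(x$degenerate))
    cat("  zero-variance differences; t test degenerate\n")
  cat(sprintf("  t(%d) = %.3f, p = %.3f; Shapiro-Wilk p = %.3f%s\n",
              x$dof, x$t_statistic, x$p_two_sided, x$shapiro_p,
              if (isFALSE(x$normality_ok)) " (non-normal)" else ""))
  cat(sprintf("  Wilcoxon Z = %.3f, p = %.3f\n", x$wilcoxon_z, x$wilcoxon_p))
  cat(sprintf("  BF01 = %.2f (%s)\n", x$bf01, x$evidence))
  invisible(x)
}

#' Verbal category for a null-favouring Bayes factor
#'
#' BF01 above three counts as positive evidence for the null; values in
#' `(1, 3]` as anecdotal evidence for the null; values at or below one
#' favour the alternative.
#'
#' @param bf01 A positive Bayes factor in the null-favouring direction.
#' @return A character label.
#' @export
evidence_category <- function(bf01) {
  stopifnot(bf01 > 0)
  if (bf01 > 3) "positive evidence for null"
  else if (bf01 > 1) "anecdotal for null"
  else "favors alternative"
}

#' Correlate a task measure with a covariate
#'
#' Pearson correlation with two-sided p, Kendall's tau with two-sided p,
#' and the default-prior correlation Bayes factor of [bf01_correlation()],
#' as used for the alcohol-use (AUDIT) add-on analyses.
#'
#' @param measure,covariate Per-subject numeric vectors (n >= 4 complete
#'   pairs).
#' @param label Measure label carried into the result.
#' @return An object of class `correlation_result` with `pearson_r`,
#'   `pearson_p`, `kendall_tau`, `kendall_p`, `bf01_correlation`, `n`.
#' @export
correlate_with_covariate <- function(measure, covariate, label = "measure") {
  keep <- complete.cases(measure, covariate)
  x <- as.numeric(measure[keep])
  y <- as.numeric(covariate[keep])
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant input: correlation undefined")
  pe <- cor.test(x, y, method = "pearson")
  ke <- suppressWarnings(cor.test(x, y, method = "kendall"))
  out <- list(
    measure = label, n = n,
    pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
    kendall_tau = unname(ke$estimate), kendall_p = ke$p.value,
    bf01_correlation = bf01_correlation(unname(pe$estimate), n))
  class(out) <- "correlation_result"
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "Correlation (%s, n = %d): r = %.3f (p = %.3f), tau = %.3f (p = %.3f), BF01 = %.2f\n",
    x$measure, x$n, x$pearson_r, x$pearson_p, x$kendall_tau, x$kendall_p,
    x$bf01_correlation))
  invisible(x)
}

#' Compare symptom ratings between sessions
#'
#' Likert symptom ratings (0-10) are compared with a paired Wilcoxon
#' signed-rank test when the sober ratings vary; when every sober rating
#' is zero, the hungover ratings are tested against zero with a one-sample
#' Wilcoxon signed-rank test. All-zero data in both sessions admit no
#' test. P values are two-sided and uncorrected.
#'
#' @param sober_ratings,hungover_ratings Paired integer vectors.
#' @param symptom Label carried into the result.
#' @return A list with `symptom`, `branch`
#'   (`"paired"`/`"one_sample"`/`"none"`), `statistic`, `p_two_sided`, and
#'   `n`.
#' @export
symptom_compare <- function(sober_ratings, hungover_ratings,
                            symptom = "symptom") {
  if (length(sober_ratings) != length(hungover_ratings))
    stop("paired vectors must have equal length")
  s <- as.numeric(sober_ratings)
  h <- as.numeric(hungover_ratings)
  n <- length(s)
  if (all(s == 0) && all(h == 0)) {
    return(list(symptom = symptom, branch = "none",
                statistic = NA_real_, p_two_sided = NA_real_, n = n))
  }
  if (all(s == 0)) {
    wt <- suppressWarnings(wilcox.test(h, mu = 0))
    return(list(symptom = symptom, branch = "one_sample",
                statistic = unname(wt$statistic),
                p_two_sided = wt$p.value, n = n))
  }
  if (all(s == h)) {
    # no nonzero signed ranks: the test carries no information
    return(list(symptom = symptom, branch = "paired",
                statistic = 0, p_two_sided = 1, n = n))
  }
  wt <- suppressWarnings(wilcox.test(s, h, paired = TRUE))
  list(symptom = symptom, branch = "paired",
       statistic = unname(wt$statistic), p_two_sided = wt$p.value, n = n)
}

#' Write a table of paired comparisons as CSV
#'
#' @param comparisons List of `paired_comparison` objects.
#' @param path Optional output path.
#' @return A data frame, one row per measure.
#' @export
comparison_table <- function(comparisons, path = NULL) {
  rows <- lapply(comparisons, function(p) {
    data.frame(measure = p$measure, n = p$n, mean_diff = p$mean_diff,
               t = p$t_statistic, dof = p$dof, p = p$p_two_sided,
               shapiro_p = p$shapiro_p, wilcoxon_z = p$wilcoxon_z,
               wilcoxon_p = p$wilcoxon_p, bf01 = p$bf01,
               evidence = p$evidence, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
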