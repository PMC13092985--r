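#' Hypothesis-testing toolkit
#'
#' The statistical procedures used throughout the survey: two-sample
#' proportion Z-test, normality-gated two-group comparison (Shapiro-Wilk
#' gate at alpha, then Mann-Whitney U or pooled-variance Student t), Welch
#' t, one-way ANOVA, Cohen's d, and tail-probability helpers.  Every test
#' returns a uniform `test_result` row (method, statistic, df, p-value,
#' effect size, group sizes).
#'
#' @name hypothesis_stats
NULL

test_result <- function(method, statistic, df = NA_real_, p_value,
                        effect_size = NA_real_, n = NA_integer_) {
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value),
                 effect_size = unname(effect_size), n = n),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, df = %s, p = %.4g%s\n", x$method,
              x$statistic, paste(signif(x$df, 4), collapse = ","), x$p_value,
              if (!is.na(x$effect_size))
                sprintf(", effect = %.3g", x$effect_size) else ""))
  invisible(x)
}

#' Collect test results into a uniform table
#'
#' @param ... `test_result` objects (or one list of them).
#' @return Data frame with columns method, statistic, df, p_value,
#'   effect_size, n_per_group.
#' @export
test_result_table <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !inherits(xs[[1]], "test_result"))
    xs <- xs[[1]]
  do.call(rbind, lapply(xs, function(x)
    data.frame(method = x$method, statistic = x$statistic,
               df = paste(signif(x$df, 6), collapse = ","),
               p_value = x$p_value, effect_size = x$effect_size,
               n_per_group = paste(x$n, collapse = ","))))
}

#' Two-sample proportion Z-test
#'
#' Pooled-proportion Z statistic
#' \eqn{z = (k_1/n_1 - k_2/n_2) / \sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}}
#' with \eqn{\hat p = (k_1+k_2)/(n_1+n_2)}, two-sided p from the standard
#' normal.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return A `test_result` (`effect_size` is the difference in proportions).
#' @export
proportion_z_test <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p_hat <- (k1 + k2) / (n1 + n2)
  if (p_hat <= 0 || p_hat >= 1)
    stop("degenerate pooled proportion (all successes or all failures)",
         call. = FALSE)
  diff <- k1 / n1 - k2 / n2
  z <- diff / sqrt(p_hat * (1 - p_hat) * (1 / n1 + 1 / n2))
  test_result("proportion_z", z, df = NA_real_,
              p_value = 2 * stats::pnorm(-abs(z)),
              effect_size = diff, n = c(n1, n2))
}

#' Two-sided Student/Welch t tail probability
#'
#' Supports non-integer degrees of freedom (Welch-Satterthwaite).
#'
#' @param t Test statistic.
#' @param df Degrees of freedom (may be fractional).
#' @return Two-sided p-value.
#' @export
t_two_sided_p <- function(t, df) 2 * stats::pt(-abs(t), df)

#' Upper-tail F probability
#'
#' @param f F statistic.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return `P(F_{df1,df2} > f)`.
#' @export
f_upper_p <- function(f, df1, df2) stats::pf(f, df1, df2, lower.tail = FALSE)

#' Cohen's d with pooled standard deviation
#'
#' @param a,b Numeric vectors.
#' @return \eqn{(\bar a - \bar b)/s_p} with the pooled SD; errors on zero
#'   pooled variance.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stop("zero pooled variance", call. = FALSE)
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Welch's two-sample t-test
#'
#' @param a,b Numeric vectors.
#' @return A `test_result` with the Welch statistic, Welch-Satterthwaite
#'   df, two-sided p, and Cohen's d as the effect size.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero variance in both groups", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = FALSE)
  test_result("welch_t", ht$statistic, df = ht$parameter,
              p_value = ht$p.value, effect_size = cohens_d(a, b),
              n = c(length(a), length(b)))
}

#' Pooled-variance (independent) Student t-test
#'
#' @param a,b Numeric vectors.
#' @return A `test_result`.
#' @export
student_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  ht <- stats::t.test(a, b, var.equal = TRUE)
  test_result("student_t", ht$statistic, df = ht$parameter,
              p_value = ht$p.value, effect_size = cohens_d(a, b),
              n = c(length(a), length(b)))
}

#' Mann-Whitney U test (normal approximation)
#'
#' Wilcoxon rank-sum with continuity and tie corrections; the statistic
#' reported is U for the first group.
#'
#' @param a,b Numeric vectors.
#' @return A `test_result`.
#' @export
mann_whitney_u <- function(a, b) {
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  test_result("mann_whitney_u", ht$statistic, df = NA_real_,
              p_value = ht$p.value, n = c(length(a), length(b)))
}

#' Normality-gated two-group comparison
#'
#' Applies the Shapiro-Wilk test to each group; when either group deviates
#' from normality at `alpha` the groups are compared with a Mann-Whitney U
#' test, otherwise with the pooled-variance Student t-test.  The method
#' label records which branch ran.
#'
#' @param a,b Numeric vectors (each of length >= 3, the Shapiro-Wilk
#'   minimum).
#' @param alpha Gate significance level (default 0.05).
#' @return A `test_result` whose method is `"mann_whitney_u"` or
#'   `"student_t"`, with attribute `shapiro_p` carrying the two gate
#'   p-values.
#' @export
gated_compare <- function(a, b, alpha = 0.05) {
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs >= 3 values for the Shapiro-Wilk gate",
         call. = FALSE)
  sw <- function(x) {
    if (length(unique(x)) == 1) return(0)  # constant: clearly non-normal
    stats::shapiro.test(x)$p.value
  }
  p_a <- sw(a); p_b <- sw(b)
  res <- if (p_a < alpha || p_b < alpha) mann_whitney_u(a, b)
         else student_t(a, b)
  attr(res, "shapiro_p") <- c(p_a, p_b)
  res
}

#' One-way analysis of variance
#'
#' Classical equal-variance F test across k groups, F with df (k-1, N-k).
#'
#' @param groups List of numeric vectors.
#' @return A `test_result`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  test_result("one_way_anova", ht$statistic,
              df = unname(ht$parameter), p_value = ht$p.value,
              n = lengths(groups))
}

#' Pearson correlation with two-sided p-value
#'
#' Pearson r with the t-transform p-value
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} against the t distribution
#' (as computed by [stats::cor.test()]).
#'
#' @param x,y Numeric vectors.
#' @return List with `r`, `n`, `p_value`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), n = length(x), p_value = ht$p.value)
}
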