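test_that("proportion Z-test matches its closed form and symmetries", {
  eq <- proportion_z_test(50, 100, 50, 100)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  # independent normal-tail computation of the same statistic
  z <- proportion_z_test(60, 100, 40, 100)
  p_hat <- 100 / 200
  z_ref <- (0.6 - 0.4) / sqrt(p_hat * (1 - p_hat) * (2 / 100))
  expect_equal(z$statistic, z_ref)
  expect_equal(z$p_value, 2 * (1 - stats::pnorm(abs(z_ref))))

  sw <- proportion_z_test(40, 100, 60, 100)
  expect_equal(sw$statistic, -z$statistic)
  expect_equal(sw$p_value, z$p_value)

  expect_error(proportion_z_test(0, 50, 0, 80), "degenerate")
  expect_error(proportion_z_test(50, 50, 80, 80), "degenerate")
})

test_that("t and F tail helpers reproduce the published readthrough statistics", {
  # reporter quantification: unpinned 4-bp stem variant vs controls
  expect_equal(signif(t_two_sided_p(6.76, 2.86), 2), 0.0077)
  expect_equal(signif(t_two_sided_p(6.57, 2.97), 2), 0.0074)
  expect_equal(signif(f_upper_p(24.72, 2, 6), 2), 0.0013)
  # df1 = 2 closed form: P = (1 + 2F/d2)^(-d2/2)
  for (f in c(0.5, 3, 24.72)) for (d2 in c(4, 6, 11))
    expect_equal(f_upper_p(f, 2, d2), (1 + 2 * f / d2)^(-d2 / 2),
                 tolerance = 1e-10)
  # t tail converges to the normal tail at large df
  expect_lt(abs(t_two_sided_p(1.7, 1e6) - 2 * stats::pnorm(-1.7)), 1e-6)
})

test_that("Welch, Student, ANOVA and Cohen's d agree with manual formulas", {
  set.seed(5)
  a <- rnorm(8, 10); b <- rnorm(12, 12, 2)
  w <- welch_t(a, b)
  se <- sqrt(var(a) / 8 + var(b) / 12)
  expect_equal(w$statistic, (mean(a) - mean(b)) / se)
  df_ws <- se^4 / ((var(a) / 8)^2 / 7 + (var(b) / 12)^2 / 11)
  expect_equal(w$df, df_ws)
  expect_equal(w$p_value, t_two_sided_p(w$statistic, w$df))

  sp <- sqrt((7 * var(a) + 11 * var(b)) / 18)
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp)
  expect_equal(cohens_d(a, a), 0)
  expect_error(cohens_d(rep(1, 4), rep(2, 4)), "zero pooled variance")

  groups <- list(rnorm(6, 0), rnorm(6, 1), rnorm(6, 3))
  an <- one_way_anova(groups)
  gm <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  f_ref <- (ssb / 2) / (ssw / 15)
  expect_equal(an$statistic, f_ref)
  expect_equal(an$df, c(2, 15))
  expect_equal(an$p_value, f_upper_p(f_ref, 2, 15))
})

test_that("the normality gate selects the right branch", {
  set.seed(42)
  # clearly non-normal group at n = 30: U branch in nearly every replicate
  u_picked <- vapply(1:100, function(k) {
    a <- rlnorm(30, sdlog = 1.5)
    b <- rnorm(30, mean(a))
    gated_compare(a, b)$method
  }, "")
  expect_gte(mean(u_picked == "mann_whitney_u"), 0.95)

  # two normal groups: t branch, p exactly the pooled-variance t p
  a <- rnorm(15); b <- rnorm(15)
  g <- gated_compare(a, b)
  expect_equal(g$method, "student_t")
  expect_equal(g$p_value, student_t(a, b)$p_value)

  # identical groups under the U test: ties handled, p = 1
  x <- c(1, 2, 3, 4, 5)
  expect_equal(mann_whitney_u(x, x)$p_value, 1)
  expect_error(gated_compare(c(1, 2), c(1, 2, 3)), ">= 3")
})

test_that("two-sided p-values are swap-invariant and in [0, 1]", {
  set.seed(6)
  for (k in 1:25) {
    a <- rnorm(sample(5:12, 1)); b <- rnorm(sample(5:12, 1), 0.5)
    for (fn in list(welch_t, student_t, mann_whitney_u)) {
      r1 <- fn(a, b); r2 <- fn(b, a)
      expect_equal(r1$p_value, r2$p_value)
      expect_gte(r1$p_value, 0); expect_lte(r1$p_value, 1)
    }
  }
})

test_that("Pearson p matches a permutation null on small samples", {
  set.seed(9)
  x <- rnorm(10); y <- x + rnorm(10, sd = 2)
  ct <- pearson_cor(x, y)
  r_obs <- abs(ct$r)
  perm <- replicate(4000, abs(cor(x, sample(y))))
  expect_lt(abs(ct$p_value - mean(perm >= r_obs)), 0.05)
  expect_error(pearson_cor(x, rep(1, 10)), "zero variance")
})
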