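test_that("pearson_regression reproduces hand-computed fixtures", {
  x <- c(1, 2, 3, 4)
  st <- pearson_regression(x, 2 * x + 1)
  expect_equal(st$pearson_r, 1)
  expect_equal(st$r_squared, 1)
  expect_equal(st$slope, 2)
  expect_equal(st$intercept, 1)
  # hand computation: cov = 1, var_x = var_y = 5/3, r = 0.6
  st2 <- pearson_regression(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(st2$pearson_r, 0.6, tolerance = 1e-12)
  expect_equal(st2$r_squared, 0.36, tolerance = 1e-12)
  expect_equal(st2$n, 4)
  # R^2 = r^2 exactly, and the lm fit agrees with the closed-form slope
  set.seed(31)
  for (k in 1:10) {
    a <- rnorm(20); b <- 0.5 * a + rnorm(20)
    st3 <- pearson_regression(a, b)
    expect_identical(st3$r_squared, st3$pearson_r^2)
    expect_equal(st3$slope, cov(a, b) / var(a), tolerance = 1e-12)
    # invariance under positive affine rescaling
    st4 <- pearson_regression(3 * a + 7, 0.2 * b - 1)
    expect_equal(st4$pearson_r, st3$pearson_r, tolerance = 1e-12)
  }
  expect_error(pearson_regression(1:5, rep(1, 5)), "zero variance")
  expect_error(pearson_regression(1:2, 1:2), "at least 3")
  expect_error(pearson_regression(1:4, 1:5), "equal length")
})

test_that("squaring a 3-dp Pearson r is consistent with a printed 3-dp R^2", {
  # worst-case 3-dp rounding of both r and R^2 allows |r^2 - R2| up to
  # 2*|r|*5e-4 + 5e-4 < 0.0015
  r <- 0.768
  expect_lt(abs(r^2 - 0.590), 0.0015)
  expect_equal(round(r^2, 3), 0.590)
})

test_that("ks_normality is calibrated under the null and powered under a gross alternative", {
  ok <- 0
  for (k in 1:100) {
    set.seed(1000 + k)
    if (ks_normality(rnorm(10000))$p_value > 0.05) ok <- ok + 1
  }
  expect_gte(ok, 95)
  set.seed(7)
  bimodal <- c(rnorm(100, -5), rnorm(100, 5))
  expect_lt(ks_normality(bimodal)$p_value, 0.01)
  expect_error(ks_normality(rep(1, 10)), "zero variance")
  expect_error(ks_normality(rnorm(4)), "at least 5")
})

test_that("welch_two_sample matches hand computation and conventions", {
  x <- c(1, 2, 3, 4, 5)
  w0 <- welch_two_sample(x, x)
  expect_equal(w0$t, 0)
  expect_equal(w0$p_value, 1)
  # textbook fixture, hand-computed Welch statistic
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1,
         19.6, 19.0, 21.7, 21.4)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9,
         22.1, 22.9, 30.5, 24.1)
  mx <- mean(a); my <- mean(b)
  se2 <- var(a) / 15 + var(b) / 15
  t_hand <- (mx - my) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 15)^2 / 14 + (var(b) / 15)^2 / 14)
  w <- welch_two_sample(a, b)
  expect_equal(w$t, t_hand, tolerance = 1e-12)
  expect_equal(w$df, df_hand, tolerance = 1e-9)
  # well-separated groups are detected
  set.seed(9)
  g1 <- rnorm(50, 0, 1); g2 <- rnorm(50, 3, 1)
  expect_lt(welch_two_sample(g1, g2)$p_value, 0.001)
  # degenerate conventions
  expect_equal(welch_two_sample(rep(2, 5), rep(2, 5))$p_value, 1)
  expect_error(welch_two_sample(rep(1, 5), rep(2, 5)), "undefined")
  expect_error(welch_two_sample(1, 1:3), "at least 2")
})

test_that("welch type-I error is close to nominal", {
  set.seed(20200519)
  n_sim <- 5000
  rejections <- 0
  for (k in seq_len(n_sim)) {
    if (welch_two_sample(rnorm(15), rnorm(15))$p_value < 0.05) {
      rejections <- rejections + 1
    }
  }
  expect_lt(abs(rejections / n_sim - 0.05), 0.01)
})

test_that("cohort_summary reports moments, correlations and the group split", {
  set.seed(41)
  n <- 30
  ps <- pmax(0, rnorm(n, 0.10, 0.04))
  pi_ <- pmax(0, 0.6 * ps + rnorm(n, 0.02, 0.02))
  as_ <- pmax(0, rnorm(n, 0.08, 0.04))
  ai <- pmax(0, rnorm(n, 0.05, 0.02))
  h <- rnorm(n, 32, 4); r <- rnorm(n, 25, 4.5)
  rec <- data.frame(asucr = as_, aiucr = ai, psucr = ps, piucr = pi_,
                    tucr = as_ + ai + ps + pi_, height_mm = h,
                    ap_diameter_mm = r, volume_proxy_mm3 = h * r^2)
  s <- cohort_summary(rec, group_split_tucr = 0.3)
  expect_equal(s$variables$mean[s$variables$variable == "tucr"],
               mean(rec$tucr))
  expect_equal(s$groups$n_above + s$groups$n_below, n)
  expect_equal(s$groups$n_above, sum(rec$tucr > 0.3))
  # every correlation cell satisfies R^2 = r^2
  ok <- !is.na(s$correlations$pearson_r)
  expect_identical(s$correlations$r_squared[ok],
                   s$correlations$pearson_r[ok]^2)
  # flags match the p-values
  flagged <- s$correlations$flag == "**"
  expect_true(all(s$correlations$p_value[flagged & ok] < 0.01))
  expect_match(s$footer, "no multiple-testing adjustment")
  # identical hips: correlations reported as n/a, no crash
  rec0 <- rec[rep(1, 5), ]
  s0 <- cohort_summary(rec0)
  expect_true(all(s0$correlations$flag == "n/a"))
  expect_true(all(is.na(s0$correlations$pearson_r)))
  expect_equal(s0$variables$sd, rep(0, 8))
})
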