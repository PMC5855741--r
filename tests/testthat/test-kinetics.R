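test_that("fpc_profile passes through its anchors", {
  a <- list(initial = 9.7, peak = 15.3, t_peak = 16, final = 8.7)
  v <- fpc_profile(c(0, 16, 75), a)
  expect_equal(v, c(9.7, 15.3, 8.7))
  grid <- fpc_profile(0:75, a)
  expect_equal(which.max(grid) - 1, 16)
  expect_true(all(grid <= 15.3 + 1e-9))
  # flat profile reproduces the constant control level
  expect_equal(fpc_profile(0:75, list(initial = 1.5, peak = 1.5, t_peak = 37,
                                      final = 1.5)), rep(1.5, 76))
})

test_that("build_kinetics: means, SDs and the smoother", {
  # single nucleus: mean is its series, SD = 0
  one <- build_kinetics(c(1, 2, 3))
  expect_equal(one$mean, c(1, 2, 3))
  expect_equal(one$sd, c(0, 0, 0))
  expect_equal(one$n, rep(1L, 3))

  # two constant series {2} and {4}: mean 3, sample SD sqrt(2)
  two <- build_kinetics(list(rep(2, 5), rep(4, 5)))
  expect_equal(two$mean, rep(3, 5))
  expect_equal(two$sd, rep(sqrt(2), 5))

  # smoother shifts a resolved noiseless peak by at most 1 minute
  prof <- 2 + 6 * exp(-((0:75) - 30)^2 / (2 * 12^2))
  kt <- build_kinetics(prof)
  expect_lte(abs(kt$minute[which.max(kt$fitted)] - 30), 1)
})

test_that("summarize_kinetics reproduces the ratio definitions", {
  ctrl <- anchor_kinetics("control")
  xr <- anchor_kinetics("xray")
  s <- summarize_kinetics(xr, ctrl)
  expect_equal(s$initial, 9.7)
  expect_equal(s$highest, 15.3)
  expect_equal(s$t_peak, 16)
  expect_equal(s$final, 8.7)
  expect_equal(s$max_increase, 15.3 / 1.5)
  expect_equal(s$max_reduction, 15.3 / 8.7)
  expect_output(print(s), "10.2")

  # constant series: max_reduction exactly 1
  const <- anchor_kinetics(list(initial = 2, peak = 2, t_peak = 10, final = 2))
  expect_equal(summarize_kinetics(const, ctrl)$max_reduction, 1)

  zero <- anchor_kinetics(list(initial = 0, peak = 0, t_peak = 10, final = 0))
  expect_error(summarize_kinetics(xr, zero), "control")
})

test_that("expected_mixed is an additive, linear, idempotent half-sum", {
  al <- anchor_kinetics("alpha")
  xr <- anchor_kinetics("xray")
  e <- expected_mixed(al, xr)
  expect_equal(e$fitted, (al$fitted + xr$fitted) / 2)
  # idempotence and linearity
  expect_equal(expected_mixed(al, al)$fitted, al$fitted)
  al3 <- al; al3$fitted <- 3 * al$fitted
  xr3 <- xr; xr3$fitted <- 3 * xr$fitted
  expect_equal(expected_mixed(al3, xr3)$fitted, 3 * e$fitted)
  expect_error(expected_mixed(al, anchor_kinetics("xray", minutes = 0:40)),
               "grid")
})

test_that("relative_to_control and fading fit", {
  ctrl <- seq(100, 80, length.out = 5)
  expect_equal(relative_to_control(ctrl, ctrl)$ratio, rep(1, 5))
  expect_equal(relative_to_control(2 * ctrl, ctrl)$ratio, rep(2, 5))
  expect_error(relative_to_control(ctrl, c(ctrl[-5], 0)), "control")
  rr <- relative_to_control(2 * ctrl, ctrl, treated_sem = rep(1, 5),
                            control_sem = rep(1, 5))
  expect_equal(rr$sem, 2 * sqrt((1 / (2 * ctrl))^2 + (1 / ctrl)^2))

  # exact published line: 25% loss, 104.6 AU at minute 75
  slope <- (139.3 - 104.6) / 75
  ff <- fit_control_fading(139.3 - slope * (0:75), 0:75)
  expect_equal(ff$intercept - ff$slope * 75, 104.6, tolerance = 1e-9)
  expect_equal(round(ff$percent_loss), 25)
  expect_equal(fit_control_fading(rep(100, 10), 0:9)$percent_loss, 0)

  # noisy line: slope recovered within 2 SE
  set.seed(42)
  y <- 139.3 - 0.4627 * (0:75) + rnorm(76, 0, 3)
  fn <- fit_control_fading(y, 0:75)
  se <- summary(fn$fit)$coefficients[2, 2]
  expect_lte(abs(fn$slope - 0.4627), 2 * se)
})

test_that("coefficient of variation: arithmetic, window and invariance", {
  expect_equal(coefficient_of_variation(rep(5, 10), window = NULL), 0)
  expect_equal(coefficient_of_variation(c(1, 3), window = NULL),
               sqrt(2) / 2)
  x <- c(10, rnorm(75, 5, 1))  # minute 0 outside the default 1..75 window
  expect_equal(coefficient_of_variation(x), stats::sd(x[-1]) / mean(x[-1]))
  expect_equal(coefficient_of_variation(3.7 * x),
               coefficient_of_variation(x))
  expect_error(coefficient_of_variation(5, window = NULL), "2 points")
  expect_error(coefficient_of_variation(c(-1, 1), window = NULL), "zero")
})

test_that("kde_intensity is a normalised Gaussian kernel estimate", {
  # a single point gives the kernel itself
  # stats::density bins the data before convolving, so the single-point
  # estimate matches the kernel to ~1%, not to machine precision
  k1 <- kde_intensity(0.7, h = 0.1)
  expect_equal(k1$density, stats::dnorm(k1$x, 0.7, 0.1), tolerance = 0.02)
  expect_lt(abs(k1$x[which.max(k1$density)] - 0.7), 0.01)
  expect_lte(abs(attr(k1, "area") - 1), 0.01)

  # symmetric sample: density symmetric about the midpoint
  k2 <- kde_intensity(c(-1, 1), h = 0.5)
  expect_equal(k2$density, rev(k2$density), tolerance = 1e-9)

  # integrated squared error vs the true density shrinks with n
  ise <- function(n, seed) {
    set.seed(seed)
    k <- kde_intensity(stats::rnorm(n))
    sum(diff(k$x) * ((k$density - stats::dnorm(k$x))^2)[-1])
  }
  expect_lt(ise(5000, 1), ise(100, 1))

  expect_error(kde_intensity(c(1, 2), h = 0), "bandwidth")
  expect_error(kde_intensity(1), "n >= 2")
})

test_that("ANOVA and chi-square comparisons match textbook computation", {
  # identical groups: F = 0, p = 1
  v0 <- rep(c(1, 2, 3), 3)
  g0 <- rep(c("a", "b", "c"), each = 3)
  r0 <- compare_conditions(v0, g0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_false(r0$significant)

  # 3 groups, n = 25: F matches the hand sum-of-squares computation
  set.seed(5)
  g <- rep(c("a", "b", "c"), each = 25)
  v <- stats::rnorm(75, rep(c(0, 0.5, 1), each = 25),
                    rep(c(1, 1.2, 0.8), each = 25))
  r <- compare_conditions(v, g)
  gm <- tapply(v, g, mean)
  ssb <- sum(25 * (gm - mean(v))^2)
  ssw <- sum((v - gm[g])^2)
  expect_equal(r$statistic, (ssb / 2) / (ssw / 72), tolerance = 1e-10)
  expect_equal(r$df, c(2, 72))

  expect_error(compare_conditions(1:6, rep("a", 6)), "2 groups")
  expect_error(compare_conditions(1:3, c("a", "a", "b")), "at least 2 values")

  # balanced 2x2 table: chi-square 0
  r22 <- compare_counts(matrix(10, 2, 2))
  expect_equal(r22$statistic, 0)
  expect_false(r22$significant)
  expect_error(compare_counts(matrix(1, 3, 2)), "2 x 2")
  expect_error(compare_counts(matrix(c(-1, 1, 1, 1), 2, 2)), "non-negative")
})
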