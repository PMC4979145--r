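make_traits <- function(n = 60, seed = 1) {
  set.seed(seed)
  data.frame(bird_id = sprintf("b%03d", seq_len(n)),
             sex = rep(c("M", "F"), length.out = n),
             pen = rep(1:6, length.out = n),
             mmbw = rnorm(n, 220, 10),
             adg = rnorm(n, 28, 2),
             adfi = NA_real_, stringsAsFactors = FALSE)
}

test_that("an exactly linear intake model gives zero RFI and exact coefficients", {
  tr <- make_traits(30)
  tr$adfi <- 10 + 0.5 * tr$mmbw + 1.2 * tr$adg
  kf <- fit_koch_rfi(tr)
  expect_equal(unname(coef(kf)), c(10, 0.5, 1.2), tolerance = 1e-9)
  expect_lt(max(abs(residuals(kf))), 1e-9)
})

test_that("RFI is mean-zero and orthogonal to both regressors", {
  tr <- make_traits(200, seed = 7)
  set.seed(8)
  tr$adfi <- 16 + 0.25 * tr$mmbw + 1.2 * tr$adg + rnorm(200, 0, 8)
  kf <- fit_koch_rfi(tr)
  expect_lt(abs(mean(kf$rfi)), 1e-9)
  expect_lt(abs(cor(kf$rfi, tr$mmbw)), 1e-10)
  expect_lt(abs(cor(kf$rfi, tr$adg)), 1e-10)
})

test_that("Koch residuals match the normal-equation oracle on a toy table", {
  tr <- data.frame(bird_id = letters[1:6],
                   mmbw = c(210, 215, 220, 225, 230, 235),
                   adg = c(25, 29, 26, 30, 27, 31),
                   adfi = c(98, 112, 101, 118, 103, 121))
  kf <- fit_koch_rfi(tr)
  X <- cbind(1, tr$mmbw, tr$adg)
  b <- ols_oracle(X, tr$adfi)
  expect_equal(kf$rfi, drop(tr$adfi - X %*% b), tolerance = 1e-9)
})

test_that("collinear regressors are rejected", {
  tr <- make_traits(10)
  tr$adg <- tr$mmbw * 2
  tr$adfi <- rnorm(10, 100, 5)
  expect_error(fit_koch_rfi(tr), "collinear")
})

test_that("fixed-effect testing adjusts only significant factors", {
  # equal pen means: F = 0, p = 1, no adjustment
  rfi <- rep(c(-1, 0, 1), times = 6)
  pen <- rep(1:6, each = 3)
  sex <- rep(c("M", "F"), 9)
  res <- test_fixed_effects_and_adjust(rfi, sex, pen)
  expect_equal(res$p_pen, 1)
  expect_identical(res$rfi_adjusted, rfi)

  # injected pen effect, no sex effect
  set.seed(21)
  n <- 300
  sex <- rep(c("M", "F"), length.out = n)
  pen <- integer(n)
  pen[sex == "M"] <- rep(1:3, length.out = n / 2)
  pen[sex == "F"] <- rep(4:6, length.out = n / 2)
  rfi <- rnorm(n) + c(0, 3, 0, 0, 3, 0)[pen]
  res <- test_fixed_effects_and_adjust(rfi, sex, pen)
  expect_lt(res$p_pen, 0.01)
  expect_gt(res$p_sex, 0.1)
  expect_identical(res$adjusted_for, "pen")
  pen_means <- tapply(res$rfi_adjusted, pen, mean)
  expect_lt(max(abs(pen_means - mean(pen_means))), 1e-9)

  # idempotence
  res2 <- test_fixed_effects_and_adjust(res$rfi_adjusted, sex, pen)
  if (length(res2$adjusted_for) == 0)
    expect_equal(res2$rfi_adjusted, res$rfi_adjusted, tolerance = 1e-12)
})

test_that("the one-way F-test matches a hand-computed ANOVA", {
  y <- c(1, 2, 3, 3, 4, 5)
  g <- rep(1:2, each = 3)
  m1 <- mean(y[1:3]); m2 <- mean(y[4:6]); mg <- mean(y)
  ssb <- 3 * (m1 - mg)^2 + 3 * (m2 - mg)^2
  ssw <- sum((y[1:3] - m1)^2) + sum((y[4:6] - m2)^2)
  f_hand <- (ssb / 1) / (ssw / 4)
  p_hand <- pf(f_hand, 1, 4, lower.tail = FALSE)
  res <- test_fixed_effects_and_adjust(y, rep(c("M", "F"), 3), g)
  expect_equal(res$p_pen, p_hand, tolerance = 1e-12)
})

test_that("Anderson-Darling test behaves across known regimes", {
  # perfect normal scores
  x <- qnorm((1:100 - 0.5) / 100)
  expect_gt(anderson_darling_test(x)$p_value, 0.05)

  # fixed sample against the nortest implementation (independent oracle)
  skip_if_not_installed("nortest")
  set.seed(13)
  y <- rnorm(10, 5, 2)
  mine <- anderson_darling_test(y)
  ref <- nortest::ad.test(y)
  expect_equal(mine$A2, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)

  # strongly right-skewed sample is rejected
  z <- exp(qnorm((1:426 - 0.5) / 426))
  expect_lt(anderson_darling_test(z)$p_value, 0.01)

  expect_error(anderson_darling_test(rep(1, 20)), "zero variance")
  expect_error(anderson_darling_test(rnorm(5)), "n >= 8")
})

test_that("Johnson transformation is monotone and improves normality", {
  set.seed(31)
  x <- exp(rnorm(426, 0, 0.8))
  jt <- johnson_transform(x)
  expect_gt(jt$ad_after, jt$ad_before)
  # rank preservation
  o <- order(x)
  expect_true(all(diff(jt$z[o]) > 0))
  # invertible on the sample range: transform reproduces z
  expect_equal(jt$transform(x), jt$z, tolerance = 1e-12)

  # already-normal scores stay acceptable
  xn <- qnorm((1:100 - 0.5) / 100)
  jtn <- johnson_transform(xn)
  expect_gt(anderson_darling_test(jtn$z)$p_value, 0.05)
})

test_that("divergent-tail contrast has correct structure and statistics", {
  set.seed(17)
  n <- 100
  tr <- data.frame(bird_id = sprintf("b%03d", 1:n),
                   rfi = rnorm(n), adfi = rnorm(n, 105, 10),
                   adg = rnorm(n, 28, 2), mbw = rnorm(n, 1330, 60),
                   fcr = rnorm(n, 3.8, 0.4))
  ct <- divergent_group_contrast(tr, fraction = 0.10)
  expect_equal(length(ct$low_ids), 10)
  rfi_row <- ct$table[ct$table$trait == "rfi", ]
  expect_lt(rfi_row$mean_low, 0)
  expect_gt(rfi_row$mean_high, 0)
  expect_error(divergent_group_contrast(tr, fraction = 0.6), "fraction")

  # Welch oracle on a fixed 2x5 example
  xl <- c(1, 2, 3, 4, 5); xh <- c(4, 5, 6, 8, 9)
  s1 <- var(xl) / 5; s2 <- var(xh) / 5
  t_hand <- (mean(xl) - mean(xh)) / sqrt(s1 + s2)
  df_hand <- (s1 + s2)^2 / (s1^2 / 4 + s2^2 / 4)
  p_hand <- 2 * pt(abs(t_hand), df_hand, lower.tail = FALSE)
  tr2 <- data.frame(bird_id = sprintf("b%02d", 1:20),
                    rfi = c(seq(-2, -1.2, length.out = 5), rnorm(10, 0, .1),
                            seq(1.2, 2, length.out = 5)),
                    adfi = c(xl, rnorm(10, 5, 1), xh))
  ct2 <- divergent_group_contrast(tr2, fraction = 0.25,
                                  trait_cols = "adfi")
  expect_equal(ct2$table$p_value, p_hand, tolerance = 1e-9)
})

test_that("null contrasts give uniform p-values", {
  set.seed(99)
  ps <- replicate(200, {
    tr <- data.frame(bird_id = sprintf("b%03d", 1:60),
                     rfi = rnorm(60), adg = rnorm(60))
    divergent_group_contrast(tr, fraction = 0.2,
                             trait_cols = "adg")$table$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})
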