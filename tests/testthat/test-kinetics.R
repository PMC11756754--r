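test_that("log-linear fit is exact on noiseless exponential growth", {
  t <- 0:48
  fit <- fit_exponential(t, 2^(t / 15))
  expect_equal(fit$pdt, 15, tolerance = 1e-10)
  expect_equal(fit$k * fit$pdt, log(2))

  # doubling every 330 minutes
  tm <- seq(0, 12, by = 0.25)
  fit2 <- fit_exponential(tm, 2^(tm / 5.5))
  expect_equal(fit2$pdt, 5.5, tolerance = 1e-10)

  expect_error(fit_exponential(1:3, c(1, 2, 4)), "4 points")
  expect_error(fit_exponential(0:9, c(-1, 2:10)), "positive")
})

test_that("doubling time is invariant to rescaling and normalization", {
  t <- seq(0, 40, by = 2)
  set.seed(11)
  v <- 2^(t / 15) * exp(rnorm(length(t), 0, 0.03))
  f1 <- fit_exponential(t, v)
  f2 <- fit_exponential(t, 7.3 * v)
  f3 <- fit_exponential(t, normalize_series(v))
  expect_equal(f1$pdt, f2$pdt)
  expect_equal(f1$k, f3$k)
})

test_that("rate recovery is essentially unbiased at moderate noise", {
  # 200 Monte-Carlo series, 5% multiplicative noise, n = 21 points
  set.seed(202)
  k_true <- log(2) / 15
  t <- seq(0, 40, by = 2)
  ks <- replicate(200, {
    v <- exp(k_true * t) * exp(rnorm(length(t), 0, 0.05))
    fit_exponential(t, v)$k
  })
  expect_lt(abs(mean(ks) - k_true) / k_true, 0.01)
})

test_that("normalize_series divides by the first value", {
  expect_equal(normalize_series(c(2, 4, 8)), c(1, 2, 4))
  expect_equal(normalize_series(rep(3.3, 5)), rep(1, 5))
  expect_error(normalize_series(c(0, 1)), "positive")
})

test_that("breakpoint fit is exact on noiseless piecewise data", {
  r <- seq(10, 80, length.out = 40)
  th <- 12 + 0.1 * r + 0.2 * pmax(r - 40, 0)
  fit <- fit_breakpoint(r, th)
  expect_false(fit$single_line)
  expect_equal(fit$breakpoint, 40, tolerance = 1e-6)
  expect_equal(fit$slope1, 0.1, tolerance = 1e-8)
  expect_equal(fit$slope2, 0.3, tolerance = 1e-8)
})

test_that("breakpoint fit falls back to a single line when unsupported", {
  set.seed(4)
  r <- seq(10, 80, length.out = 30)
  th <- 12 + 0.15 * r + rnorm(30, 0, 0.3)
  fit <- fit_breakpoint(r, th)
  expect_true(fit$single_line)
  expect_true(is.na(fit$breakpoint))
  expect_equal(fit$slope1, fit$slope2)
  expect_error(fit_breakpoint(rep(5, 10), 1:10), "equal")
  expect_error(fit_breakpoint(1:5, 1:5), "8 points")
})

test_that("noisy breakpoint is recovered near the critical radius", {
  set.seed(1)
  r <- seq(10, 80, length.out = 40)
  th <- 12 + 0.1 * r + 0.2 * pmax(r - 40, 0) + rnorm(40, 0, 0.5)
  fit <- fit_breakpoint(r, th)
  expect_false(fit$single_line)
  expect_gte(fit$breakpoint, 35)
  expect_lte(fit$breakpoint, 45)
})

test_that("breakpoint search matches the exhaustive-grid oracle", {
  # brute force: continuous hinge OLS at every interior observed radius
  brute <- function(x, y) {
    grid <- sort(unique(x))
    grid <- grid[vapply(grid, function(g) sum(x < g) >= 3 && sum(x > g) >= 3,
                        logical(1))]
    rss <- vapply(grid, function(g) {
      h <- pmax(x - g, 0)
      sum(residuals(lm(y ~ x + h))^2)
    }, numeric(1))
    list(psi = grid[which.min(rss)], rss = min(rss))
  }
  set.seed(9)
  for (i in 1:5) {
    x <- sort(runif(30, 10, 80))
    y <- 10 + 0.1 * x + 0.25 * pmax(x - runif(1, 30, 50), 0) +
      rnorm(30, 0, 0.4)
    oracle <- brute(x, y)
    fit <- fit_breakpoint(x, y)
    # refinement may only improve on the best grid point
    h <- pmax(x - fit$breakpoint, 0)
    rss_fit <- sum(residuals(lm(y ~ x + h))^2)
    expect_lte(rss_fit, oracle$rss + 1e-8)
    expect_lt(abs(fit$breakpoint - oracle$psi), diff(range(x)) / 10)
  }
})

test_that("breakpoint estimate agrees with an independent implementation", {
  skip_if_not_installed("segmented")
  set.seed(13)
  r <- seq(10, 80, length.out = 50)
  th <- 12 + 0.1 * r + 0.2 * pmax(r - 40, 0) + rnorm(50, 0, 0.4)
  ours <- fit_breakpoint(r, th)
  ref <- segmented::segmented(lm(th ~ r), seg.Z = ~r, psi = 45)
  expect_equal(ours$breakpoint, ref$psi[, "Est."], tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("fit objects expose tidy, glance and autoplot methods", {
  t <- seq(0, 30, by = 2)
  fit <- fit_exponential(t, 2^(t / 15))
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("k", "pdt", "v0"))
  gl <- generics::glance(fit)
  expect_equal(gl$pdt, 15, tolerance = 1e-9)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")

  r <- seq(10, 80, length.out = 40)
  bf <- fit_breakpoint(r, 12 + 0.1 * r + 0.2 * pmax(r - 40, 0))
  expect_equal(generics::glance(bf)$breakpoint, 40, tolerance = 1e-6)
  expect_s3_class(ggplot2::autoplot(bf), "ggplot")
})
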