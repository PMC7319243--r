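test_that("body mass ratios follow from group mean masses", {
  expect_equal(body_mass_ratio(1.70, 0.018), 94.44, tolerance = 1e-3)
  expect_equal(body_mass_ratio(12.29, 0.018), 682.8, tolerance = 1e-3)
  expect_identical(body_mass_ratio(3.5, 3.5), 1)
  expect_error(body_mass_ratio(0, 1), "> 0")
  expect_error(body_mass_ratio(1, -2), "> 0")
})

test_that("parameter transforms match their closed forms", {
  draws <- data.frame(a = c(0.45, 1, 10), h = c(0, 0.01, 9))
  tp <- transform_params(draws, mass_ratio = 100)
  expect_equal(tp$x, rep(2, 3))
  expect_equal(tp$y_a, log10(c(0.45, 1, 10)))
  expect_equal(tp$y_a[1], -0.34679, tolerance = 1e-4)
  expect_equal(tp$y_h, c(0, log10(1.01), 1))
})

test_that("zero attack-rate draws are dropped with a count, not propagated", {
  draws <- data.frame(a = c(0, 0.5, 0), h = c(0.01, 0.02, 0.03))
  expect_warning(tp <- transform_params(draws, 50), "zero attack-rate")
  expect_identical(attr(tp, "n_zero_a"), 2L)
  expect_true(all(is.na(tp$y_a[c(1, 3)])))
  expect_false(is.na(tp$y_a[2]))
})

test_that("an exactly linear relationship selects degree 1 and recovers the slope", {
  x <- seq(1, 3, length.out = 40)
  y <- 0.7 - 0.42 * x
  fit <- fit_scaling(x, y)
  expect_identical(fit$degree, 1L)
  expect_equal(fit$coef_raw[2], -0.42, tolerance = 1e-10)
  expect_equal(fit$coef_raw[1], 0.7, tolerance = 1e-10)
})

test_that("a planted quadratic peak is recovered within 0.1 log-ratio units", {
  set.seed(3)
  x <- runif(180, 0.5, 3.5)
  y <- -(x - 2)^2 + rnorm(180, sd = 0.05)
  fit <- fit_scaling(x, y)
  expect_true(fit$degree %in% c(2L, 3L))
  expect_gt(fit$peak, 1.9)
  expect_lt(fit$peak, 2.1)
})

test_that("degenerate inputs error or cap the candidate degrees", {
  expect_error(fit_scaling(1:4, rnorm(4)), "points")
  expect_warning(fit_scaling(rep(c(1, 2, 3), 5), rnorm(15)), "distinct")
})

test_that("the small-sample correction vanishes for large n", {
  set.seed(14)
  x <- runif(1e5, 0, 3)
  y <- 1 + x + rnorm(1e5)
  fit <- fit_scaling(x, y)
  expect_true(all(abs(fit$aicc_table$aicc - fit$aicc_table$aic) < 1e-3))
})

test_that("hump-shaped attack-rate truths reproduce an interior scaling peak", {
  # emulate bootstrap draws from groups whose true log10(a) is unimodal in
  # the log10 mass ratio
  set.seed(77)
  ratios <- 10^seq(1.3, 2.9, length.out = 9)
  pts <- do.call(rbind, lapply(ratios, function(r) {
    lr <- log10(r)
    a_true <- 1.4 * exp(-(lr - 2.1)^2 / (2 * 0.35^2))
    data.frame(x = lr, y = log10(a_true * exp(rnorm(20, sd = 0.15))))
  }))
  fit <- fit_scaling(pts$x, pts$y)
  expect_gte(fit$degree, 2L)
  expect_true(is.finite(fit$peak))
  expect_gt(fit$peak, min(pts$x))
  expect_lt(fit$peak, max(pts$x))
})

test_that("declining handling-time truths yield a negative average fitted slope", {
  set.seed(78)
  ratios <- 10^seq(1.3, 2.9, length.out = 9)
  pts <- do.call(rbind, lapply(ratios, function(r) {
    h_true <- 2 * r^-0.7
    data.frame(x = log10(r),
               y = log10(pmax(h_true * exp(rnorm(20, sd = 0.2)), 0) + 1))
  }))
  fit <- fit_scaling(pts$x, pts$y)
  ends <- predict(fit, range(pts$x))
  expect_lt(ends[2], ends[1])
})
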