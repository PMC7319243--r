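test_that("rogers_expected_eaten reproduces analytic limits and the fixed-point oracle", {
  # no attacks without an attack rate
  expect_identical(rogers_expected_eaten(16, a = 0, h = 0.01, T = 1), 0)
  # h = 0 collapses to exponential depletion
  expect_equal(rogers_expected_eaten(10, a = 0.45, h = 0, T = 1),
               10 * (1 - exp(-0.45)), tolerance = 1e-12)
  # frozen fixed-point oracle value (strong depletion cell)
  expect_equal(rogers_expected_eaten(2, a = 5, h = 0.01, T = 1),
               1.9851179118, tolerance = 1e-8)
  # the oracle itself, recomputed across a spread of conditions
  for (cs in list(c(8, 0.3, 0.05, 1), c(32, 1, 0.01, 1.5),
                  c(64, 0.45, 0.3, 0.2), c(4, 2, 0.1, 0.5))) {
    expect_equal(rogers_expected_eaten(cs[1], cs[2], cs[3], cs[4]),
                 fixed_point_eaten(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-9)
  }
})

test_that("the solution solves the implicit equation when plugged back in", {
  set.seed(42)
  for (i in 1:50) {
    a <- runif(1, 0.01, 10); h <- runif(1, 0, 0.5)
    n0 <- sample(2:64, 1); t_hr <- runif(1, 0.1, 2)
    ne <- rogers_expected_eaten(n0, a, h, t_hr)
    expect_equal(ne, n0 * (1 - exp(a * (ne * h - t_hr))), tolerance = 1e-8)
  }
})

test_that("expected eaten is monotone in density, attack rate, time, handling time", {
  n0 <- 2^(1:6)
  ne <- rogers_expected_eaten(n0, 0.8, 0.05, 1)
  expect_true(all(diff(ne) > 0))
  for (a in c(0.1, 0.5, 2)) {
    expect_lt(rogers_expected_eaten(16, a, 0.05, 1),
              rogers_expected_eaten(16, a * 1.5, 0.05, 1))
    expect_gt(rogers_expected_eaten(16, a, 0.05, 1),
              rogers_expected_eaten(16, a, 0.10, 1))
    expect_lt(rogers_expected_eaten(16, a, 0.05, 0.5),
              rogers_expected_eaten(16, a, 0.05, 1.0))
  }
})

test_that("expected eaten respects its bounds and the handling-limited asymptote", {
  set.seed(7)
  for (i in 1:30) {
    a <- runif(1, 0.01, 10); h <- runif(1, 0.001, 0.5)
    n0 <- sample(2:64, 1); t_hr <- runif(1, 0.1, 2)
    ne <- rogers_expected_eaten(n0, a, h, t_hr)
    expect_gte(ne, 0)
    expect_lte(ne, min(n0, t_hr / h) + 1e-9)
  }
  # saturation: at N0 = 1e6 * T/h the expectation reaches T/h within 1%
  for (h in c(0.05, 0.1, 0.3)) {
    t_hr <- 1
    ne <- rogers_expected_eaten(1e6 * t_hr / h, a = 1, h = h, T = t_hr)
    expect_equal(ne, t_hr / h, tolerance = 0.01)
  }
})

test_that("rogers_expected_eaten rejects invalid inputs", {
  expect_error(rogers_expected_eaten(-1, 1, 0.1, 1), ">= 0")
  expect_error(rogers_expected_eaten(8, -1, 0.1, 1), ">= 0")
  expect_error(rogers_expected_eaten(8, 1, -0.1, 1), ">= 0")
  expect_error(rogers_expected_eaten(8, 1, 0.1, 0), "> 0")
})

test_that("density-dependent forms dispatch correctly and nest type II", {
  # h = 0 limit with a(N0) = b * N0
  p <- fr_params(0.1, 0, form = "hassell_iii")
  expect_equal(fr_expected_eaten(8, p, 1), 8 * (1 - exp(-0.8)), tolerance = 1e-10)
  # q = 0 generalized degenerates to the type II response
  pg <- fr_params(0.7, 0.05, q = 0, form = "generalized")
  expect_equal(fr_expected_eaten(c(2, 8, 32), pg, 1),
               rogers_expected_eaten(c(2, 8, 32), 0.7, 0.05, 1))
  # fixed-point oracle with the density-scaled attack coefficient
  ph <- fr_params(0.05, 0.05, form = "hassell_iii")
  expect_equal(fr_expected_eaten(16, ph, 1), 6.6281213240, tolerance = 1e-8)
  expect_equal(fr_expected_eaten(16, ph, 1),
               fixed_point_eaten(16, 0.05 * 16, 0.05, 1), tolerance = 1e-9)
})

test_that("fr_params enforces its invariants", {
  expect_error(fr_params(-1, 0.1), ">= 0")
  expect_error(fr_params(1, -0.1), ">= 0")
  expect_error(fr_params(1, 0.1, q = 2, form = "rogers_ii"), "q")
  expect_error(fr_params(1, 0.1, form = "generalized"), "required")
  expect_identical(fr_params(1, 0.1)$q, 0)
  expect_identical(fr_params(1, 0.1, form = "hassell_iii")$q, 1)
})

test_that("the depletion ODE matches the closed form (differential/integral equivalence)", {
  # frozen examples
  expect_identical(integrate_depletion(32, a = 0, h = 0.01, T = 1), 32)
  expect_equal(32 - integrate_depletion(32, a = 1, h = 0.01, T = 1),
               rogers_expected_eaten(32, 1, 0.01, 1), tolerance = 1e-6)
  expect_equal(integrate_depletion(2, a = 5, h = 0.01, T = 1),
               2 - 1.9851179118, tolerance = 1e-6)
  # random-draw equivalence at the solver tolerance
  set.seed(11)
  for (i in 1:25) {
    a <- runif(1, 0.01, 10); h <- runif(1, 0, 0.5)
    n0 <- sample(2:64, 1); t_hr <- runif(1, 0.1, 2)
    eaten_ode <- n0 - integrate_depletion(n0, a, h, T = t_hr)
    expect_equal(eaten_ode, rogers_expected_eaten(n0, a, h, t_hr),
                 tolerance = 1e-6 * n0)
  }
})

test_that("depletion trajectories are monotone non-increasing", {
  ts <- seq(0.1, 2, by = 0.1)
  remaining <- vapply(ts, function(t_hr) {
    integrate_depletion(32, a = 1.5, h = 0.05, T = t_hr)
  }, numeric(1))
  expect_true(all(diff(remaining) < 0))
  expect_true(all(remaining >= 0 & remaining <= 32))
})
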