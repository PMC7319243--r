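test_that("the default design mirrors the crossed size-class experiment", {
  d <- fr_design()
  expect_setequal(unique(d$species), c("bluegill", "largemouth_bass"))
  expect_equal(length(unique(interaction(d$species, d$pred_size_class,
                                         d$prey_size_class))), 18)
  # density 64 offered only to small prey
  expect_setequal(unique(d$n0[d$prey_size_class == "small"]),
                  c(2, 4, 8, 16, 32, 64))
  expect_setequal(unique(d$n0[d$prey_size_class != "small"]),
                  c(2, 4, 8, 16, 32))
  expect_true(all(d$t_hr == 1))
  # group mean masses as measured for the study animals
  expect_equal(unique(d$pred_mass_g[d$species == "largemouth_bass" &
                                    d$pred_size_class == "small"]), 1.70)
  expect_equal(unique(d$prey_mass_g[d$prey_size_class == "small"]), 0.018)
  expect_equal(unique(d$pred_mass_g[d$species == "bluegill" &
                                    d$pred_size_class == "large"]), 12.29)
})

test_that("generate_trials is deterministic under a fixed seed and respects bounds", {
  t1 <- generate_trials(seed = 99)
  t2 <- generate_trials(seed = 99)
  expect_identical(t1, t2)
  t3 <- generate_trials(seed = 100)
  expect_false(identical(t1, t3))
  expect_true(all(t1$ne >= 0 & t1$ne <= t1$n0))
  expect_error(generate_trials(), "seed")
})

test_that("zero attack rate produces zero consumption everywhere", {
  d <- make_design()
  tr <- generate_trials(d, make_truths(d, a = 0, h = 0.1), seed = 1)
  expect_true(all(tr$ne == 0))
})

test_that("binomial generator means match the Rogers expectation", {
  # strong-depletion cell: eaten ~ 1.985 of 2, so P(Ne = 2) ~ 0.985
  d <- make_design(densities = 2, replicates = 4000)
  tr <- generate_trials(d, make_truths(d, a = 5, h = 0.01), seed = 5)
  p_full <- mean(tr$ne == 2)
  expect_equal(p_full, (1.9851179118 / 2)^2, tolerance = 0.015)

  # mean over many replicates within 2 Monte-Carlo SEs of the closed form
  d <- make_design(densities = 16, replicates = 10000)
  tr <- generate_trials(d, make_truths(d, a = 1, h = 0.01), seed = 123)
  mu <- rogers_expected_eaten(16, 1, 0.01, 1)
  p <- mu / 16
  mc_se <- sqrt(16 * p * (1 - p) / 10000)
  expect_lt(abs(mean(tr$ne) - mu), 2 * mc_se)
})

test_that("the capture process respects N0 and agrees with the binomial mean at low depletion", {
  d <- make_design(densities = 32, replicates = 3000)
  tr <- generate_trials(d, make_truths(d, a = 0.2, h = 0.01),
                        noise = "event_process", seed = 17)
  expect_true(all(tr$ne <= 32))
  mu <- rogers_expected_eaten(32, 0.2, 0.01, 1)
  expect_lt(mu / 32, 0.5)          # documented validity region
  expect_lt(abs(mean(tr$ne) - mu) / mu, 0.05)
})

test_that("controls have complete survival and empty designs pass through", {
  ctl <- generate_controls(fr_design())
  expect_true(all(ctl$ne == 0))
  expect_true(all(ctl$species == "none"))
  # survival fraction is 1 at every density
  surv <- tapply(1 - ctl$ne / ctl$n0, ctl$n0, mean)
  expect_true(all(surv == 1))
  empty <- generate_controls(fr_design()[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("unknown groups in the truth table are rejected", {
  d <- make_design()
  truths <- make_truths(make_design(species = "largemouth_bass"), 1, 0.1)
  expect_error(generate_trials(d, truths, seed = 1), "absent")
})
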