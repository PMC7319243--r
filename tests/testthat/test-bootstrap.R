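test_that("bootstrap returns the requested number of non-negative capped draws", {
  tr <- make_group_trials(a = 1, h = 0.05, seed = 3)
  b <- bootstrap_fr(tr, n = 20, seed = 42)
  expect_s3_class(b, "fr_boot")
  expect_equal(nrow(b$draws), 20)
  expect_true(all(b$draws$a >= 0))
  expect_true(all(b$draws$h >= 0))
  # deterministic under seed
  b2 <- bootstrap_fr(tr, n = 20, seed = 42)
  expect_identical(b$draws, b2$draws)
})

test_that("zero-variance data give draws equal to the point estimate", {
  # deterministic identical replicates: every resample is the same dataset
  tr <- simulate_consumption(a = 1, h = 0.05, duration = 1)
  fit <- fit_rogers_mle(tr)
  b <- bootstrap_fr(tr, n = 8, seed = 9, fit = fit)
  expect_equal(b$draws$a, rep(fit$coef[["a"]], 8), tolerance = 1e-6)
  expect_equal(b$draws$h, rep(fit$coef[["h"]], 8), tolerance = 1e-4)
})

test_that("large-n bootstrap mean stays near the point estimate", {
  tr <- make_group_trials(a = 1, h = 0.05, seed = 13)
  fit <- fit_rogers_mle(tr)
  b <- bootstrap_fr(tr, n = 500, seed = 101, fit = fit)
  expect_lt(abs(mean(b$draws$a) - fit$coef[["a"]]) / fit$coef[["a"]], 0.10)
  expect_lt(abs(mean(b$draws$h) - fit$coef[["h"]]) / fit$coef[["h"]], 0.10)
})

test_that("bootstrapping a boundary fit is refused and a seed is required", {
  tr0 <- data.frame(n0 = rep(c(2, 8, 32), each = 3), ne = 0, t_hr = 1)
  fit0 <- fit_rogers_mle(tr0)
  expect_error(bootstrap_fr(tr0, seed = 1, fit = fit0), "boundary")
  tr <- make_group_trials(a = 1, h = 0.05, seed = 3)
  expect_error(bootstrap_fr(tr), "seed")
})

test_that("identical group truths produce no spurious factor interactions", {
  sizes <- c("small", "medium", "large")
  grid <- expand.grid(species = c("bluegill", "largemouth_bass"),
                      pred = sizes, prey = sizes, stringsAsFactors = FALSE)
  terms_hit <- c(a = 0, h = 0)
  n_runs <- 100
  set.seed(2024)
  any_hit <- 0
  three_way_hit <- 0
  for (r in seq_len(n_runs)) {
    boots <- lapply(seq_len(nrow(grid)), function(i) {
      fake_boot(grid$species[i], grid$pred[i], grid$prey[i],
                a = rgamma(20, shape = 25, rate = 25),       # mean 1
                h = rgamma(20, shape = 25, rate = 25 / 0.05)) # mean 0.05
    })
    cmp <- compare_bootstrapped_params(boots)
    inter <- grepl(":", cmp$a$term)
    p_int <- cmp$a$p[inter]
    if (any(p_int < 0.05)) any_hit <- any_hit + 1
    p3 <- cmp$a$p[cmp$a$term == "species:pred_size_class:prey_size_class"]
    if (length(p3) == 1 && p3 < 0.05) three_way_hit <- three_way_hit + 1
  }
  # per-term size: the three-way interaction rejects at ~alpha
  expect_lte(three_way_hit / n_runs, 0.12)
  # family-wise: with 4 interaction terms at alpha = 0.05, runs with any
  # false positive stay below ~1 - 0.95^4 plus Monte-Carlo slack
  expect_lte(any_hit / n_runs, 0.30)
})

test_that("a true species difference in attack rate is detected", {
  sizes <- c("small", "medium", "large")
  grid <- expand.grid(species = c("bluegill", "largemouth_bass"),
                      pred = sizes, prey = sizes, stringsAsFactors = FALSE)
  set.seed(55)
  boots <- lapply(seq_len(nrow(grid)), function(i) {
    a_mean <- if (grid$species[i] == "bluegill") 1 else 5
    fake_boot(grid$species[i], grid$pred[i], grid$prey[i],
              a = rgamma(20, shape = 25, rate = 25 / a_mean),
              h = rgamma(20, shape = 25, rate = 25 / 0.05))
  })
  cmp <- compare_bootstrapped_params(boots)
  p_species <- cmp$a$p[cmp$a$term == "species"]
  expect_lt(p_species, 0.05)
})

test_that("a single group yields empty deviance tables without error", {
  b <- fake_boot("bluegill", "small", "small",
                 a = rgamma(20, 25, 25), h = rgamma(20, 25, 500))
  cmp <- compare_bootstrapped_params(list(b))
  expect_equal(nrow(cmp$a), 0)
  expect_equal(nrow(cmp$h), 0)
})

test_that("capped zero draws are substituted by the smallest positive draw", {
  set.seed(8)
  sizes <- c("small", "large")
  boots <- list(
    fake_boot("bluegill", "small", "small",
              a = c(0, 0, rgamma(18, 25, 25)), h = rgamma(20, 25, 500)),
    fake_boot("largemouth_bass", "small", "small",
              a = rgamma(20, 25, 25), h = rgamma(20, 25, 500))
  )
  cmp <- compare_bootstrapped_params(boots)
  expect_identical(unname(cmp$n_zero_replaced[["a"]]), 2L)
  expect_true(nrow(cmp$a) >= 1)
})
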