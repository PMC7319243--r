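# Independent oracles used across the suite.

# Fixed-point iteration of the implicit random predator equation
# Ne = N0 (1 - exp(a (Ne h - T))); independent of the Lambert-W route.
fixed_point_eaten <- function(n0, a, h, t_hr, tol = 1e-12) {
  # damping keeps the iteration contractive when n0*a*h > 1
  lam <- 1 / (1 + n0 * a * h)
  ne <- 0
  for (i in 1:1000000) {
    ne_new <- (1 - lam) * ne + lam * n0 * (1 - exp(a * (ne * h - t_hr)))
    if (abs(ne_new - ne) < tol) return(ne_new)
    ne <- ne_new
  }
  stop("fixed-point oracle did not converge")
}

# One-group trial table with binomial noise around the type II expectation.
make_group_trials <- function(a, h, seed,
                              densities = c(2, 4, 8, 16, 32, 64),
                              replicates = 3, t_hr = 1,
                              form = c("rogers_ii", "hassell_iii")) {
  form <- match.arg(form)
  params <- if (form == "rogers_ii") fr_params(a, h) else
    fr_params(a, h, form = "hassell_iii")
  n0 <- rep(densities, each = replicates)
  mu <- fr_expected_eaten(n0, params, t_hr)
  withr::with_seed(seed, {
    data.frame(n0 = n0, ne = stats::rbinom(length(n0), n0, mu / n0),
               t_hr = t_hr,
               replicate = rep(seq_len(replicates), times = length(densities)))
  })
}

# Minimal design data frame for one named experimental group, in the shape
# generate_trials() expects.
make_design <- function(species = "bluegill", pred_size = "small",
                        prey_size = "small", pred_mass = 1.65,
                        prey_mass = 0.018,
                        densities = c(2, 4, 8, 16, 32, 64),
                        replicates = 3, t_hr = 1) {
  data.frame(
    species = species, pred_size_class = pred_size,
    prey_size_class = prey_size,
    pred_mass_g = pred_mass, prey_mass_g = prey_mass,
    n0 = rep(densities, each = replicates), t_hr = t_hr,
    replicate = rep(seq_len(replicates), times = length(densities)),
    stringsAsFactors = FALSE
  )
}

make_truths <- function(design, a, h) {
  key <- !duplicated(design[c("species", "pred_size_class", "prey_size_class")])
  g <- design[key, c("species", "pred_size_class", "prey_size_class")]
  g$a <- a; g$h <- h
  g
}

# Fabricated bootstrap-draw container for GLM-comparison tests (the op under
# test consumes draws; how they arose is irrelevant to it).
fake_boot <- function(species, pred_size, prey_size, a, h,
                      pred_mass = 5, prey_mass = 0.035) {
  structure(list(
    draws = data.frame(a = a, h = h, flagged = FALSE),
    estimate = c(a = mean(a), h = mean(h)),
    n = length(a), seed = NA_integer_, form = "rogers_ii",
    group = data.frame(species = species, pred_size_class = pred_size,
                       prey_size_class = prey_size,
                       pred_mass_g = pred_mass, prey_mass_g = prey_mass,
                       stringsAsFactors = FALSE)
  ), class = "fr_boot")
}
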