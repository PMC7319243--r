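#' Experimental design skeleton for synthetic feeding trials
#'
#' Builds the trial layout of a fully crossed feeding experiment: two
#' predator species (bluegill, largemouth bass) in three size classes,
#' each offered three size classes of tilapia prey at densities
#' 2, 4, 8, 16, 32 (plus 64 for small prey, so consumption can approach
#' its asymptote), with three replicates per density and 1-hr trials.
#' Group mean body masses default to the study animals' measured means.
#'
#' @param densities Prey densities offered to every group.
#' @param small_prey_extra Additional density offered only to small prey
#'   (`NULL` to disable).
#' @param replicates Replicates per density (at least 3 in the emulated
#'   design).
#' @param t_hr Trial duration in hours.
#'
#' @return A data frame with one row per planned trial: `species`,
#'   `pred_size_class`, `prey_size_class`, `pred_mass_g`, `prey_mass_g`,
#'   `n0`, `t_hr`, `replicate` (the `ne` column is added by
#'   [generate_trials]).
#' @export
fr_design <- function(densities = c(2, 4, 8, 16, 32),
                      small_prey_extra = 64,
                      replicates = 3,
                      t_hr = 1) {
  stopifnot(all(densities > 0), replicates >= 1, t_hr > 0)
  sizes <- c("small", "medium", "large")
  pred_mass <- list(
    bluegill        = c(small = 1.65, medium = 5.45, large = 12.29),
    largemouth_bass = c(small = 1.70, medium = 4.95, large = 11.38)
  )
  prey_mass <- c(small = 0.018, medium = 0.035, large = 0.075)

  grid <- expand.grid(species = names(pred_mass),
                      pred_size_class = sizes,
                      prey_size_class = sizes,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    dens <- densities
    if (!is.null(small_prey_extra) && g$prey_size_class == "small") {
      dens <- c(dens, small_prey_extra)
    }
    data.frame(
      species = g$species,
      pred_size_class = g$pred_size_class,
      prey_size_class = g$prey_size_class,
      pred_mass_g = unname(pred_mass[[g$species]][g$pred_size_class]),
      prey_mass_g = unname(prey_mass[g$prey_size_class]),
      n0 = rep(dens, each = replicates),
      t_hr = t_hr,
      replicate = rep(seq_len(replicates), times = length(dens)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Default ground-truth parameters for each experimental group
#'
#' Assigns a true type II parameter pair to every species x predator size x
#' prey size group, patterned on how the fitted parameters behave in this
#' kind of system: attack rate is hump-shaped in the log10 predator-prey
#' body-mass ratio (peaking at intermediate ratios) and handling time
#' declines as a power law of the ratio.
#'
#' @param design A design data frame from [fr_design].
#' @param a_max Peak attack rate (cage/hr) at the optimal ratio.
#' @param log10_ratio_peak Location of the attack-rate peak on the log10
#'   mass-ratio axis.
#' @param peak_width Gaussian width (log10 units) of the attack-rate hump.
#' @param h_scale,h_exponent Handling time `h = h_scale * ratio^-h_exponent`
#'   (hr/prey).
#'
#' @return A data frame with one row per group: group labels, masses,
#'   `mass_ratio`, and true `a`, `h`.
#' @export
default_group_truths <- function(design = fr_design(),
                                 a_max = 1.5,
                                 log10_ratio_peak = 2.1,
                                 peak_width = 0.35,
                                 h_scale = 2,
                                 h_exponent = 0.7) {
  key <- !duplicated(design[c("species", "pred_size_class", "prey_size_class")])
  groups <- design[key, c("species", "pred_size_class", "prey_size_class",
                          "pred_mass_g", "prey_mass_g")]
  rownames(groups) <- NULL
  groups$mass_ratio <- groups$pred_mass_g / groups$prey_mass_g
  lr <- log10(groups$mass_ratio)
  groups$a <- a_max * exp(-(lr - log10_ratio_peak)^2 / (2 * peak_width^2))
  groups$h <- h_scale * groups$mass_ratio^(-h_exponent)
  groups
}

#' Generate a synthetic trial table
#'
#' Fills a design skeleton with simulated consumption counts drawn around
#' the Rogers expectation for each group's true parameters. Two noise
#' models are available:
#'
#' * `"binomial"` (default): each of the `N0` prey is eaten independently
#'   with probability `rogers_expected_eaten(N0, a, h, T) / N0`. This is
#'   exactly the likelihood the estimator assumes, so parameter recovery
#'   under this generator is a clean test of the fitting machinery.
#' * `"event_process"`: a continuous-time capture process with
#'   state-dependent rate `a N / (1 + a h N)` simulated to time `T` via
#'   exponential waiting times, which probes robustness to a generating
#'   process the estimator does not assume.
#'
#' @param design Design data frame ([fr_design]).
#' @param truths Data frame with group labels and true `a`, `h`
#'   ([default_group_truths]); every design group must appear.
#' @param noise `"binomial"` or `"event_process"`.
#' @param seed Integer seed; required, so output is reproducible.
#'
#' @return The design with an integer `ne` column (`0 <= ne <= n0`) added.
#' @examples
#' tr <- generate_trials(seed = 1)
#' head(tr)
#' @export
generate_trials <- function(design = fr_design(),
                            truths = default_group_truths(design),
                            noise = c("binomial", "event_process"),
                            seed) {
  noise <- match.arg(noise)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  key_d <- interaction(design$species, design$pred_size_class,
                       design$prey_size_class, drop = TRUE)
  key_t <- interaction(truths$species, truths$pred_size_class,
                       truths$prey_size_class, drop = TRUE)
  idx <- match(key_d, key_t)
  if (anyNA(idx)) {
    stop("design contains groups absent from `truths`", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  a <- truths$a[idx]; h <- truths$h[idx]
  ne <- integer(nrow(design))
  if (noise == "binomial") {
    for (i in seq_len(nrow(design))) {
      mu <- rogers_expected_eaten(design$n0[i], a[i], h[i], design$t_hr[i])
      ne[i] <- stats::rbinom(1L, design$n0[i], mu / design$n0[i])
    }
  } else {
    for (i in seq_len(nrow(design))) {
      ne[i] <- sim_capture_process(design$n0[i], a[i], h[i], design$t_hr[i])
    }
  }
  design$ne <- ne
  design[c("species", "pred_size_class", "prey_size_class",
           "pred_mass_g", "prey_mass_g", "n0", "ne", "t_hr", "replicate")]
}

# One trial of the continuous-time capture process: captures occur at rate
# a*N/(1 + a*h*N) given N prey remaining; waiting times are exponential.
sim_capture_process <- function(n0, a, h, t_hr) {
  n <- n0; t <- 0; eaten <- 0L
  while (n > 0) {
    rate <- a * n / (1 + a * h * n)
    if (rate <= 0) break
    t <- t + stats::rexp(1L, rate)
    if (t >= t_hr) break
    n <- n - 1L
    eaten <- eaten + 1L
  }
  eaten
}

#' Generate predator-free control trials
#'
#' Control cages hold prey with no predator; with zero background
#' mortality every control trial ends with all prey alive (`ne = 0`,
#' survival fraction 1), matching the experiment these simulations emulate.
#'
#' @param design Design data frame; only the layout columns are used.
#' @param seed Ignored (controls are deterministic); accepted so control
#'   generation slots into seeded pipelines.
#' @return The design with `species = "none"` and `ne = 0` everywhere.
#' @export
generate_controls <- function(design = fr_design(), seed = NULL) {
  if (nrow(design) == 0L) {
    design$ne <- integer(0)
    return(design)
  }
  design$species <- "none"
  design$pred_mass_g <- NA_real_
  design$ne <- 0L
  design[c("species", "pred_size_class", "prey_size_class",
           "pred_mass_g", "prey_mass_g", "n0", "ne", "t_hr", "replicate")]
}
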