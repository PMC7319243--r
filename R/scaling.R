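#' Predator-prey body mass ratio
#'
#' @param pred_mass_g Predator mass in grams (`> 0`); vectorized.
#' @param prey_mass_g Prey mass in grams (`> 0`); vectorized.
#' @return `pred_mass_g / prey_mass_g` (dimensionless).
#' @examples
#' body_mass_ratio(1.70, 0.018)   # ~94.4
#' @export
body_mass_ratio <- function(pred_mass_g, prey_mass_g) {
  stopifnot(is.numeric(pred_mass_g), is.numeric(prey_mass_g))
  if (any(pred_mass_g <= 0) || any(prey_mass_g <= 0)) {
    stop("masses must be > 0", call. = FALSE)
  }
  pred_mass_g / prey_mass_g
}

#' Transform bootstrap draws and mass ratios for scaling regression
#'
#' Attack rates and mass ratios are log10-transformed; handling times are
#' log10(x + 1)-transformed, because the zero-capped bootstrap can yield
#' null handling times and log10(0) is undefined. Zero attack-rate draws
#' (possible after the bootstrap cap) cannot be log-transformed and are
#' returned as `NA` with a warning and a count in the `n_zero_a`
#' attribute; downstream fits drop them.
#'
#' @param draws Data frame with columns `a` and `h` (e.g. the `draws`
#'   element of an `fr_boot`).
#' @param mass_ratio Predator-prey body mass ratio(s) for these draws
#'   (length 1 or `nrow(draws)`).
#' @return Data frame with columns `x` (log10 ratio), `y_a` (log10 a, `NA`
#'   where `a == 0`) and `y_h` (log10(h + 1)); attribute `n_zero_a`.
#' @export
transform_params <- function(draws, mass_ratio) {
  stopifnot(all(c("a", "h") %in% names(draws)),
            length(mass_ratio) %in% c(1L, nrow(draws)))
  if (any(mass_ratio <= 0)) stop("mass_ratio must be > 0", call. = FALSE)
  if (any(draws$a < 0) || any(draws$h < 0)) {
    stop("draws must be >= 0", call. = FALSE)
  }
  n_zero <- sum(draws$a == 0)
  if (n_zero > 0) {
    warning(sprintf("%d zero attack-rate draw(s) set NA (log10(0) undefined)",
                    n_zero), call. = FALSE)
  }
  out <- data.frame(
    x = rep_len(log10(mass_ratio), nrow(draws)),
    y_a = ifelse(draws$a > 0, log10(draws$a), NA_real_),
    y_h = log10(draws$h + 1)
  )
  attr(out, "n_zero_a") <- n_zero
  out
}

#' Polynomial scaling regression with AICc degree selection
#'
#' Regresses a transformed functional-response parameter on the log10
#' predator-prey body mass ratio with ordinary least squares, comparing
#' polynomial degrees 1-3 by AICc (`AIC + 2k(k+1)/(n - k - 1)`, `k`
#' counting the residual variance) and returning the minimum-AICc model.
#' Fitting uses an orthogonal polynomial basis for numerical stability;
#' coefficients are also reported on the raw basis
#' (`y = b0 + b1 x + b2 x^2 + ...`). For selected fits of degree >= 2 the
#' location of an interior maximum of the fitted curve over the observed
#' ratio range is reported (for a concave quadratic this is
#' `-b1 / (2 b2)`).
#'
#' @param x log10 body mass ratios.
#' @param y Transformed parameter values (NAs dropped pairwise).
#' @param degrees Candidate polynomial degrees (default 1:3).
#' @return An object of class `scaling_fit`: selected `degree`, raw-basis
#'   `coef_raw`, orthogonal-basis `coef_orth`, the `aicc_table` across
#'   degrees, `peak` (log10-ratio of an interior maximum, or `NA`), and
#'   `n`.
#' @examples
#' x <- runif(60, 1, 3)
#' fit_scaling(x, 0.5 - 0.2 * x)
#' @export
fit_scaling <- function(x, y, degrees = 1:3) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  dmax <- max(degrees)
  if (n <= dmax + 2) {
    stop(sprintf("need more than %d points to compare degrees up to %d",
                 dmax + 2, dmax), call. = FALSE)
  }
  n_unique <- length(unique(x))
  if (n_unique <= dmax) {
    warning(sprintf("only %d distinct x values; capping degree at %d",
                    n_unique, n_unique - 1L), call. = FALSE)
    degrees <- degrees[degrees <= n_unique - 1L]
    if (length(degrees) == 0L) stop("no fittable degree", call. = FALSE)
  }

  fits <- lapply(degrees, function(d) stats::lm(y ~ stats::poly(x, d)))
  k <- degrees + 2              # intercept + slopes + residual variance
  aic <- vapply(fits, stats::AIC, numeric(1))
  # degrees whose small-sample correction is undefined (n <= k + 1) are
  # uncompetitive by construction
  aicc <- ifelse(n - k - 1 > 0, aic + 2 * k * (k + 1) / (n - k - 1), Inf)
  tab <- data.frame(degree = degrees, k = k, aic = aic, aicc = aicc)
  best_i <- which.min(aicc)
  d <- degrees[best_i]

  raw <- stats::lm(y ~ stats::poly(x, d, raw = TRUE))
  b <- unname(stats::coef(raw))

  peak <- NA_real_
  if (d >= 2) {
    rng <- range(x)
    f <- function(z) drop(outer(z, 0:d, `^`) %*% b)
    opt <- stats::optimize(f, interval = rng, maximum = TRUE)
    inner <- diff(rng) * 1e-4
    if (opt$maximum > rng[1] + inner && opt$maximum < rng[2] - inner) {
      peak <- opt$maximum
    }
  }

  structure(list(degree = d,
                 coef_raw = b,
                 coef_orth = unname(stats::coef(fits[[best_i]])),
                 aicc_table = tab,
                 peak = peak,
                 n = n,
                 x_range = range(x)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit: degree %d, n = %d>\n", x$degree, x$n))
  cat("  raw coefficients:", paste(signif(x$coef_raw, 5), collapse = ", "), "\n")
  if (is.finite(x$peak)) cat(sprintf("  interior peak at x = %.3f\n", x$peak))
  print(x$aicc_table, row.names = FALSE)
  invisible(x)
}

#' @export
predict.scaling_fit <- function(object, newdata, ...) {
  x <- if (is.list(newdata)) newdata$x else newdata
  drop(outer(x, 0:object$degree, `^`) %*% object$coef_raw)
}
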