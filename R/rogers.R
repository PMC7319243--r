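#' Expected prey eaten under Rogers' random predator equation
#'
#' Solves the implicit non-replacement functional response
#' \deqn{N_e = N_0 (1 - \exp(a (N_e h - T)))}
#' for the expected number of prey eaten `Ne` over a trial of duration `T`,
#' where prey eaten are not replaced. The unique solution in `[0, N0]` has
#' the closed Lambert-W form
#' \deqn{N_e = N_0 - W(a h N_0 e^{-a (T - h N_0)}) / (a h).}
#'
#' Degenerate parameter values are handled by their analytic limits rather
#' than the Lambert-W branch: `a = 0` gives 0 eaten, and `h = 0` collapses
#' to the exponential depletion `N0 (1 - exp(-a T))`.
#'
#' @param N0 Initial prey density (count, `>= 0`); vectorized.
#' @param a Attack rate (cage/hr, `>= 0`).
#' @param h Handling time (hr/prey, `>= 0`).
#' @param T Trial duration (hr, `> 0`).
#'
#' @return Expected number eaten, same length as `N0`, in `[0, N0]`;
#'   monotone non-decreasing in `N0`, `a`, `T` and non-increasing in `h`.
#' @examples
#' rogers_expected_eaten(16, a = 0.45, h = 0.01, T = 1)
#' rogers_expected_eaten(c(2, 4, 8), a = 5, h = 0.01, T = 1)
#' @export
rogers_expected_eaten <- function(N0, a, h, T = 1) {
  stopifnot(is.numeric(N0), is.numeric(a), is.numeric(h), is.numeric(T),
            length(a) == 1L, length(h) == 1L,
            length(T) == 1L || length(T) == length(N0))
  if (any(N0 < 0)) stop("`N0` must be >= 0", call. = FALSE)
  if (a < 0 || h < 0) stop("`a` and `h` must be >= 0", call. = FALSE)
  if (any(T <= 0)) stop("`T` must be > 0", call. = FALSE)
  .rogers_ne(N0, a, h, T)
}

# Elementwise Rogers solution with recycling; tolerates vector attack rates
# (used for the density-dependent forms) and handles the a = 0 / h = 0
# limits analytically.
.rogers_ne <- function(N0, a, h, T) {
  n <- max(length(N0), length(a), length(T))
  N0 <- rep_len(N0, n); a <- rep_len(a, n); T <- rep_len(T, n)
  if (h == 0) {
    ne <- N0 * (1 - exp(-a * T))
  } else {
    x <- a * h * N0 * exp(-a * (T - h * N0))
    w <- numeric(n)
    big <- is.infinite(x) & x > 0    # argument overflows double: go to logs
    w[!big] <- lambert_w0(x[!big])
    if (any(big)) {
      z <- log(a[big]) + log(h) + log(N0[big]) - a[big] * (T[big] - h * N0[big])
      w[big] <- lambert_w0_logarg(z)
    }
    ne <- N0 - w / (a * h)
    ne[a == 0] <- 0   # 0/0 above; analytic limit is no consumption
  }
  pmin(pmax(ne, 0), N0)   # guard tiny float excursions only
}

# W0(exp(z)) for large z, solving w + log(w) = z by Newton; used when the
# Lambert argument itself would overflow (huge prey densities)
lambert_w0_logarg <- function(z) {
  w <- z - log(z)
  for (i in 1:50) {
    f <- w + log(w) - z
    w_new <- w - f / (1 + 1 / w)
    if (all(abs(w_new - w) <= 1e-13 * (1 + abs(w_new)))) {
      return(w_new)
    }
    w <- w_new
  }
  stop("lambert_w0_logarg: Newton iteration did not converge", call. = FALSE)
}

#' Expected prey eaten for any supported functional response form
#'
#' Dispatches on the form held in an [fr_params] object. For the type II
#' (`rogers_ii`) form this is [rogers_expected_eaten]. For the density-
#' dependent forms (`hassell_iii`, `generalized`) the attack coefficient is
#' evaluated at the initial density, `a(N0) = b N0^q`, and substituted into
#' the same non-replacement solution — the common convention for fitting
#' flexible-exponent responses to non-replacement designs.
#'
#' @param N0 Initial prey density (vectorized).
#' @param params An [fr_params] object.
#' @param T Trial duration (hr).
#' @return Expected number eaten in `[0, N0]`.
#' @examples
#' p3 <- fr_params(a = 0.05, h = 0.05, form = "hassell_iii")
#' fr_expected_eaten(16, p3, T = 1)
#' @export
fr_expected_eaten <- function(N0, params, T = 1) {
  stopifnot(inherits(params, "fr_params"))
  if (params$form == "rogers_ii") {
    return(rogers_expected_eaten(N0, params$a, params$h, T))
  }
  if (any(N0 < 0)) stop("`N0` must be >= 0", call. = FALSE)
  if (any(T <= 0)) stop("`T` must be > 0", call. = FALSE)
  # attack coefficient evaluated at initial density
  a_eff <- params$a * N0^params$q
  .rogers_ne(N0, a_eff, params$h, T)
}
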