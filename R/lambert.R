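#' Principal branch of the Lambert W function
#'
#' Computes \eqn{W_0(x)}, the principal-branch inverse of \eqn{w e^w}, used
#' to write the explicit solution of Rogers' random predator equation (the
#' equation is recursive in the number of prey eaten, and the Lambert W
#' function untangles that recursion into a closed form).
#'
#' Implementation: a branch-point series expansion near \eqn{x = -1/e},
#' asymptotic `log(x) - log(log(x))` start for large `x`, then Halley
#' iteration with a hard iteration cap. `Inf` maps to `Inf` (the analytic
#' limit), which keeps likelihood optimizers safe when they probe extreme
#' parameter values.
#'
#' @param x Numeric vector, each element \eqn{\ge -1/e}.
#'
#' @return Numeric vector `w` with `w * exp(w) == x` (to ~1e-10 relative
#'   tolerance) and `w >= -1`.
#'
#' @examples
#' lambert_w0(0)            # 0
#' lambert_w0(exp(1))       # 1
#' lambert_w0(-exp(-1))     # -1 (branch point)
#' @export
lambert_w0 <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  bad <- !is.na(x) & x < -exp(-1) - 1e-12
  if (any(bad)) {
    stop(sprintf("lambert_w0: argument below branch point -1/e (first offender: %g)",
                 x[which(bad)[1]]), call. = FALSE)
  }
  w <- rep(NA_real_, length(x))
  w[is.infinite(x) & x > 0] <- Inf
  w[x == 0] <- 0

  todo <- which(is.finite(x) & x != 0)
  if (length(todo) == 0L) return(w)
  xv <- pmax(x[todo], -exp(-1))   # clamp float dust below the branch point

  # initial guess by region
  p <- sqrt(2 * (exp(1) * xv + 1))            # branch-point parameter
  w0 <- numeric(length(xv))
  lo <- xv < -0.25; hi <- xv >= exp(1); mid <- !lo & !hi
  w0[lo] <- -1 + p[lo] - p[lo]^2 / 3 + 11 * p[lo]^3 / 72
  w0[mid] <- xv[mid] * exp(-xv[mid] * 0.5)    # crude but in basin
  w0[hi] <- log(xv[hi]) - log(log(xv[hi]))

  # very close to the branch point the series is already more accurate than
  # Halley steps with a vanishing derivative (next term is O(p^4))
  series_only <- p < 1e-3
  active <- !series_only
  for (iter in 1:100) {
    if (!any(active)) break
    wi <- w0[active]
    ew <- exp(wi)
    # Halley step written with ratios so huge exp(w) cannot overflow it
    t1 <- (wi * ew - xv[active]) / (ew * (wi + 1))       # Newton step
    step <- t1 / (1 - t1 * (wi + 2) / (2 * (wi + 1)))
    step[!is.finite(step)] <- t1[!is.finite(step)]       # fall back to Newton
    wi_new <- wi - step
    conv <- is.finite(wi_new) & abs(step) <= 1e-13 * (1 + abs(wi_new))
    wi_new[!is.finite(wi_new)] <- wi[!is.finite(wi_new)]
    w0[active] <- wi_new
    active[active] <- !conv
  }
  if (any(active)) {
    stop("lambert_w0: Halley iteration did not converge", call. = FALSE)
  }
  w[todo] <- pmax(w0, -1)
  w
}
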