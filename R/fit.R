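#' Binomial log-likelihood of a functional response on trial data
#'
#' The probability that any one prey is eaten in a trial is the Rogers
#' expectation divided by the initial density, so the number eaten is
#' binomial: \eqn{N_e \sim Bin(N_0, N_e^{exp}/N_0)}. The log-likelihood sums
#' `dbinom` over trials with the per-prey probability clamped to
#' `[1e-9, 1 - 1e-9]` for numerical safety at the boundaries.
#'
#' @param trials Data frame with columns `n0`, `ne`, `t_hr`.
#' @param params An [fr_params] object.
#' @return The log-likelihood (a single number).
#' @export
fr_loglik <- function(trials, params) {
  stopifnot(all(c("n0", "ne", "t_hr") %in% names(trials)))
  mu <- fr_expected_eaten(trials$n0, params, trials$t_hr)
  p <- pmin(pmax(mu / trials$n0, 1e-9), 1 - 1e-9)
  sum(stats::dbinom(trials$ne, trials$n0, p, log = TRUE))
}

# negative log-likelihood on the log parameter scale (keeps a, h, q > 0)
fr_nll_log <- function(theta, n0, ne, t_hr, form) {
  a <- exp(theta[1]); h <- exp(theta[2])
  a_eff <- switch(form,
    rogers_ii   = a,
    hassell_iii = a * n0,
    generalized = a * n0^exp(theta[3])
  )
  mu <- .rogers_ne(n0, a_eff, h, t_hr)
  p <- pmin(pmax(mu / n0, 1e-9), 1 - 1e-9)
  nll <- -sum(stats::dbinom(ne, n0, p, log = TRUE))
  if (!is.finite(nll)) return(1e10)
  nll
}

# same objective on the natural scale, for observed-information SEs
fr_nll_natural <- function(par, n0, ne, t_hr, form) {
  if (any(par <= 0)) return(NA_real_)
  fr_nll_log(log(par), n0, ne, t_hr, form)
}

#' Fit a non-replacement functional response by maximum likelihood
#'
#' Maximizes the binomial likelihood of [fr_loglik] over attack rate and
#' handling time (plus the density exponent for the generalized form).
#' Parameters are optimized on the log scale, which enforces positivity
#' without hard constraints. By default a 3 x 3 grid of starting values
#' (`a` in 0.1/1/5, `h` in 0.001/0.05/0.3) is tried and the best likelihood
#' kept; pass `start` to use a single start (e.g. when refitting bootstrap
#' resamples from a known point estimate).
#'
#' Standard errors come from the observed information: the numerical
#' Hessian of the negative log-likelihood at the optimum on the natural
#' parameter scale. A singular or non-positive Hessian yields `NA` SEs and
#' a flagged fit rather than an error. Data with no consumption at all give
#' a boundary fit (`a = 0`), also flagged.
#'
#' @param trials Data frame with columns `n0`, `ne`, `t_hr`; at least two
#'   distinct densities are required for the 2-parameter fit.
#' @param form Functional response form (see [fr_params]).
#' @param start Optional named vector `c(a =, h =)` (plus `q =` for the
#'   generalized form) giving a single starting point.
#' @param multistart Use the 3 x 3 start grid (default `TRUE`; ignored when
#'   `start` is given).
#'
#' @return An object of class `fr_fit`: estimates, SEs, log-likelihood,
#'   AIC (`2k - 2 logLik`), convergence/boundary flags and the number of
#'   trials.
#' @examples
#' tr <- simulate_consumption(a = 1, h = 0.01, duration = 1)
#' fit_rogers_mle(tr)
#' @export
fit_rogers_mle <- function(trials,
                           form = c("rogers_ii", "hassell_iii", "generalized"),
                           start = NULL, multistart = TRUE) {
  form <- match.arg(form)
  stopifnot(all(c("n0", "ne", "t_hr") %in% names(trials)), nrow(trials) > 0)
  if (any(trials$ne > trials$n0) || any(trials$ne < 0)) {
    stop("trials must satisfy 0 <= ne <= n0", call. = FALSE)
  }
  if (length(unique(trials$n0)) < 2L) {
    stop("need >= 2 distinct prey densities to fit", call. = FALSE)
  }
  k <- if (form == "generalized") 3L else 2L
  par_names <- if (k == 3L) c("a", "h", "q") else c("a", "h")

  if (all(trials$ne == 0)) {
    ll0 <- sum(stats::dbinom(trials$ne, trials$n0, 1e-9, log = TRUE))
    return(new_fr_fit(form, coef = c(a = 0, h = NA_real_,
                                     if (k == 3L) c(q = NA_real_)),
                      se = setNames(rep(NA_real_, k), par_names),
                      logLik = ll0, k = k, n = nrow(trials),
                      converged = FALSE, boundary = TRUE,
                      note = "no consumption in any trial; attack rate at boundary 0"))
  }

  starts <- if (!is.null(start)) {
    stopifnot(all(c("a", "h") %in% names(start)))
    q0 <- if (k == 3L) { if ("q" %in% names(start)) start[["q"]] else 1 }
    list(c(start[["a"]], start[["h"]], q0))
  } else if (multistart) {
    grid <- expand.grid(a = c(0.1, 1, 5), h = c(0.001, 0.05, 0.3))
    lapply(seq_len(nrow(grid)),
           function(i) c(grid$a[i], grid$h[i], if (k == 3L) 1))
  } else {
    list(c(1, 0.05, if (k == 3L) 1))
  }

  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      stats::optim(log(s), fr_nll_log,
                   n0 = trials$n0, ne = trials$ne, t_hr = trials$t_hr,
                   form = form, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) {
    stop("all optimizer starts failed", call. = FALSE)
  }

  est <- exp(best$par)
  names(est) <- par_names
  hess <- tryCatch(
    stats::optimHess(est, fr_nll_natural,
                     n0 = trials$n0, ne = trials$ne, t_hr = trials$t_hr,
                     form = form,
                     control = list(ndeps = pmax(1e-3 * est, 1e-6))),
    error = function(e) NULL)
  se <- setNames(rep(NA_real_, k), par_names)
  singular <- TRUE
  if (!is.null(hess) && all(is.finite(hess))) {
    vc <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vc) && all(diag(vc) > 0)) {
      se <- setNames(sqrt(diag(vc)), par_names)
      singular <- FALSE
    }
  }
  converged <- best$convergence == 0 && !singular
  new_fr_fit(form, coef = est, se = se, logLik = -best$value, k = k,
             n = nrow(trials), converged = converged, boundary = FALSE,
             note = if (singular) "singular or non-finite Hessian; SEs undefined")
}

new_fr_fit <- function(form, coef, se, logLik, k, n, converged, boundary,
                       note = NULL) {
  structure(list(form = form, coef = coef, se = se, logLik = logLik,
                 aic = 2 * k - 2 * logLik, k = k, n = n,
                 converged = converged, boundary = boundary, note = note),
            class = "fr_fit")
}

#' @export
print.fr_fit <- function(x, ...) {
  cat(sprintf("<fr_fit: %s>  n = %d trials, logLik = %.3f, AIC = %.3f\n",
              x$form, x$n, x$logLik, x$aic))
  tab <- data.frame(estimate = x$coef, se = x$se)
  print(round(tab, 5))
  if (!x$converged) cat("** fit flagged:", x$note %||% "did not converge", "\n")
  if (x$boundary) cat("** boundary fit\n")
  invisible(x)
}

#' @export
coef.fr_fit <- function(object, ...) object$coef

#' @export
logLik.fr_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, class = "logLik")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
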