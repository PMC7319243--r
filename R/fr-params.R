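#' Functional response parameter set
#'
#' Bundles the parameters of a non-replacement functional response. Three
#' forms are supported: `"rogers_ii"`, the classic type II random predator
#' model with constant attack rate `a`; `"hassell_iii"`, a type III form in
#' which the attack coefficient scales linearly with initial prey density
#' (`a(N0) = a * N0`, i.e. exponent fixed at 1); and `"generalized"`, with a
#' free density exponent `q` (`a(N0) = a * N0^q`), which nests the type II
#' model at `q = 0`.
#'
#' @param a Attack rate (type II; cage/hr) or attack coefficient `b` of
#'   `a(N) = b N^q` for the density-dependent forms. Must be `>= 0`.
#' @param h Handling time (hr/prey), `>= 0`. With `h > 0` the expected
#'   number eaten over a duration `T` is bounded above by `T/h`.
#' @param q Density exponent (dimensionless, `>= 0`). Only meaningful for
#'   `form = "generalized"`; fixed at 1 for `"hassell_iii"`, 0 for
#'   `"rogers_ii"`.
#' @param form One of `"rogers_ii"`, `"hassell_iii"`, `"generalized"`.
#'
#' @return An object of class `fr_params`.
#' @examples
#' fr_params(a = 0.45, h = 0.01)
#' fr_params(a = 0.05, h = 0.05, form = "hassell_iii")
#' @export
fr_params <- function(a, h, q = NULL,
                      form = c("rogers_ii", "hassell_iii", "generalized")) {
  form <- match.arg(form)
  stopifnot(is.numeric(a), length(a) == 1L, is.numeric(h), length(h) == 1L)
  if (is.na(a) || a < 0) stop("`a` must be >= 0", call. = FALSE)
  if (is.na(h) || h < 0) stop("`h` must be >= 0", call. = FALSE)
  q <- switch(form,
    rogers_ii = {
      if (!is.null(q) && q != 0) stop("`q` must be absent (or 0) for rogers_ii", call. = FALSE)
      0
    },
    hassell_iii = {
      if (!is.null(q) && q != 1) stop("`q` is fixed at 1 for hassell_iii", call. = FALSE)
      1
    },
    generalized = {
      if (is.null(q)) stop("`q` required for the generalized form", call. = FALSE)
      stopifnot(is.numeric(q), length(q) == 1L)
      if (is.na(q) || q < 0) stop("`q` must be >= 0", call. = FALSE)
      q
    }
  )
  structure(list(a = a, h = h, q = q, form = form), class = "fr_params")
}

#' @export
print.fr_params <- function(x, ...) {
  cat(sprintf("<fr_params: %s>  a = %g, h = %g%s\n", x$form, x$a, x$h,
              if (x$form == "rogers_ii") "" else sprintf(", q = %g", x$q)))
  invisible(x)
}
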