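#' Bootstrap attack rate and handling time for one experimental group
#'
#' Non-parametric bootstrap of the functional response fit: trials are
#' resampled with replacement within each prey-density stratum (so every
#' resample keeps the design's density coverage) and the model is refit to
#' each resample, starting from the group's point estimate. Draws are
#' floored at zero. Resamples with no consumption at all cannot support a
#' fit and are recorded at the boundary (`a = 0, h = 0`) and flagged.
#'
#' @param trials Data frame with `n0`, `ne`, `t_hr` for one group.
#' @param n Number of bootstrap draws (default 20).
#' @param seed Integer seed (required; draws are deterministic under it).
#' @param fit Optional `fr_fit` point estimate; computed (multi-start) if
#'   missing. Must have converged.
#' @param form Functional response form, used when `fit` is missing.
#'
#' @return An object of class `fr_boot`: a `draws` data frame (`a`, `h`,
#'   `flagged`), the point estimate, `n`, `seed`, and any group label
#'   columns carried on `trials`.
#' @examples
#' tr <- simulate_consumption(a = 1, h = 0.05, duration = 1)
#' bootstrap_fr(tr, n = 5, seed = 42)
#' @export
bootstrap_fr <- function(trials, n = 20, seed, fit = NULL,
                         form = "rogers_ii") {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(n >= 1)
  if (is.null(fit)) fit <- fit_rogers_mle(trials, form = form)
  if (fit$boundary) {
    stop("point estimate is a boundary fit; nothing to bootstrap", call. = FALSE)
  }
  start <- fit$coef[!is.na(fit$coef)]

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  strata <- split(seq_len(nrow(trials)), trials$n0)
  draws <- data.frame(a = numeric(n), h = numeric(n), flagged = logical(n))
  for (b in seq_len(n)) {
    idx <- unlist(lapply(strata, function(s) {
      s[sample.int(length(s), length(s), replace = TRUE)]
    }), use.names = FALSE)
    res <- trials[idx, , drop = FALSE]
    if (all(res$ne == 0)) {
      draws[b, ] <- list(0, 0, TRUE)
      next
    }
    bf <- tryCatch(
      fit_rogers_mle(res, form = fit$form, start = start),
      error = function(e) NULL)
    if (is.null(bf)) {
      draws[b, ] <- list(0, 0, TRUE)
    } else {
      a_b <- max(bf$coef[["a"]], 0); h_b <- max(bf$coef[["h"]], 0)
      # a refit without usable curvature (SE undefined) is non-identified:
      # the draw is recorded but flagged so comparisons can exclude it
      bad <- (!bf$converged && is.na(bf$se[["a"]])) ||
        !is.finite(a_b) || !is.finite(h_b)
      draws[b, ] <- list(a_b, h_b, bad)
    }
  }
  group_cols <- intersect(c("species", "pred_size_class", "prey_size_class",
                            "pred_mass_g", "prey_mass_g"), names(trials))
  group <- if (length(group_cols)) unique(trials[group_cols]) else NULL
  structure(list(draws = draws, estimate = fit$coef, n = n, seed = seed,
                 form = fit$form, group = group),
            class = "fr_boot")
}

#' @export
print.fr_boot <- function(x, ...) {
  cat(sprintf("<fr_boot: %d draws, form %s>\n", x$n, x$form))
  cat(sprintf("  a: mean %.4g (point %.4g)   h: mean %.4g (point %.4g)\n",
              mean(x$draws$a), x$estimate[["a"]],
              mean(x$draws$h), x$estimate[["h"]]))
  if (any(x$draws$flagged)) {
    cat("  flagged draws:", sum(x$draws$flagged), "\n")
  }
  invisible(x)
}

#' Compare bootstrapped parameters across experimental groups
#'
#' Models the bootstrap draws of each parameter with a Gamma GLM (log
#' link) on the crossed experimental factors (species, predator size
#' class, prey size class) and their interactions, and reports F-tests via
#' analysis of deviance with type III sums of squares. Draws flagged as
#' non-identified (no-consumption resamples at the zero boundary, or
#' refits whose likelihood carried no usable curvature) are excluded with
#' a reported count. The Gamma family requires a strictly positive
#' response, so remaining draws capped at zero are replaced by the
#' smallest positive draw of that parameter (counted and reported).
#' Groups whose draws are all zero carry no information about that
#' parameter and are excluded with a warning.
#'
#' @param boots List of `fr_boot` objects, each carrying group labels
#'   (i.e. built from trials that had `species`/size-class columns).
#'
#' @return A list with elements `a` and `h`, each a deviance table (data
#'   frame: term, SS proxy via deviance F-tests, df, F, p), plus
#'   `n_zero_replaced` counts. With fewer than two groups the tables are
#'   empty data frames.
#' @export
compare_bootstrapped_params <- function(boots) {
  stopifnot(is.list(boots), all(vapply(boots, inherits, logical(1), "fr_boot")))
  empty <- data.frame(term = character(0), df = numeric(0),
                      F = numeric(0), p = numeric(0))
  if (length(boots) < 2L) {
    return(list(a = empty, h = empty, n_zero_replaced = c(a = 0L, h = 0L)))
  }
  long <- do.call(rbind, lapply(boots, function(b) {
    if (is.null(b$group)) stop("fr_boot lacks group labels", call. = FALSE)
    cbind(b$group[rep(1L, nrow(b$draws)), , drop = FALSE], b$draws)
  }))
  rownames(long) <- NULL

  factors <- intersect(c("species", "pred_size_class", "prey_size_class"),
                       names(long))
  factors <- factors[vapply(factors,
                            function(f) length(unique(long[[f]])) >= 2L,
                            logical(1))]

  n_flagged <- sum(long$flagged)
  if (n_flagged > 0) {
    warning(sprintf("%d non-identified draw(s) excluded from the comparison",
                    n_flagged), call. = FALSE)
    long <- long[!long$flagged, , drop = FALSE]
  }

  fit_one <- function(resp) {
    y <- long[[resp]]
    zero_groups <- tapply(y, interaction(long[factors], drop = TRUE),
                          function(v) all(v == 0))
    keep <- rep(TRUE, nrow(long))
    if (any(zero_groups)) {
      warning(sprintf("%d group(s) with all-zero %s draws excluded",
                      sum(zero_groups), resp), call. = FALSE)
      bad <- names(zero_groups)[zero_groups]
      keep <- !(as.character(interaction(long[factors], drop = TRUE)) %in% bad)
    }
    y <- y[keep]
    n_zero <- sum(y == 0)
    if (n_zero > 0) y[y == 0] <- min(y[y > 0])
    dat <- long[keep, factors, drop = FALSE]
    dat[] <- lapply(dat, factor)
    dat$.y <- y
    usable <- factors[vapply(factors, function(f) nlevels(dat[[f]]) >= 2L,
                             logical(1))]
    if (length(usable) == 0L) {
      return(list(tab = empty, n_zero = n_zero))
    }
    rhs <- paste(usable, collapse = " * ")
    m <- stats::glm(stats::as.formula(paste(".y ~", rhs)),
                    family = stats::Gamma(link = "log"), data = dat,
                    control = stats::glm.control(maxit = 200),
                    contrasts = lapply(stats::setNames(usable, usable),
                                       function(f) "contr.sum"))
    an <- car::Anova(m, type = 3, test.statistic = "F")
    tab <- data.frame(term = rownames(an),
                      df = an$Df,
                      F = an$F,
                      p = an[["Pr(>F)"]],
                      stringsAsFactors = FALSE)
    list(tab = tab, n_zero = n_zero)
  }

  ra <- fit_one("a")
  rh <- fit_one("h")
  list(a = ra$tab, h = rh$tab,
       n_zero_replaced = c(a = ra$n_zero, h = rh$n_zero),
       n_flagged_excluded = n_flagged)
}
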