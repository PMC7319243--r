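#' Read a trial table from CSV
#'
#' Reads the canonical trial CSV (columns `species`, `pred_size_class`,
#' `prey_size_class`, `pred_mass_g`, `prey_mass_g`, `n0`, `ne`, `t_hr`,
#' `replicate`) and validates every row: counts non-negative, `ne <= n0`,
#' positive duration, known size classes. Invalid rows abort the read with
#' a per-row error listing, so bad data never propagates silently.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return Validated trial data frame (possibly empty, with a warning).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("species", "pred_size_class", "prey_size_class",
           "pred_mass_g", "prey_mass_g", "n0", "ne", "t_hr", "replicate")
  missing_cols <- setdiff(req, names(tr))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tr) == 0L) {
    warning("trial file is empty", call. = FALSE)
    return(tr)
  }
  sizes <- c("small", "medium", "large")
  problems <- character(0)
  bad <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx)) sprintf("row %d: %s", idx, msg) else character(0)
  }
  problems <- c(
    bad(!is.finite(tr$n0) | tr$n0 <= 0 | tr$n0 != round(tr$n0),
        "n0 must be a positive integer"),
    bad(!is.finite(tr$ne) | tr$ne < 0 | tr$ne != round(tr$ne),
        "ne must be a non-negative integer"),
    bad(is.finite(tr$ne) & is.finite(tr$n0) & tr$ne > tr$n0, "ne > n0"),
    bad(!is.finite(tr$t_hr) | tr$t_hr <= 0, "t_hr must be > 0"),
    bad(!(tr$pred_size_class %in% sizes), "unknown pred_size_class"),
    bad(!(tr$prey_size_class %in% sizes), "unknown prey_size_class")
  )
  if (length(problems)) {
    stop("invalid trial rows:\n", paste(problems, collapse = "\n"),
         call. = FALSE)
  }
  tr
}

#' Write a trial table to CSV
#'
#' @param trials Trial data frame.
#' @param path Output path; written atomically (temp file + rename).
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  write_atomic_csv(trials, path)
}

write_atomic_csv <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

write_atomic_json <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline]. A seed is
#' mandatory: every stochastic stage derives its seed from it, so a
#' configuration fully determines the result bundle.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer master seed (required).
#' @param nboot Bootstrap draws per group.
#' @param alpha Significance level for response-type classification.
#' @param form Functional response form to fit.
#' @param noise Synthetic-data noise model (see [generate_trials]).
#' @param design Trial design data frame (default [fr_design]).
#' @param truths Group truth table (default [default_group_truths]).
#' @param bias_scenarios,bias_durations Bias-study grid (defaults to the
#'   standard grid; set `bias_scenarios = NULL` to skip the stage).
#' @param se_mult SE-overlap half width for the bias study.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed, nboot = 20, alpha = 0.05,
                            form = "rogers_ii", noise = "binomial",
                            design = fr_design(),
                            truths = default_group_truths(design),
                            bias_scenarios = bias_default_scenarios(),
                            bias_durations = c(0.2, 0.5, 1.0, 1.5),
                            se_mult = 1.96) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("config requires an explicit integer `seed`", call. = FALSE)
  }
  stopifnot(nboot >= 1, alpha > 0, alpha < 1)
  structure(list(out_dir = out_dir, seed = as.integer(seed), nboot = nboot,
                 alpha = alpha, form = form, noise = noise,
                 design = design, truths = truths,
                 bias_scenarios = bias_scenarios,
                 bias_durations = bias_durations, se_mult = se_mult),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic trial generation, per-group functional
#' response classification, per-group maximum-likelihood fitting,
#' bootstrap of attack rate and handling time, body-mass-ratio scaling
#' regressions per species and parameter, and the prey-depletion bias
#' study. Each stage writes its output atomically under
#' `config$out_dir`, and a machine-readable manifest (package and R
#' versions, seed, config hash, stage list, output checksums) accompanies
#' the results. A failing stage aborts with the stage name; outputs of
#' completed stages are preserved.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stages <- character(0)
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    stages <<- c(stages, name)
    res
  }

  # 1. simulate
  trials <- run_stage("simulate", {
    tr <- generate_trials(config$design, config$truths,
                          noise = config$noise, seed = config$seed)
    write_trials(tr, out("trials.csv"))
    tr
  })

  key <- interaction(trials$species, trials$pred_size_class,
                     trials$prey_size_class, drop = TRUE)
  groups <- split(trials, key)

  # 2. classify
  types <- run_stage("classify", {
    res <- lapply(groups, classify_fr, alpha = config$alpha)
    write_atomic_json(lapply(res, function(t) {
      list(type = t$type,
           first_order = as.list(t$first_order),
           second_order = as.list(t$second_order),
           aic_choice = t$aic_choice)
    }), out("classify.json"))
    res
  })

  # 3. fit
  fits <- run_stage("fit", {
    res <- lapply(groups, fit_rogers_mle, form = config$form)
    write_atomic_json(lapply(res, function(f) {
      list(form = f$form, estimate = as.list(f$coef), se = as.list(f$se),
           logLik = f$logLik, aic = f$aic, converged = f$converged,
           boundary = f$boundary)
    }), out("fits.json"))
    res
  })

  # 4. bootstrap
  boots <- run_stage("bootstrap", {
    res <- vector("list", length(groups))
    names(res) <- names(groups)
    for (i in seq_along(groups)) {
      res[[i]] <- bootstrap_fr(groups[[i]], n = config$nboot,
                               seed = config$seed + 1000L + i,
                               fit = fits[[i]])
    }
    long <- do.call(rbind, lapply(res, function(b) {
      cbind(b$group[rep(1L, nrow(b$draws)), , drop = FALSE],
            draw = seq_len(nrow(b$draws)), b$draws)
    }))
    rownames(long) <- NULL
    write_atomic_csv(long, out("bootstrap_draws.csv"))
    res
  })

  # 5. scaling
  scaling <- run_stage("scaling", {
    res <- list()
    for (sp in unique(trials$species)) {
      sp_boots <- Filter(function(b) b$group$species[1] == sp, boots)
      pts <- do.call(rbind, lapply(sp_boots, function(b) {
        ratio <- body_mass_ratio(b$group$pred_mass_g[1], b$group$prey_mass_g[1])
        ok <- b$draws[!b$draws$flagged, , drop = FALSE]  # identified draws only
        suppressWarnings(transform_params(ok, ratio))
      }))
      for (par in c("a", "h")) {
        y <- if (par == "a") pts$y_a else pts$y_h
        f <- fit_scaling(pts$x, y)
        res[[paste(sp, par, sep = ".")]] <- f
      }
    }
    write_atomic_json(lapply(res, function(f) {
      list(degree = f$degree, coef_raw = f$coef_raw,
           coef_orth = f$coef_orth, peak = f$peak, n = f$n,
           aicc_table = f$aicc_table)
    }), out("scaling.json"))
    res
  })

  # 6. bias-sim
  bias <- run_stage("bias_sim", {
    if (is.null(config$bias_scenarios)) {
      NULL
    } else {
      b <- run_bias_study(config$bias_scenarios,
                          durations = config$bias_durations,
                          se_mult = config$se_mult)
      write_atomic_csv(b, out("bias_sim.csv"))
      b
    }
  })

  # manifest: versions, seed, config hash, per-file checksums
  cfg_json <- out("config.json")
  write_atomic_json(list(seed = config$seed, nboot = config$nboot,
                         alpha = config$alpha, form = config$form,
                         noise = config$noise, se_mult = config$se_mult,
                         bias_durations = config$bias_durations),
                    cfg_json)
  files <- list.files(config$out_dir, pattern = "\\.(csv|json)$",
                      full.names = TRUE)
  files <- setdiff(files, out("manifest.json"))
  manifest <- list(
    package = "rogersfr",
    package_version = as.character(utils::packageVersion("rogersfr")),
    r_version = R.version.string,
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_json)),
    stages = stages,
    n_groups = length(groups),
    unconverged_fits = sum(!vapply(fits, function(f) f$converged, logical(1))),
    outputs = as.list(tools::md5sum(files))
  )
  names(manifest$outputs) <- basename(files)
  write_atomic_json(manifest, out("manifest.json"))

  invisible(list(trials = trials, types = types, fits = fits, boots = boots,
                 scaling = scaling, bias = bias, manifest = manifest))
}
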