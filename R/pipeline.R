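#' End-to-end analysis pipeline
#'
#' Runs a complete, seeded analysis from a single configuration: simulate
#' (or read) a trial table, fit the requested models per participant,
#' compare every model against a reference model with bootstrapped median
#' criterion differences, compute the model-free behavioral statistics, and
#' write everything — tables as CSV/JSON, figures as PDF, a manifest with
#' the configuration — into an output directory. Reruns with the same
#' configuration and seeds reproduce identical tables.
#'
#' The configuration is a named list (or the path of a YAML file holding
#' one) with fields:
#' \describe{
#'   \item{out_dir}{output directory (required).}
#'   \item{seed}{master seed; stage seeds are derived from it (default 1).}
#'   \item{experiment}{1 or 2 (default 1).}
#'   \item{models}{strategies to fit (default `c("proportional",
#'     "flexible")`); the first is the comparison reference.}
#'   \item{generate}{list with `strategy`, `theta` (named list/vector),
#'     `n_participants`, `n_trials` — used to simulate the input table.}
#'   \item{trials_file}{alternatively, an existing CSV from
#'     [write_trials()]; exactly one of `generate`/`trials_file`.}
#'   \item{n_starts}{optimization starts per fit (default 5).}
#'   \item{n_boot}{bootstrap resamples for comparisons (default 1000).}
#'   \item{n_perm}{permutations for the confound nulls (default 1000;
#'     Experiment 2 only). `0` skips the permutation stage.}
#'   \item{control}{named overrides passed to [fit_control()], e.g.
#'     `n_nodes`.}
#'   \item{figures}{write PDF figures (default TRUE).}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, a list with the fits, comparisons, behavioral
#'   summaries and output paths. Per-participant fit failures are logged to
#'   `run.log`, skipped, and reported in the returned `failures` element.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("`out_dir` is required", call. = FALSE)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", file = logf,
                                append = TRUE, sep = "")
  cat("", file = logf)

  seed <- as.integer(config$seed %||% 1L)
  experiment <- as.integer(config$experiment %||% 1L)
  models <- config$models %||% c("proportional", "flexible")
  n_starts <- as.integer(config$n_starts %||% 5L)
  n_boot <- as.integer(config$n_boot %||% 1000L)
  n_perm <- as.integer(config$n_perm %||% 1000L)
  control <- do.call(fit_control, config$control %||% list())
  log_line("pipeline start: experiment %d, models [%s], seed %d",
           experiment, paste(models, collapse = ", "), seed)

  # --- stage: simulate or load -------------------------------------------
  if (!is.null(config$generate)) {
    gen <- config$generate
    design <- design_config(
      n_trials = gen$n_trials %||% 600L,
      n_participants = gen$n_participants %||% 4L)
    gspec <- model_spec(experiment, gen$strategy %||% "flexible")
    theta <- unlist(gen$theta)
    trials <- generate_experiment(gspec, theta, design, seed = seed,
                                  control = control)
    write_trials(trials, file.path(out_dir, "trials.csv"),
                 meta = list(generating_strategy = gspec$strategy,
                             theta = as.list(theta), seed = seed,
                             design = unclass(design)))
    log_line("simulated %d trials x %d participants from %s model",
             design$n_trials, design$n_participants, gspec$strategy)
  } else if (!is.null(config$trials_file)) {
    trials <- read_trials(config$trials_file)
    log_line("loaded %d trials from %s", nrow(trials), config$trials_file)
  } else {
    stop("config needs either `generate` or `trials_file`", call. = FALSE)
  }

  # --- stage: fit ---------------------------------------------------------
  ids <- unique(trials$participant)
  specs <- lapply(models, function(m) model_spec(experiment, m))
  names(specs) <- models
  fits <- list(); failures <- character(0)
  for (m in models) {
    fits[[m]] <- list()
    for (i in seq_along(ids)) {
      tr <- trials[trials$participant == ids[i], ]
      f <- tryCatch(
        fit_model(specs[[m]], tr, n_starts = n_starts,
                  seed = seed + 131L * i + match(m, models), control = control),
        error = function(e) e)
      if (inherits(f, "error")) {
        failures <- c(failures, sprintf("%s/%s: %s", m, ids[i],
                                        conditionMessage(f)))
        log_line("FIT FAILURE %s %s: %s", m, ids[i], conditionMessage(f))
      } else {
        fits[[m]][[ids[i]]] <- f
        log_line("fit %s %s: loglik %.2f AICc %.2f", m, ids[i],
                 f$loglik, f$aicc)
      }
    }
  }
  fit_row_list <- unlist(lapply(fits, function(fm)
    lapply(fm, function(f) {
      row <- data.frame(participant = f$participant,
                        model = f$spec$strategy, loglik = f$loglik,
                        aicc = f$aicc, bic = f$bic,
                        n_trials = f$n_trials, n_starts = f$n_starts)
      for (nm in names(f$theta_hat)) row[[nm]] <- f$theta_hat[[nm]]
      for (i in seq_along(f$allocation))
        row[[paste0("alloc_", c("high", "med", "low")[i])]] <-
          f$allocation[i]
      row
    })), recursive = FALSE)
  # models differ in their free parameters; align on the column union
  all_cols <- Reduce(union, lapply(fit_row_list, names))
  fit_rows <- do.call(rbind, lapply(fit_row_list, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  }))
  utils::write.csv(fit_rows, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(unlist(fits, recursive = FALSE), function(f)
      list(participant = f$participant, strategy = f$spec$strategy,
           experiment = f$spec$experiment, theta_hat = as.list(f$theta_hat),
           allocation = f$allocation, loglik = f$loglik, aicc = f$aicc,
           bic = f$bic, n_trials = f$n_trials, n_starts = f$n_starts,
           start_loglik = f$start_loglik)),
    file.path(out_dir, "fits.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  # --- stage: compare (each model vs the reference, first in the list) ----
  comparisons <- list()
  if (length(models) > 1L) {
    ref <- models[1L]
    comp_rows <- list()
    for (m in models[-1L]) {
      common <- intersect(names(fits[[ref]]), names(fits[[m]]))
      if (length(common) < 1L) next
      cmp <- compare_models(fits[[ref]][common], fits[[m]][common],
                            n_boot = n_boot, seed = seed + 7L)
      comparisons[[m]] <- cmp
      comp_rows[[m]] <- data.frame(
        comparison = cmp$direction,
        median_delta_aicc = cmp$median_aicc,
        ci_lo_aicc = cmp$ci_aicc[1], ci_hi_aicc = cmp$ci_aicc[2],
        median_delta_bic = cmp$median_bic,
        ci_lo_bic = cmp$ci_bic[1], ci_hi_bic = cmp$ci_bic[2],
        n_participants = length(cmp$participants))
    }
    if (length(comp_rows))
      utils::write.csv(do.call(rbind, comp_rows),
                       file.path(out_dir, "comparison.csv"),
                       row.names = FALSE)
  }

  # --- stage: behavioral statistics --------------------------------------
  psum <- priority_summary(trials)
  utils::write.csv(psum$summary, file.path(out_dir, "behavior_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(psum$by_participant,
                   file.path(out_dir, "behavior_by_participant.csv"),
                   row.names = FALSE)
  correlations <- NULL; perm <- NULL
  if ("radius" %in% names(trials)) {
    correlations <- within_priority_correlation(trials)
    utils::write.csv(correlations$pooled,
                     file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    if (n_perm > 0L) {
      perm <- list(
        location = permutation_null(trials, "location", n_perm = n_perm,
                                    seed = seed + 11L),
        delay = permutation_null(trials, "delay", n_perm = n_perm,
                                 seed = seed + 13L))
      perm_tab <- rbind(perm$location$table, perm$delay$table)
      utils::write.csv(perm_tab, file.path(out_dir, "permutation.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(location = summary_permnull(perm$location),
             delay = summary_permnull(perm$delay)),
        file.path(out_dir, "permutation.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE)
    }
  }

  # --- stage: figures -----------------------------------------------------
  if (isTRUE(config$figures %||% TRUE)) {
    figdir <- file.path(out_dir, "figures")
    dir.create(figdir, showWarnings = FALSE)
    plot_to_pdf(file.path(figdir, "error_by_priority.pdf"),
                function() plot_priority_summary(psum))
    if ("flexible" %in% models && length(fits[["flexible"]]))
      plot_to_pdf(file.path(figdir, "allocation.pdf"),
                  function() plot_allocation(fits[["flexible"]]))
    if (length(comparisons))
      plot_to_pdf(file.path(figdir, "model_comparison.pdf"),
                  function() plot_comparison(comparisons))
    if (!is.null(correlations))
      plot_to_pdf(file.path(figdir, "correlations.pdf"),
                  function() plot_correlations(trials))
  }

  manifest <- list(package = "vpalloc",
                   version = as.character(utils::packageVersion("vpalloc")),
                   r_version = as.character(getRversion()),
                   seed = seed, experiment = experiment, models = models,
                   n_starts = n_starts, n_boot = n_boot, n_perm = n_perm,
                   config = config[setdiff(names(config), "control")],
                   failures = failures)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("pipeline done (%d fit failures)", length(failures))
  invisible(list(trials = trials, fits = fits, comparisons = comparisons,
                 behavior = psum, correlations = correlations,
                 permutation = perm, failures = failures,
                 out_dir = out_dir))
}

summary_permnull <- function(x) {
  list(covariate = x$covariate, n_perm = x$n_perm,
       mean_observed = mean(x$table$observed),
       mean_null_median = mean(x$table$null_median),
       signed_rank = signed_rank_vs_null(x$table$observed,
                                         x$table$null_median))
}

# ---- figures -------------------------------------------------------------

plot_to_pdf <- function(path, draw) {
  grDevices::pdf(path, width = 5, height = 4)
  on.exit(grDevices::dev.off())
  draw()
  invisible(path)
}

priority_cols <- function(pr) {
  c("0.6" = "firebrick", "0.3" = "steelblue", "0.1" = "black")[
    as.character(pr)]
}

#' Plot per-priority means with SEM error bars
#'
#' @param psum A [priority_summary()] result.
#' @param var `"error"` or `"radius"`.
#' @export
plot_priority_summary <- function(psum, var = "error") {
  sm <- psum$summary
  m <- sm[[paste0("mean_", var)]]; se <- sm[[paste0("sem_", var)]]
  se[is.na(se)] <- 0
  x <- seq_len(nrow(sm))
  graphics::plot(x, m, pch = 19, col = priority_cols(sm$priority),
                 xaxt = "n", xlab = "probe probability",
                 ylab = sprintf("%s (dva)", var),
                 ylim = range(c(m - se, m + se)),
                 main = sprintf("%s by priority", var))
  graphics::axis(1, at = x, labels = sm$priority)
  graphics::arrows(x, m - se, x, m + se, angle = 90, code = 3,
                   length = 0.04, col = priority_cols(sm$priority))
}

#' Plot fitted Flexible allocations against the probe probabilities
#'
#' @param flex_fits List of Flexible-model [fit_model()] results.
#' @export
plot_allocation <- function(flex_fits) {
  A <- t(vapply(flex_fits, function(f) f$allocation, numeric(3)))
  graphics::matplot(1:3, t(A), type = "p", pch = 19, col = "grey30",
                    xaxt = "n", xlab = "priority condition",
                    ylab = "proportion allocated", ylim = c(0, 1),
                    main = "Flexible-model allocation")
  graphics::axis(1, at = 1:3, labels = c("0.6", "0.3", "0.1"))
  graphics::segments(1:3 - 0.2, c(0.6, 0.3, 0.1), 1:3 + 0.2,
                     c(0.6, 0.3, 0.1), lwd = 3,
                     col = priority_cols(c(0.6, 0.3, 0.1)))
}

#' Dot-and-median plot of per-participant criterion differences
#'
#' @param comparisons List of [compare_models()] results.
#' @export
plot_comparison <- function(comparisons) {
  k <- length(comparisons)
  graphics::plot(NULL, xlim = c(0.5, k + 0.5),
                 ylim = range(unlist(lapply(comparisons, `[[`,
                                            "delta_aicc"))),
                 xaxt = "n", xlab = "", ylab = "delta AICc",
                 main = "Model comparison")
  graphics::axis(1, at = seq_len(k),
                 labels = vapply(comparisons, `[[`, character(1),
                                 "direction"), cex.axis = 0.7)
  for (i in seq_len(k)) {
    d <- comparisons[[i]]$delta_aicc
    graphics::points(stats::runif(length(d), i - 0.12, i + 0.12), d,
                     pch = 19, col = "grey50")
    graphics::rect(i - 0.2, comparisons[[i]]$ci_aicc[1], i + 0.2,
                   comparisons[[i]]$ci_aicc[2],
                   border = "grey70")
    graphics::segments(i - 0.2, comparisons[[i]]$median_aicc, i + 0.2,
                       comparisons[[i]]$median_aicc, lwd = 2)
  }
  graphics::abline(h = 0, lty = 2)
}

#' Scatter of standardized error vs radius by priority
#'
#' @param trials Experiment-2-style trial data frame.
#' @export
plot_correlations <- function(trials) {
  tz <- standardize_trials(trials)
  graphics::plot(tz$z_radius, tz$z_error,
                 col = priority_cols(tz$priority), pch = 19, cex = 0.4,
                 xlab = "z(radius)", ylab = "z(error)",
                 main = "error vs wager radius (standardized)")
  graphics::legend("topleft", legend = c(0.6, 0.3, 0.1), pch = 19,
                   col = priority_cols(c(0.6, 0.3, 0.1)), bty = "n",
                   title = "priority")
}
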