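#' Task design configuration
#'
#' Encodes the priority memory-guided saccade design: on each trial four
#' targets appear, one per visual quadrant, at about 10 dva eccentricity
#' (with up to 1 dva of radial jitter) and polar angles drawn from a 10
#' degree grid that avoids the cardinal axes. The quadrants carry probe
#' probabilities 0.6 / 0.3 / 0.1 / 0.0; after a delay of 1000 to 4000 ms
#' (500 ms steps, equiprobable) one quadrant is cued and the participant
#' saccades to the remembered location.
#'
#' @param probe_probs Probe probabilities of the three probed conditions.
#' @param n_trials Trials per participant (default 600).
#' @param n_participants Number of synthetic participants.
#' @param eccentricity Nominal target eccentricity, dva.
#' @param jitter Radial jitter half-width, dva.
#' @param angle_step Polar-angle grid spacing, degrees.
#' @param delays Possible delays, ms.
#' @param dropout Fraction of trials dropped uniformly at random, emulating
#'   post-hoc screening exclusions (the task's screening removed 1-7% of
#'   trials per participant); default 0, i.e. post-screening data.
#' @param delay_decay Optional testing hook: precision mean is multiplied by
#'   `exp(-delay_decay * delay / 1000)`, giving delay-dependent precision.
#'   Default 0 (no delay effect) — the generator emulates coupling driven by
#'   precision fluctuations alone.
#' @return An object of class `vp_design`.
#' @export
design_config <- function(probe_probs = c(0.6, 0.3, 0.1), n_trials = 600L,
                          n_participants = 1L, eccentricity = 10,
                          jitter = 1, angle_step = 10,
                          delays = seq(1000, 4000, by = 500),
                          dropout = 0, delay_decay = 0) {
  probe_probs <- check_probe_probs(probe_probs)
  if (abs(sum(probe_probs) - 1) > 1e-8)
    stop("probed-condition probabilities must sum to 1", call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("`dropout` must be in [0, 1)", call. = FALSE)
  structure(list(probe_probs = probe_probs, n_trials = as.integer(n_trials),
                 n_participants = as.integer(n_participants),
                 eccentricity = eccentricity, jitter = jitter,
                 angle_step = angle_step, delays = delays,
                 dropout = dropout, delay_decay = delay_decay),
            class = "vp_design")
}

#' @export
print.vp_design <- function(x, ...) {
  cat(sprintf(paste0(
    "Priority saccade design: %d participant(s) x %d trials\n",
    "  probe probabilities %s; targets at %g +/- %g dva, %g-degree angle grid\n",
    "  delays %g-%g ms\n"),
    x$n_participants, x$n_trials,
    paste(x$probe_probs, collapse = "/"), x$eccentricity, x$jitter,
    x$angle_step, min(x$delays), max(x$delays)))
  invisible(x)
}

#' Generate target locations
#'
#' Draws, for each of `n` trials, four targets — one per visual quadrant —
#' with polar angles sampled from the design's angular grid (cardinal axes
#' excluded, so every angle is at least `angle_step` from 0/90/180/270) and
#' eccentricity jittered radially within `eccentricity +/- jitter` dva.
#'
#' @param design A [design_config()].
#' @param n Number of trials.
#' @param seed Integer seed.
#' @return Data frame with one row per target: `trial`, `quadrant`,
#'   `angle_deg`, `ecc`, `x`, `y`.
#' @export
generate_targets <- function(design, n, seed = NULL) {
  stopifnot(inherits(design, "vp_design"))
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(0, 350, by = design$angle_step)
  grid <- grid[grid %% 90 != 0]             # avoid cardinal axes
  quadrant <- floor(grid / 90) + 1L
  rows <- n * 4L
  q <- rep(1:4, times = n)
  ang <- vapply(q, function(qq) sample(grid[quadrant == qq], 1L), numeric(1))
  ecc <- design$eccentricity +
    stats::runif(rows, -design$jitter, design$jitter)
  data.frame(trial = rep(seq_len(n), each = 4L), quadrant = q,
             angle_deg = ang, ecc = ecc,
             x = ecc * cos(ang * pi / 180), y = ecc * sin(ang * pi / 180))
}

# draw one radius per trial from the softmax choice mass given that trial's J
sample_radii <- function(J, lam, payoff, r_grid) {
  P <- exp(softmax_radius_logmass(J, lam, payoff, r_grid))
  u <- stats::runif(length(J))
  idx <- vapply(seq_along(J),
                function(i) which(cumsum(P[i, ]) >= u[i])[1L], integer(1))
  idx[is.na(idx)] <- length(r_grid)
  r_grid[idx]
}

#' Simulate a complete experiment from a model
#'
#' Generates trial tables faithful to the task design and the VP generative
#' process: a probed condition drawn with the probe probabilities, a delay
#' drawn uniformly from the design's levels, targets from
#' [generate_targets()], precision drawn from the condition's gamma
#' distribution (mean `p_c * Jbar_total`, scale `tau`), and the saccade
#' endpoint from the isotropic 2-D Gaussian with per-axis sd `J^(-1/2)`.
#' For Experiment 2 the wager radius is drawn from the softmax expected-
#' utility density at the trial's precision and points are scored by the
#' payoff rule with the hit indicator.
#'
#' @param spec A [model_spec()]; its strategy determines the allocation
#'   (computing it from `theta` for the planner strategies).
#' @param theta Named generating parameter vector for the spec.
#' @param design A [design_config()].
#' @param seed Integer seed; a fixed seed reproduces the table exactly.
#' @param keep_latent Keep the latent precision column `J` (testing only).
#' @param control A [fit_control()] (radius grid, payoff, planner controls).
#' @return Trial data frame: `participant`, `priority`, `target_x`,
#'   `target_y`, `endpoint_x`, `endpoint_y`, `error`, `delay`, and for
#'   Experiment 2 `radius` and `points`.
#' @export
generate_experiment <- function(spec, theta, design = design_config(),
                                seed = NULL, keep_latent = FALSE,
                                control = fit_control()) {
  stopifnot(inherits(spec, "vp_model_spec"), inherits(design, "vp_design"))
  theta <- check_theta(theta, spec)
  ctl <- control
  ctl$probe_probs <- design$probe_probs
  p_alloc <- allocation_for(spec, theta, ctl)
  if (is.null(p_alloc))
    stop("invalid theta: expected loss diverges at every allocation",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", design$n_participants)
  for (s in seq_len(design$n_participants)) {
    n <- design$n_trials
    tg <- generate_targets(design, n)
    cond_idx <- sample.int(length(design$probe_probs), n, replace = TRUE,
                           prob = design$probe_probs)
    # priorities are assigned to quadrants by a fresh permutation each trial
    probed_quadrant <- vapply(seq_len(n), function(i)
      sample.int(4L, 4L)[cond_idx[i]], integer(1))
    probed <- tg[4L * (seq_len(n) - 1L) + probed_quadrant, ]
    delay <- sample(design$delays, n, replace = TRUE)
    Jbar_i <- p_alloc[cond_idx] * theta[["Jbar_total"]]
    if (design$delay_decay != 0)
      Jbar_i <- Jbar_i * exp(-design$delay_decay * delay / 1000)
    J <- stats::rgamma(n, shape = Jbar_i / theta[["tau"]],
                       scale = theta[["tau"]])
    sd <- 1 / sqrt(J)
    ex <- probed$x + stats::rnorm(n, sd = sd)
    ey <- probed$y + stats::rnorm(n, sd = sd)
    err <- sqrt((ex - probed$x)^2 + (ey - probed$y)^2)
    df <- data.frame(participant = sprintf("S%02d", s),
                     priority = design$probe_probs[cond_idx],
                     target_x = probed$x, target_y = probed$y,
                     endpoint_x = ex, endpoint_y = ey,
                     error = err, delay = delay)
    if (spec$experiment == 2) {
      df$radius <- sample_radii(J, theta[["lam"]], ctl$payoff, ctl$r_grid)
      df$points <- wager_points(df$radius, ctl$payoff) * (err <= df$radius)
    }
    if (keep_latent) df$J <- J
    if (design$dropout > 0)
      df <- df[stats::runif(n) >= design$dropout, , drop = FALSE]
    out[[s]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

trial_schema <- function() {
  list(required = c("participant", "priority", "target_x", "target_y",
                    "endpoint_x", "endpoint_y", "error", "delay"),
       optional = c("radius", "points", "J"),
       version = "1.0")
}

#' Write trials to CSV (with optional JSON sidecar)
#'
#' @param trials Trial data frame.
#' @param path Output CSV path.
#' @param meta Optional list (design, generating parameters, ...) written to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, meta = NULL) {
  utils::write.csv(trials, path, row.names = FALSE)
  if (!is.null(meta)) {
    meta$schema_version <- trial_schema()$version
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read and validate a trial table
#'
#' Checks the column schema and the internal consistency of the recorded
#' error against the target/endpoint coordinates; a trial whose `error`
#' disagrees with the coordinates by more than `tol` raises an error naming
#' the column and row.
#'
#' @param path CSV file written by [write_trials()] (or conformant).
#' @param tol Consistency tolerance, dva.
#' @return Trial data frame.
#' @export
read_trials <- function(path, tol = 1e-6) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  sch <- trial_schema()
  miss <- setdiff(sch$required, names(trials))
  if (length(miss))
    stop("trial file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  num_cols <- setdiff(c(sch$required, intersect(sch$optional, names(trials))),
                      "participant")
  for (cc in num_cols) {
    bad <- which(!is.finite(as.numeric(trials[[cc]])))
    if (length(bad))
      stop(sprintf("column `%s`, row %d: non-finite value", cc, bad[1L]),
           call. = FALSE)
  }
  d <- sqrt((trials$target_x - trials$endpoint_x)^2 +
              (trials$target_y - trials$endpoint_y)^2)
  bad <- which(abs(d - trials$error) > tol)
  if (length(bad))
    stop(sprintf(
      "column `error`, row %d: value %.6g inconsistent with coordinates (%.6g)",
      bad[1L], trials$error[bad[1L]], d[bad[1L]]), call. = FALSE)
  trials
}
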