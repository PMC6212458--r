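#' Euclidean estimation error
#'
#' Distance, in dva, between the true and reported target locations.
#'
#' @param target,response Length-2 vectors or n x 2 matrices of (x, y)
#'   coordinates in dva.
#' @return Nonnegative error magnitude(s).
#' @export
euclidean_error <- function(target, response) {
  target <- rbind(target); response <- rbind(response)
  if (!all(is.finite(target)) || !all(is.finite(response)))
    stop("coordinates must be finite", call. = FALSE)
  if (!identical(dim(target), dim(response)) || ncol(target) != 2L)
    stop("`target` and `response` must both be (x, y) pairs", call. = FALSE)
  unname(sqrt(rowSums((target - response)^2)))
}

# per-participant z-scores of error (and radius, when present), computed
# over all of a participant's trials before any aggregation by priority
standardize_trials <- function(trials) {
  zfun <- function(x) (x - mean(x)) / stats::sd(x)
  trials$z_error <- stats::ave(trials$error, trials$participant, FUN = zfun)
  if ("radius" %in% names(trials))
    trials$z_radius <- stats::ave(trials$radius, trials$participant,
                                  FUN = zfun)
  trials
}

#' Per-priority behavioral summary
#'
#' Means of estimation error (and wager radius, when present) by priority:
#' first averaged within participant, then summarized across participants
#' as mean +/- SEM. Flags whether both measures decrease monotonically with
#' increasing priority, the qualitative signature of priority-dependent
#' resource allocation. The per-participant x priority table is returned so
#' that routine repeated-measures tests can be run externally.
#'
#' @param trials Trial data frame with `participant`, `priority`, `error`
#'   and optionally `radius`.
#' @return List of class `vp_priority_summary`: `summary` (per-priority
#'   mean/SEM), `by_participant`, and `monotonic` flags.
#' @export
priority_summary <- function(trials) {
  check_trials(trials)
  pr <- sort(unique(trials$priority), decreasing = TRUE)
  counts <- table(trials$priority)
  if (any(counts == 0) || length(pr) < 2L)
    stop("every priority condition needs at least one trial", call. = FALSE)
  vars <- intersect(c("error", "radius"), names(trials))
  bp <- stats::aggregate(trials[vars],
                         by = list(participant = trials$participant,
                                   priority = trials$priority), mean)
  n_sub <- length(unique(bp$participant))
  sm <- do.call(rbind, lapply(pr, function(p) {
    rows <- bp[bp$priority == p, , drop = FALSE]
    out <- data.frame(priority = p, n_participants = n_sub)
    for (v in vars) {
      out[[paste0("mean_", v)]] <- mean(rows[[v]])
      out[[paste0("sem_", v)]] <- stats::sd(rows[[v]]) / sqrt(n_sub)
    }
    out
  }))
  mono <- vapply(vars, function(v) {
    m <- sm[[paste0("mean_", v)]]      # rows ordered by decreasing priority
    all(diff(m) > 0)                   # value grows as priority drops
  }, logical(1))
  structure(list(summary = sm, by_participant = bp, monotonic = mono),
            class = "vp_priority_summary")
}

#' @export
print.vp_priority_summary <- function(x, ...) {
  cat("Per-priority summary (mean +/- SEM across participants):\n")
  print(x$summary, row.names = FALSE)
  cat("monotonically decreasing with priority:",
      paste(sprintf("%s = %s", names(x$monotonic), x$monotonic),
            collapse = ", "), "\n")
  invisible(x)
}

#' Within-priority error-radius correlations
#'
#' Spearman rank correlation between estimation error and wager radius
#' inside each priority condition: pooled across participants after
#' per-participant standardization (mean 0, sd 1, removing between-subject
#' offsets), and per participant on the raw values. A positive correlation
#' is the model's signature of a shared latent precision driving both
#' measures. Cells with fewer than 3 trials are omitted with a warning.
#'
#' @param trials Experiment-2-style trial data frame (needs `radius`).
#' @return List with `pooled` (priority, rho, n) and `per_participant`
#'   (participant, priority, rho, n) data frames.
#' @export
within_priority_correlation <- function(trials) {
  check_trials(trials, need_radius = TRUE)
  tz <- standardize_trials(trials)
  pr <- sort(unique(tz$priority), decreasing = TRUE)
  pooled <- do.call(rbind, lapply(pr, function(p) {
    d <- tz[tz$priority == p, ]
    data.frame(priority = p,
               rho = stats::cor(d$z_error, d$z_radius, method = "spearman"),
               n = nrow(d))
  }))
  cells <- expand.grid(participant = unique(tz$participant), priority = pr,
                       stringsAsFactors = FALSE)
  per <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    d <- tz[tz$participant == cells$participant[i] &
              tz$priority == cells$priority[i], ]
    if (nrow(d) < 3L) {
      warning(sprintf("cell %s x %g has < 3 trials; omitted",
                      cells$participant[i], cells$priority[i]),
              call. = FALSE)
      return(NULL)
    }
    data.frame(participant = cells$participant[i],
               priority = cells$priority[i],
               rho = stats::cor(d$error, d$radius, method = "spearman"),
               n = nrow(d))
  }))
  list(pooled = pooled, per_participant = per)
}

angle_bin_of <- function(x, y, width) {
  ang <- (atan2(y, x) * 180 / pi) %% 360
  floor(ang / width)
}

#' Stratified permutation null for the error-radius correlation
#'
#' Tests whether the within-priority error-radius correlation survives
#' controls for stimulus location or delay. For each participant x priority
#' cell, wager radii are permuted only among trials sharing the same
#' covariate stratum — the exact delay value, or the same polar-angle bin
#' (default 10 degrees, the design's angular grid) — which preserves any
#' covariate-driven association while destroying the trial-level coupling.
#' The Spearman correlation is recomputed for each permutation.
#'
#' @param trials Experiment-2-style trial data frame.
#' @param covariate `"location"` or `"delay"`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param angle_bin Polar-angle bin width in degrees (location strata).
#' @return Object of class `vp_permnull`: `table` with one row per
#'   participant x priority (observed rho, null median, null 97.5th
#'   percentile, permutation p-value) and `null`, the named list of
#'   permutation correlation vectors.
#' @export
permutation_null <- function(trials, covariate = c("location", "delay"),
                             n_perm = 1000L, seed = NULL, angle_bin = 10) {
  covariate <- match.arg(covariate)
  check_trials(trials, need_radius = TRUE)
  if (!"delay" %in% names(trials) && covariate == "delay")
    stop("`delay` column required for the delay-stratified null",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pr <- sort(unique(trials$priority), decreasing = TRUE)
  ids <- unique(trials$participant)
  rows <- list(); nulls <- list()
  for (id in ids) for (p in pr) {
    d <- trials[trials$participant == id & trials$priority == p, ]
    if (nrow(d) < 3L) next
    strata <- if (covariate == "delay") factor(d$delay)
              else factor(angle_bin_of(d$target_x, d$target_y, angle_bin))
    if (any(table(strata) == 1L))
      warning(sprintf(
        "%s x %g: %d singleton stratum(a) contribute no permutation",
        id, p, sum(table(strata) == 1L)), call. = FALSE)
    obs <- stats::cor(d$error, d$radius, method = "spearman")
    shuffle <- function(v) v[sample.int(length(v))]  # length-1 safe
    null <- vapply(seq_len(n_perm), function(b) {
      r_perm <- stats::ave(d$radius, strata, FUN = shuffle)
      stats::cor(d$error, r_perm, method = "spearman")
    }, numeric(1))
    key <- sprintf("%s|%g", id, p)
    nulls[[key]] <- null
    rows[[key]] <- data.frame(
      participant = id, priority = p, covariate = covariate,
      n_trials = nrow(d), n_perm = n_perm, observed = obs,
      null_median = stats::median(null),
      null_q975 = stats::quantile(null, 0.975, names = FALSE),
      p_value = (1 + sum(null >= obs)) / (n_perm + 1))
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 null = nulls, covariate = covariate, n_perm = n_perm),
            class = "vp_permnull")
}

#' @export
print.vp_permnull <- function(x, ...) {
  cat(sprintf(
    "Stratified permutation null (%s, %d permutations, %d cells):\n",
    x$covariate, x$n_perm, nrow(x$table)))
  cat(sprintf(
    "  observed rho: mean %.3f; null medians: mean %.4f; %d/%d cells with p < 0.025\n",
    mean(x$table$observed), mean(x$table$null_median),
    sum(x$table$p_value < 0.025), nrow(x$table)))
  invisible(x)
}

#' Wilcoxon signed-rank test of observed correlations against null medians
#'
#' Paired signed-rank test comparing each participant's observed
#' within-priority correlation to the median of its stratified permutation
#' null. All-zero differences are reported as a degenerate case with
#' p = 1 rather than an error.
#'
#' @param observed,null_median Paired numeric vectors (length >= 5).
#' @return List with `statistic`, `p_value`, `n`, `degenerate`.
#' @export
signed_rank_vs_null <- function(observed, null_median) {
  if (length(observed) != length(null_median) || length(observed) < 5L)
    stop("need paired vectors of equal length >= 5", call. = FALSE)
  diffs <- observed - null_median
  if (all(diffs == 0))
    return(list(statistic = NA_real_, p_value = 1, n = length(diffs),
                degenerate = TRUE))
  wt <- suppressWarnings(stats::wilcox.test(observed, null_median,
                                            paired = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = length(diffs), degenerate = FALSE)
}
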