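#' @name allocation
#' @title Resource allocation strategies over priority conditions
#'
#' @description
#' Four strategies map the experiment's probe probabilities and the observer's
#' parameters to a point on the allocation simplex: the proportions
#' `p = (p_high, p_med, p_low)` of the total mean precision `Jbar_total`
#' assigned to the three probed priority conditions (the never-probed quadrant
#' receives nothing and is excluded from the simplex). The condition-level
#' precision distribution is then `Gamma(mean = p_i * Jbar_total, scale = tau)`.
#'
#' * **Proportional**: allocation equals probe probability.
#' * **Flexible**: the proportions are free parameters.
#' * **Minimizing Error (ME)**: allocation minimizes the probe-probability
#'   weighted expected estimation error raised to the power `beta`.
#' * **Maximizing Points (MP)**: allocation maximizes expected wager points
#'   under the payoff rule, assuming a noiseless wager at known precision.
NULL

# probe probabilities over the probed conditions; zero entries are allowed
# (an excluded condition) and simply receive zero allocation
check_probe_probs <- function(t) {
  if (!is.numeric(t) || length(t) < 2L || any(!is.finite(t)) || any(t < 0) ||
      sum(t) <= 0)
    stop("probe probabilities must be nonnegative with a positive sum",
         call. = FALSE)
  t
}

check_allocation <- function(p) {
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-10)
    stop("allocation must be a simplex point (nonnegative, summing to 1)",
         call. = FALSE)
  pmax(p, 0)
}

#' Proportional allocation
#'
#' Resource proportional to probe probability, renormalized over the probed
#' conditions. With the task's probabilities (0.6, 0.3, 0.1) the allocation
#' is exactly (0.6, 0.3, 0.1).
#'
#' @param t Probe probabilities over the probed conditions.
#' @return Allocation proportions summing to 1.
#' @export
proportional_allocation <- function(t = c(0.6, 0.3, 0.1)) {
  t <- check_probe_probs(t)
  check_allocation(t / sum(t))
}

#' Flexible allocation
#'
#' The proportions allocated to the high- and medium-priority conditions are
#' free parameters; the low-priority condition receives the remainder.
#'
#' @param p_high,p_med Proportions for the high and medium conditions;
#'   both >= 0 with `p_high + p_med <= 1`.
#' @return Allocation `(p_high, p_med, 1 - p_high - p_med)`.
#' @export
flexible_allocation <- function(p_high, p_med) {
  stopifnot_scalar(p_high, "p_high", nonneg = TRUE)
  stopifnot_scalar(p_med, "p_med", nonneg = TRUE)
  if (p_high + p_med > 1 + 1e-12)
    stop("`p_high + p_med` must not exceed 1", call. = FALSE)
  check_allocation(c(p_high, p_med, max(0, 1 - p_high - p_med)))
}

# ---- simplex optimization ------------------------------------------------

# stick-breaking bijection between the open simplex and R^(n-1);
# near-vertex points (remainders approaching 0) are clamped so the
# transform always returns finite coordinates
simplex_to_z <- function(p) {
  p <- pmax(p, 1e-10)
  p <- p / sum(p)
  z <- numeric(length(p) - 1L)
  rem <- 1
  for (i in seq_along(z)) {
    frac <- p[i] / max(rem, 1e-12)
    z[i] <- stats::qlogis(min(max(frac, 1e-9), 1 - 1e-9))
    rem <- rem - p[i]
  }
  z
}

z_to_simplex <- function(z) {
  n <- length(z) + 1L
  p <- numeric(n)
  rem <- 1
  for (i in seq_along(z)) {
    p[i] <- rem * stats::plogis(z[i])
    rem <- rem - p[i]
  }
  p[n] <- rem
  p
}

default_simplex_starts <- function(n, n_starts) {
  if (n == 3L) {
    S <- rbind(c(1, 1, 1) / 3,
               c(0.6, 0.2, 0.2), c(0.2, 0.6, 0.2), c(0.2, 0.2, 0.6),
               c(0.45, 0.45, 0.10), c(0.45, 0.10, 0.45), c(0.10, 0.45, 0.45),
               c(0.6, 0.3, 0.1), c(0.1, 0.3, 0.6), c(0.8, 0.1, 0.1))
  } else {
    S <- matrix(1 / n, 1L, n)
    for (i in seq_len(n)) {
      s <- rep(0.3 / (n - 1), n); s[i] <- 0.7
      S <- rbind(S, s)
    }
  }
  S[rep_len(seq_len(nrow(S)), n_starts), , drop = FALSE]
}

# multistart Nelder-Mead minimization of fn(p) over the simplex;
# ties broken toward the lexicographically smallest optimum
optimize_simplex <- function(fn, n = 3L, n_starts = 10L, starts = NULL,
                             maxit = 500L, reltol = 1e-10) {
  starts <- starts %||% default_simplex_starts(n, n_starts)
  obj_z <- function(z) {
    v <- tryCatch(fn(pmax(z_to_simplex(z), 1e-10)),
                  error = function(e) Inf)
    if (!is.finite(v)) 1e15 else v
  }
  best <- NULL
  cand_p <- list()
  cand_v <- numeric(0)
  for (s in seq_len(nrow(starts))) {
    z0 <- simplex_to_z(starts[s, ])
    fit <- stats::optim(z0, obj_z, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    cand_p[[s]] <- z_to_simplex(fit$par)
    cand_v[s] <- fit$value
  }
  vmin <- min(cand_v)
  ties <- which(cand_v <= vmin + max(1e-9, abs(vmin) * 1e-9))
  P <- do.call(rbind, cand_p[ties])
  pick <- do.call(order, as.data.frame(P))[1L]
  list(p = check_allocation(P[pick, ] / sum(P[pick, ])), value = vmin,
       start_values = cand_v)
}

# ---- Minimizing Error ----------------------------------------------------

#' Probe-probability-weighted expected loss of an allocation
#'
#' The objective minimized by the ME observer:
#' `sum_i t_i * E[eps^beta | Jbar = p_i * Jbar_total, tau]`, using the
#' closed-form power moment of the VP error distribution. Returns `Inf` when
#' any condition's gamma shape `p_i * Jbar_total / tau` is at or below
#' `beta / 2` (divergent expected loss).
#'
#' @param p Allocation proportions (simplex point).
#' @param Jbar_total Total mean precision resource (dva^-2).
#' @param tau Gamma scale (dva^-2).
#' @param beta Loss exponent; > 0.
#' @param t Probe probabilities.
#' @return Weighted expected loss (dva^beta), or `Inf` if infeasible.
#' @export
me_objective <- function(p, Jbar_total, tau, beta, t = c(0.6, 0.3, 0.1)) {
  t <- check_probe_probs(t)
  k <- p * Jbar_total / tau
  if (any(k <= beta / 2)) return(Inf)
  E <- 2^(beta / 2) * gamma(1 + beta / 2) * tau^(-beta / 2) *
    exp(lgamma(k - beta / 2) - lgamma(k))
  sum(t * E)
}

#' Error-minimizing allocation
#'
#' Finds the allocation minimizing the probe-probability-weighted expected
#' error to the power `beta` ([me_objective()]) by multistart Nelder-Mead on
#' the stick-breaking transform of the simplex. In the limit of no precision
#' variability (`tau -> 0`) with `beta = 2` the optimum is the square-root
#' rule `p_i` proportional to `sqrt(t_i)` — flatter than proportional, i.e.
#' underallocating to high- and overallocating to low-priority items.
#'
#' @param Jbar_total Total mean precision (dva^-2).
#' @param tau Gamma scale (dva^-2).
#' @param beta Loss exponent; > 0.
#' @param t Probe probabilities.
#' @param n_starts Number of interior multistart points (default 10).
#' @param maxit Evaluation cap of each simplex search.
#' @param reltol Convergence tolerance of the simplex search.
#' @return Allocation proportions.
#' @export
minimize_error_allocation <- function(Jbar_total, tau, beta,
                                      t = c(0.6, 0.3, 0.1), n_starts = 10L,
                                      maxit = 500L, reltol = 1e-10) {
  stopifnot_scalar(Jbar_total, "Jbar_total", positive = TRUE)
  stopifnot_scalar(tau, "tau", positive = TRUE)
  stopifnot_scalar(beta, "beta", positive = TRUE)
  t <- check_probe_probs(t)
  n <- length(t)
  if (Jbar_total / tau <= n * beta / 2)
    stop("infeasible: total resource too small for finite expected loss ",
         "at any allocation (need Jbar_total/tau > n * beta / 2)",
         call. = FALSE)
  optimize_simplex(function(p) me_objective(p, Jbar_total, tau, beta, t),
                   n = n, n_starts = n_starts, maxit = maxit,
                   reltol = reltol)$p
}

# ---- Maximizing Points ---------------------------------------------------

#' Expected wager points at known precision, optimized over radius
#'
#' `mp_value(Jbar, ...)` is the expected (over the gamma distribution of J)
#' maximum expected utility `E_J[max_r EU(r; J)]` for one item whose mean
#' precision is `Jbar`: the value, in points, the MP planner attaches to
#' allocating `Jbar` to an item. The inner maximization over r is noiseless
#' and evaluated on a fine radius grid.
#'
#' @param Jbar Mean precision for the item (dva^-2).
#' @param tau Gamma scale (dva^-2).
#' @param payoff A [payoff_rule()].
#' @param n_nodes Quadrature nodes over J.
#' @param r_max,r_step Inner maximization grid, dva.
#' @return Expected points.
#' @export
mp_value <- function(Jbar, tau, payoff = payoff_rule(), n_nodes = 200,
                     r_max = 10, r_step = 0.01) {
  g <- precision_grid(precision_dist(Jbar, tau), n_nodes = n_nodes)
  r <- seq(r_step, r_max, by = r_step)
  U <- wager_points(r, payoff)
  EU <- sweep(-expm1(-outer(g$J, r^2 / 2)), 2L, U, `*`)
  eumax <- EU[cbind(seq_along(g$J), max.col(EU, ties.method = "first"))]
  sum(g$w * eumax)
}

#' Probe-probability-weighted expected points of an allocation
#'
#' The objective maximized by the MP observer:
#' `sum_i t_i * mp_value(p_i * Jbar_total, tau)`.
#'
#' @inheritParams me_objective
#' @param payoff A [payoff_rule()].
#' @param n_nodes,r_max,r_step Passed to [mp_value()].
#' @return Expected points per trial.
#' @export
mp_objective <- function(p, Jbar_total, tau, t = c(0.6, 0.3, 0.1),
                         payoff = payoff_rule(), n_nodes = 200,
                         r_max = 10, r_step = 0.01) {
  t <- check_probe_probs(t)
  v <- vapply(pmax(p, 1e-10) * Jbar_total, mp_value, numeric(1),
              tau = tau, payoff = payoff, n_nodes = n_nodes,
              r_max = r_max, r_step = r_step)
  sum(t * v)
}

#' Points-maximizing allocation
#'
#' Finds the allocation maximizing expected wager points ([mp_objective()]).
#' Because the payoff saturates, points are won mostly on items remembered
#' well: at low resource budgets the MP observer concentrates resource on
#' high-probability items and largely ignores the low-priority one —
#' qualitatively opposite to the flattening of the ME strategy.
#'
#' @inheritParams minimize_error_allocation
#' @param payoff A [payoff_rule()].
#' @param n_nodes,r_max,r_step Passed to [mp_value()].
#' @param starts Optional matrix of simplex starting points overriding the
#'   default interior set (one row per start).
#' @return Allocation proportions.
#' @export
maximize_points_allocation <- function(Jbar_total, tau,
                                       t = c(0.6, 0.3, 0.1),
                                       payoff = payoff_rule(),
                                       n_starts = 10L, n_nodes = 200,
                                       r_max = 10, r_step = 0.01,
                                       maxit = 500L, reltol = 1e-10,
                                       starts = NULL) {
  stopifnot_scalar(Jbar_total, "Jbar_total", positive = TRUE)
  stopifnot_scalar(tau, "tau", positive = TRUE)
  t <- check_probe_probs(t)
  optimize_simplex(
    function(p) -mp_objective(p, Jbar_total, tau, t, payoff,
                              n_nodes = n_nodes, r_max = r_max,
                              r_step = r_step),
    n = length(t), n_starts = n_starts, maxit = maxit, reltol = reltol,
    starts = starts)$p
}
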