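#' Post-decision wager payoff rule
#'
#' Points awarded when the true target lies inside the wager circle decay
#' exponentially with the circle radius: `alpha * exp(-gamma_decay * r)`.
#' The task used `alpha = 120` points and `gamma_decay = 0.4` per dva, so a
#' zero-radius circle is worth 120 points and a miss is worth nothing.
#'
#' @param alpha Maximum points at radius 0 (default 120).
#' @param gamma_decay Decay rate per dva of radius (default 0.4).
#' @return An object of class `vp_payoff`.
#' @export
payoff_rule <- function(alpha = 120, gamma_decay = 0.4) {
  stopifnot_scalar(alpha, "alpha", positive = TRUE)
  stopifnot_scalar(gamma_decay, "gamma_decay", positive = TRUE)
  structure(list(alpha = alpha, gamma_decay = gamma_decay),
            class = "vp_payoff")
}

#' @export
print.vp_payoff <- function(x, ...) {
  cat(sprintf("Wager payoff: %g * exp(-%g * r) points on a hit\n",
              x$alpha, x$gamma_decay))
  invisible(x)
}

#' Points for a wager circle of a given radius (if the target is inside)
#'
#' @param r Circle radius/radii, dva; >= 0.
#' @param payoff A [payoff_rule()].
#' @return Points (dimensionless), strictly decreasing in `r`.
#' @export
wager_points <- function(r, payoff = payoff_rule()) {
  stopifnot(inherits(payoff, "vp_payoff"))
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0))
    stop("`r` must be finite and >= 0", call. = FALSE)
  payoff$alpha * exp(-payoff$gamma_decay * r)
}

#' Probability that the target falls inside the wager circle
#'
#' The circle is centered on the saccade endpoint and the endpoint-target
#' distance is Rayleigh with scale `J^(-1/2)`, so the hit probability is the
#' Rayleigh CDF `1 - exp(-J * r^2 / 2)`.
#'
#' @param r Circle radius/radii, dva; >= 0.
#' @param J Precision (dva^-2); > 0.
#' @return Hit probability in `[0, 1)`, nondecreasing in both arguments.
#' @export
hit_probability <- function(r, J) {
  stopifnot_scalar(J, "J", positive = TRUE)
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0))
    stop("`r` must be finite and >= 0", call. = FALSE)
  -expm1(-J * r^2 / 2)
}

#' Expected utility of a wager radius
#'
#' The observer knows the trial's precision J and multiplies the points the
#' radius would earn by the probability the target lies inside the circle:
#' `EU(r; J) = points(r) * hit_probability(r, J)`. EU vanishes at `r = 0`
#' (certain miss) and as `r -> Inf` (worthless circle), with an interior
#' maximum that shrinks as J grows.
#'
#' @param r Radius/radii, dva.
#' @param J Precision (dva^-2).
#' @param payoff A [payoff_rule()].
#' @return Expected points.
#' @export
expected_utility <- function(r, J, payoff = payoff_rule()) {
  wager_points(r, payoff) * hit_probability(r, J)
}

#' Discrete grid of candidate wager radii
#'
#' Radius responses are modeled on a finite grid (default 0.1 to 10 dva in
#' 0.05-dva steps): the display bounds the response and a finite set makes
#' the softmax normalization exact.
#'
#' @param r_min,r_max,step Grid bounds and spacing, dva.
#' @return Increasing numeric vector of radii.
#' @export
radius_grid <- function(r_min = 0.1, r_max = 10, step = 0.05) {
  stopifnot_scalar(r_min, "r_min", nonneg = TRUE)
  stopifnot_scalar(r_max, "r_max", positive = TRUE)
  stopifnot_scalar(step, "step", positive = TRUE)
  if (r_max <= r_min) stop("`r_max` must exceed `r_min`", call. = FALSE)
  seq(r_min, r_max, by = step)
}

# log softmax mass over the radius grid for a vector of precisions:
# returns length(J) x length(r_grid) matrix of log P(r | J, lam)
softmax_radius_logmass <- function(J, lam, payoff, r_grid) {
  U <- wager_points(r_grid, payoff)
  H <- -expm1(-outer(J, r_grid^2 / 2))       # hit prob, |J| x |grid|
  S <- sweep(H, 2L, U, `*`) / lam            # EU / lam
  mx <- S[cbind(seq_along(J), max.col(S, ties.method = "first"))]
  S - mx - log(rowSums(exp(S - mx)))
}

#' Softmax choice density over wager radii
#'
#' Decision noise is modeled as a softmax on expected utility: the
#' probability of choosing radius r is proportional to `exp(EU(r; J) / lam)`
#' over the radius grid. As `lam -> 0` the mass concentrates on the
#' EU-maximizing radius; as `lam -> Inf` the choice becomes uniform.
#'
#' @param J Precision (dva^-2); > 0.
#' @param lam Softmax temperature in points; > 0.
#' @param payoff A [payoff_rule()].
#' @param r_grid Radius grid from [radius_grid()].
#' @return Probability mass vector over `r_grid`, summing to 1.
#' @export
softmax_radius_density <- function(J, lam, payoff = payoff_rule(),
                                   r_grid = radius_grid()) {
  stopifnot_scalar(J, "J", positive = TRUE)
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0)
    stop("`lam` must be > 0", call. = FALSE)
  if (length(r_grid) == 0L || is.unsorted(r_grid, strictly = TRUE))
    stop("`r_grid` must be nonempty and strictly increasing", call. = FALSE)
  as.vector(exp(softmax_radius_logmass(J, lam, payoff, r_grid)))
}

#' Radius maximizing expected utility at known precision
#'
#' Noiseless inner maximization of `EU(r; J)` over r, used by the
#' points-maximizing allocation planner. The maximum is located on a fine
#' grid and refined with a local univariate search.
#'
#' @param J Precision (dva^-2); > 0.
#' @param payoff A [payoff_rule()].
#' @param r_max Upper search bound, dva.
#' @return The EU-maximizing radius, dva.
#' @export
optimal_radius <- function(J, payoff = payoff_rule(), r_max = 15) {
  stopifnot_scalar(J, "J", positive = TRUE)
  r <- seq(0, r_max, by = 0.05)
  eu <- expected_utility(r, J, payoff)
  i <- which.max(eu)
  lo <- r[max(1L, i - 1L)]; hi <- r[min(length(r), i + 1L)]
  stats::optimize(function(x) expected_utility(x, J, payoff),
                  lower = lo, upper = hi, maximum = TRUE)$maximum
}
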