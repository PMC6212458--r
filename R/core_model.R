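#' Variable-precision distribution of memory precision
#'
#' Constructs the trial-to-trial distribution of memory precision J under the
#' variable-precision (VP) model: J is gamma-distributed with mean `Jbar` and
#' scale `tau`, i.e. shape `k = Jbar / tau`. Precision is the inverse variance
#' *per axis* of the two-dimensional Gaussian report distribution, so the
#' per-axis report standard deviation on a trial with precision J is
#' `J^(-1/2)` degrees of visual angle (dva).
#'
#' @param Jbar Mean precision (dva^-2); must be > 0.
#' @param tau Gamma scale parameter (dva^-2); must be > 0. Larger `tau` means
#'   more trial-to-trial variability in precision at fixed mean.
#' @return An object of class `vp_dist` with fields `Jbar`, `tau`, and the
#'   derived shape `k = Jbar / tau`.
#' @examples
#' d <- precision_dist(Jbar = 2, tau = 0.5)
#' d$k  # shape = 4
#' @export
precision_dist <- function(Jbar, tau) {
  stopifnot_scalar(Jbar, "Jbar", positive = TRUE)
  stopifnot_scalar(tau, "tau", positive = TRUE)
  structure(list(Jbar = Jbar, tau = tau, k = Jbar / tau), class = "vp_dist")
}

#' @export
print.vp_dist <- function(x, ...) {
  cat(sprintf(
    "Variable-precision distribution: J ~ Gamma(shape = %.4g, scale = %.4g)\n",
    x$k, x$tau))
  cat(sprintf("  mean Jbar = %.4g dva^-2, sd = %.4g dva^-2\n",
              x$Jbar, sqrt(x$k) * x$tau))
  invisible(x)
}

#' Rayleigh density of the error magnitude at fixed precision
#'
#' The saccade endpoint is drawn from an isotropic 2-D Gaussian centered on
#' the target with per-axis variance 1/J; the Euclidean error magnitude is
#' then Rayleigh-distributed: `f(eps | J) = J * eps * exp(-J * eps^2 / 2)`.
#'
#' @param eps Error magnitude(s), dva; must be >= 0.
#' @param J Precision (dva^-2); must be > 0.
#' @return Density value(s), dva^-1.
#' @export
rayleigh_error_pdf <- function(eps, J) {
  stopifnot_scalar(J, "J", positive = TRUE)
  if (!is.numeric(eps) || any(!is.finite(eps)) || any(eps < 0))
    stop("`eps` must be finite and >= 0", call. = FALSE)
  J * eps * exp(-J * eps^2 / 2)
}

#' Quadrature grid over the precision distribution
#'
#' Log-spaced nodes spanning at least the central `1 - tail_mass`
#' probability mass of the gamma distribution of J, with composite Simpson
#' weights that include the gamma density, so that `sum(w * g(J))`
#' approximates `E[g(J)]`. The integrand of the marginal error density is
#' smooth in log J, which makes log spacing efficient.
#'
#' @param dist A [precision_dist()].
#' @param n_nodes Number of quadrature nodes (default 500; rounded up to an
#'   odd count for the Simpson rule).
#' @param tail_mass Total gamma probability mass excluded in the two tails
#'   (default 1e-12, split evenly). A warning is issued if it exceeds 1e-4.
#' @return A list with `J` (nodes) and `w` (weights summing to about
#'   `1 - tail_mass`).
#' @export
precision_grid <- function(dist, n_nodes = 500, tail_mass = 1e-12) {
  stopifnot(inherits(dist, "vp_dist"))
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 3)
    stop("`n_nodes` must be an integer >= 3 (empty or degenerate grid)",
         call. = FALSE)
  if (tail_mass > 1e-4)
    warning("quadrature grid truncates gamma tail mass > 1e-4; ",
            "marginal densities may be biased", call. = FALSE)
  n_nodes <- as.integer(n_nodes)
  if (n_nodes %% 2L == 0L) n_nodes <- n_nodes + 1L
  lo <- stats::qgamma(tail_mass / 2, shape = dist$k, scale = dist$tau)
  hi <- stats::qgamma(1 - tail_mass / 2, shape = dist$k, scale = dist$tau)
  # for shape < 1 the lower quantile collapses toward 0 (integrable
  # singularity); clamping bounds the log-range so the node spacing stays
  # fine, and the integrands used here all vanish linearly in J at 0
  lo <- max(lo, hi * 1e-14)
  u <- seq(log(lo), log(hi), length.out = n_nodes)
  J <- exp(u)
  du <- u[2L] - u[1L]
  simpson <- rep(c(2, 4), length.out = n_nodes)
  simpson[c(1L, n_nodes)] <- 1
  w <- stats::dgamma(J, shape = dist$k, scale = dist$tau) * J * simpson *
    du / 3
  list(J = J, w = w)
}

#' Marginal density of the error magnitude under the VP model
#'
#' Marginalizes the Rayleigh error density over the gamma distribution of
#' precision by numerical quadrature:
#' `p(eps | Jbar, tau) = integral f(eps | J) Gamma(J; k, tau) dJ`.
#'
#' @param eps Error magnitude(s), dva; >= 0.
#' @param dist A [precision_dist()].
#' @param n_nodes,tail_mass Quadrature controls passed to [precision_grid()].
#' @return Density value(s), dva^-1.
#' @export
marginal_error_pdf <- function(eps, dist, n_nodes = 500, tail_mass = 1e-12) {
  stopifnot(inherits(dist, "vp_dist"))
  if (!is.numeric(eps) || any(!is.finite(eps)) || any(eps < 0))
    stop("`eps` must be finite and >= 0", call. = FALSE)
  g <- precision_grid(dist, n_nodes = n_nodes, tail_mass = tail_mass)
  # f(eps | J_j) = J_j eps exp(-J_j eps^2 / 2), summed against gamma weights
  M <- exp(-outer(g$J, eps^2 / 2))
  as.vector(crossprod(M, g$w * g$J)) * eps
}

#' Expected error magnitude raised to a power
#'
#' Closed-form expectation of the loss `eps^beta` under the VP model:
#' `E[eps^beta] = 2^(beta/2) * Gamma(1 + beta/2) * tau^(-beta/2) *
#' Gamma(k - beta/2) / Gamma(k)`, finite only when the gamma shape
#' `k = Jbar / tau` exceeds `beta / 2` (low-precision trials otherwise make
#' the expected loss diverge).
#'
#' @param dist A [precision_dist()].
#' @param beta Loss exponent (the "sensitivity to error"); >= 0.
#' @return Expected loss, dva^beta.
#' @export
expected_error_power <- function(dist, beta) {
  stopifnot(inherits(dist, "vp_dist"))
  stopifnot_scalar(beta, "beta", nonneg = TRUE)
  if (beta == 0) return(1)
  if (dist$k <= beta / 2)
    stop(sprintf(
      "divergent expected loss: gamma shape k = %.4g <= beta/2 = %.4g",
      dist$k, beta / 2), call. = FALSE)
  2^(beta / 2) * gamma(1 + beta / 2) * dist$tau^(-beta / 2) *
    exp(lgamma(dist$k - beta / 2) - lgamma(dist$k))
}

#' Sample precisions and report offsets from the VP generative model
#'
#' Draws `n` trials: precision J from the gamma distribution, then a 2-D
#' report offset from an isotropic Gaussian with per-axis sd `J^(-1/2)`.
#'
#' @param dist A [precision_dist()].
#' @param n Number of draws.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `J` (length n) and `offset` (n x 2 matrix, dva).
#' @export
sample_error <- function(dist, n = 1, seed = NULL) {
  stopifnot(inherits(dist, "vp_dist"))
  if (!is.null(seed)) set.seed(seed)
  J <- stats::rgamma(n, shape = dist$k, scale = dist$tau)
  sd <- 1 / sqrt(J)
  offset <- cbind(stats::rnorm(n, sd = sd), stats::rnorm(n, sd = sd))
  list(J = J, offset = offset)
}
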