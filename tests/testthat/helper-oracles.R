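# Independent oracles and small fixtures used across the suite.

# Closed-form marginal error density (Burr-type), derived by integrating the
# Rayleigh density against the gamma precision density by hand:
#   p(eps) = eps * k / (tau^k * (eps^2/2 + 1/tau)^(k+1)),  k = Jbar/tau.
# Used only as a test oracle; the package path is quadrature.
closed_form_marginal <- function(eps, Jbar, tau) {
  k <- Jbar / tau
  exp(log(eps) + log(k) - k * log(tau) - (k + 1) * log(eps^2 / 2 + 1 / tau))
}

# All points of the 3-simplex on a regular grid with the given step.
simplex_grid <- function(step) {
  v <- seq(0, 1, by = step)
  out <- list()
  i <- 1L
  for (p1 in v) {
    p2 <- v[v <= 1 - p1 + 1e-12]
    out[[i]] <- cbind(p1, p2, pmax(1 - p1 - p2, 0))
    i <- i + 1L
  }
  do.call(rbind, out)
}

# Brute-force minimum of the ME objective on a simplex grid, via a lookup
# over the (few) distinct per-condition allocation values.
brute_force_me <- function(Jbar_total, tau, beta, t, step) {
  v <- seq(0, 1, by = step)
  k <- v * Jbar_total / tau
  E <- rep(Inf, length(v))
  ok <- k > beta / 2
  E[ok] <- 2^(beta / 2) * gamma(1 + beta / 2) * tau^(-beta / 2) *
    exp(lgamma(k[ok] - beta / 2) - lgamma(k[ok]))
  P <- simplex_grid(step)
  idx <- round(P / step) + 1L
  obj <- t[1] * E[idx[, 1]] + t[2] * E[idx[, 2]] + t[3] * E[idx[, 3]]
  min(obj)
}

# Brute-force maximum of the MP objective on a simplex grid, sharing the
# package's per-item value function but enumerating allocations exhaustively.
brute_force_mp <- function(Jbar_total, tau, t, step, payoff = payoff_rule(),
                           n_nodes = 200, r_step = 0.01) {
  v <- seq(0, 1, by = step)
  V <- vapply(pmax(v, 1e-10) * Jbar_total, vpalloc::mp_value, numeric(1),
              tau = tau, payoff = payoff, n_nodes = n_nodes,
              r_step = r_step)
  P <- simplex_grid(step)
  idx <- round(P / step) + 1L
  max(t[1] * V[idx[, 1]] + t[2] * V[idx[, 2]] + t[3] * V[idx[, 3]])
}

# reduced-resolution controls for fits inside tests
fast_ctl <- function(...) fit_control(n_nodes = 150, ...)

flex_theta1 <- function(p_high = 0.49, p_med = 0.28,
                        Jbar_total = 4, tau = 1) {
  c(Jbar_total = Jbar_total, tau = tau, p_high = p_high, p_med = p_med)
}

flex_theta2 <- function(p_high = 0.44, p_med = 0.31, lam = 5,
                        Jbar_total = 4, tau = 1) {
  c(Jbar_total = Jbar_total, tau = tau, p_high = p_high, p_med = p_med,
    lam = lam)
}
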