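test_that("proportional allocation renormalizes probe probabilities", {
  expect_identical(proportional_allocation(c(0.6, 0.3, 0.1)),
                   c(0.6, 0.3, 0.1))
  expect_equal(proportional_allocation(rep(1 / 3, 3)), rep(1 / 3, 3))
  # an excluded (zero-probability) condition keeps zero resource
  expect_equal(proportional_allocation(c(0.5, 0.5, 0)), c(0.5, 0.5, 0))
  expect_error(proportional_allocation(c(-0.1, 0.6, 0.5)), "nonnegative")
})

test_that("flexible allocation fills in the remainder and guards the simplex", {
  expect_equal(flexible_allocation(0.49, 0.28), c(0.49, 0.28, 0.23))
  expect_equal(flexible_allocation(1 / 3, 1 / 3), rep(1 / 3, 3))
  expect_equal(flexible_allocation(1, 0), c(1, 0, 0))
  expect_error(flexible_allocation(0.7, 0.4), "exceed")
  expect_error(flexible_allocation(-0.1, 0.4), "p_high")
})

test_that("ME allocation solves the weighted expected-loss problem", {
  # symmetric objective -> uniform optimum
  expect_equal(minimize_error_allocation(6, 1, 2, t = rep(1 / 3, 3)),
               rep(1 / 3, 3), tolerance = 1e-5)
  # tau -> 0, beta = 2: Lagrange condition on sum t_i * 2/(p_i Jbar) gives
  # p proportional to sqrt(t)
  p <- minimize_error_allocation(10, 1e-4, 2)
  expect_equal(p, sqrt(c(0.6, 0.3, 0.1)) / sum(sqrt(c(0.6, 0.3, 0.1))),
               tolerance = 1e-3)
  # permuting the probe probabilities permutes the allocation
  p1 <- minimize_error_allocation(5, 0.8, 1.5, t = c(0.6, 0.3, 0.1))
  p2 <- minimize_error_allocation(5, 0.8, 1.5, t = c(0.1, 0.6, 0.3))
  expect_equal(p2, p1[c(3, 1, 2)], tolerance = 1e-5)
  expect_error(minimize_error_allocation(1, 1, 2), "infeasible")
})

test_that("interior ME optimum is flatter than proportional", {
  for (pars in list(c(6, 1, 2), c(4, 0.5, 2), c(10, 2, 1.5))) {
    p <- minimize_error_allocation(pars[1], pars[2], pars[3])
    expect_lt(p[1], 0.6)
    expect_gt(p[3], 0.1)
  }
})

test_that("ME optimizer beats a brute-force simplex grid", {
  set.seed(21)
  for (rep in 1:5) {
    repeat {
      Jb <- exp(stats::runif(1, log(3), log(40)))
      tau <- exp(stats::runif(1, log(0.3), log(4)))
      beta <- stats::runif(1, 0.5, 3)
      if (Jb / tau > 3 * beta / 2 * 1.5) break
    }
    p <- minimize_error_allocation(Jb, tau, beta)
    opt <- me_objective(p, Jb, tau, beta, c(0.6, 0.3, 0.1))
    grid <- brute_force_me(Jb, tau, beta, c(0.6, 0.3, 0.1), step = 0.005)
    expect_lte(opt, grid * (1 + 1e-9))
  }
})

test_that("MP allocation maximizes points and starves the low-priority item", {
  p_mp <- maximize_points_allocation(4, 1, n_starts = 6)
  p_me <- minimize_error_allocation(4, 1, 2)
  # symmetric case
  expect_equal(maximize_points_allocation(4, 1, t = rep(1 / 3, 3),
                                          n_starts = 4, n_nodes = 100,
                                          r_step = 0.05),
               rep(1 / 3, 3), tolerance = 1e-3)
  # optimality dominance over the other strategies' allocations
  obj_mp <- mp_objective(p_mp, 4, 1)
  expect_gte(obj_mp, mp_objective(c(0.6, 0.3, 0.1), 4, 1))
  expect_gte(obj_mp, mp_objective(p_me, 4, 1))
  # "ignore the low-priority target": MP gives it far less than ME
  expect_lt(p_mp[3], p_me[3] - 0.1)
})

test_that("all allocators return valid simplex points", {
  allocs <- list(proportional_allocation(),
                 flexible_allocation(0.2, 0.5),
                 minimize_error_allocation(8, 1.3, 2.2),
                 maximize_points_allocation(3, 0.7, n_starts = 4,
                                            n_nodes = 100, r_step = 0.05))
  for (p in allocs) {
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-10)
  }
})
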