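test_that("model specs carry the right parameter sets", {
  expect_equal(model_spec(1, "proportional")$n_params, 2)
  expect_equal(model_spec(1, "flexible")$n_params, 4)
  expect_equal(model_spec(1, "min_error")$n_params, 3)
  expect_equal(model_spec(2, "proportional")$n_params, 3)
  expect_equal(model_spec(2, "flexible")$n_params, 5)
  expect_equal(model_spec(2, "min_error")$n_params, 4)
  expect_equal(model_spec(2, "max_points")$n_params, 3)
  expect_error(model_spec(1, "max_points"), "Experiment 2")
})

test_that("Exp-1 likelihood is additive and matches the closed-form marginal", {
  sp <- model_spec(1, "proportional")
  th <- c(Jbar_total = 5, tau = 1)
  tr <- generate_experiment(sp, th, design_config(n_trials = 120), seed = 2)
  ll <- loglik_exp1(th, sp, tr)
  expect_equal(loglik_exp1(th, sp, rbind(tr, tr)), 2 * ll, tolerance = 1e-10)
  # order invariance
  expect_equal(loglik_exp1(th, sp, tr[sample(nrow(tr)), ]), ll,
               tolerance = 1e-10)
  # single trial: log closed-form marginal at that condition's Jbar
  one <- tr[5, ]
  expect_equal(loglik_exp1(th, sp, one),
               log(closed_form_marginal(one$error, one$priority * 5, 1)),
               tolerance = 1e-6)
  expect_error(loglik_exp1(c(Jbar_total = 5000, tau = 1), sp, tr), "bounds")
})

test_that("simulated error frequencies match the likelihood density", {
  sp <- model_spec(1, "flexible")
  th <- flex_theta1()
  tr <- generate_experiment(sp, th,
                            design_config(n_trials = 3e4,
                                          probe_probs = c(0.6, 0.3, 0.1)),
                            seed = 12)
  eps <- tr$error[tr$priority == 0.6]
  d <- precision_dist(0.49 * 4, 1)
  breaks <- c(seq(0, 4, by = 0.5), Inf)
  emp <- as.vector(table(cut(eps, breaks))) / length(eps)
  thr <- vapply(seq_len(length(breaks) - 1), function(i)
    stats::integrate(function(e) marginal_error_pdf(e, d), breaks[i],
                     min(breaks[i + 1], 60))$value, numeric(1))
  se <- sqrt(thr * (1 - thr) / length(eps))
  expect_true(all(abs(emp - thr) < 4 * pmax(se, 1e-4)))
})

test_that("Exp-2 likelihood factorizes in the independence limits", {
  bounds <- list(lam = c(0.01, 1e9), tau = c(1e-8, 200))
  sp <- model_spec(2, "flexible", bounds = bounds)
  th <- flex_theta2()
  tr <- generate_experiment(model_spec(2, "flexible"), th,
                            design_config(n_trials = 150), seed = 9)
  # lam -> Inf: radius mass becomes uniform over the grid
  th_hot <- th; th_hot["lam"] <- 1e8
  ll_joint <- loglik_exp2(th_hot, sp, tr)
  sp1 <- model_spec(1, "flexible")
  ll_err <- loglik_exp1(th[names(th) != "lam"], sp1, tr)
  expect_equal(ll_joint, ll_err + nrow(tr) * log(1 / length(radius_grid())),
               tolerance = 1e-4)
  # tau -> 0: product of Rayleigh error term and softmax mass at J = Jbar_c
  th_det <- th; th_det["tau"] <- 1e-7
  ll_det <- loglik_exp2(th_det, sp, tr)
  rg <- radius_grid()
  p_alloc <- c(0.44, 0.31, 0.25)
  ll_ref <- 0
  for (i in 1:3) {
    sel <- tr$priority == c(0.6, 0.3, 0.1)[i]
    Jc <- p_alloc[i] * 4
    mass <- softmax_radius_density(Jc, lam = 5)
    idx <- as.integer(round((tr$radius[sel] - rg[1]) / 0.05)) + 1L
    ll_ref <- ll_ref + sum(log(rayleigh_error_pdf(tr$error[sel], Jc))) +
      sum(log(mass[idx]))
  }
  expect_equal(ll_det, ll_ref, tolerance = 1e-3)
})

test_that("off-grid radii are snapped with a warning", {
  sp <- model_spec(2, "proportional")
  th <- c(Jbar_total = 4, tau = 1, lam = 5)
  tr <- generate_experiment(sp, th, design_config(n_trials = 50), seed = 4)
  tr$radius[1] <- tr$radius[1] + 0.013
  expect_warning(loglik_exp2(th, sp, tr), "snapped")
})

test_that("information criteria follow their definitions", {
  ic <- information_criteria(-100, 2, 100)
  expect_equal(ic[["aicc"]], 204 + 12 / 97)
  expect_equal(ic[["bic"]], 200 + 2 * log(100))
  ic0 <- information_criteria(-100, 0, 50)
  expect_equal(unname(ic0), c(200, 200))
  expect_error(information_criteria(-10, 5, 6), "AICc undefined")
  # BIC penalizes harder than AICc once n is large enough
  for (k in 1:3) for (n in c(50, 200, 1000)) {
    if (log(n) > 2 + 2 * (k + 1) / (n - k - 1)) {
      ic <- information_criteria(-50, k, n)
      expect_gt(ic[["bic"]], ic[["aicc"]])
    }
  }
})

test_that("multistart MLE dominates the generating parameters and nests", {
  sp <- model_spec(1, "flexible")
  th <- flex_theta1()
  tr <- generate_experiment(sp, th, design_config(n_trials = 250), seed = 77)
  ctl <- fast_ctl()
  f4 <- fit_model(sp, tr, n_starts = 4, seed = 5, control = ctl)
  expect_gte(f4$loglik, max(f4$start_loglik) - 1e-9)
  expect_gte(f4$loglik, loglik_exp1(th, sp, tr, ctl))
  # enlarging the start set never hurts (same seed -> nested starts)
  f2 <- fit_model(sp, tr, n_starts = 2, seed = 5, control = ctl)
  expect_gte(f4$loglik + 1e-9, f2$loglik)
  # nesting: flexible at its MLE >= restricted strategies at theirs
  fp <- fit_model(model_spec(1, "proportional"), tr, n_starts = 4, seed = 5,
                  control = ctl)
  fme <- fit_model(model_spec(1, "min_error"), tr, n_starts = 4, seed = 5,
                   control = ctl)
  expect_gte(f4$loglik + 1e-6, fp$loglik)
  expect_gte(f4$loglik + 1e-6, fme$loglik)
})

test_that("model comparison handles identity and mismatched inputs", {
  sp <- model_spec(1, "proportional")
  fits <- lapply(1:6, function(i) {
    tr <- generate_experiment(sp, c(Jbar_total = 4, tau = 1),
                              design_config(n_trials = 80), seed = i)
    tr$participant <- sprintf("S%02d", i)
    fit_model(sp, tr, n_starts = 2, seed = i, control = fast_ctl())
  })
  cmp <- compare_models(fits, fits, n_boot = 200, seed = 3)
  expect_equal(cmp$median_aicc, 0)
  expect_equal(unname(cmp$ci_aicc), c(0, 0))
  expect_true(cmp$ci_aicc[1] <= cmp$median_aicc &&
                cmp$median_aicc <= cmp$ci_aicc[2])
  expect_error(compare_models(fits[1:3], fits[4:6]), "same set")
})

test_that("nested-model penalty: proportional wins on proportional-truth data", {
  # Flexible data generated exactly at the probe probabilities is fit
  # equally well by the 2-parameter proportional model, which then wins AICc
  sp_gen <- model_spec(1, "flexible")
  th <- flex_theta1(p_high = 0.6, p_med = 0.3)
  tr <- generate_experiment(sp_gen, th, design_config(n_trials = 400),
                            seed = 19)
  ctl <- fast_ctl()
  f_prop <- fit_model(model_spec(1, "proportional"), tr, n_starts = 4,
                      seed = 2, control = ctl)
  f_flex <- fit_model(sp_gen, tr, n_starts = 4, seed = 2, control = ctl)
  expect_lt(f_prop$aicc, f_flex$aicc)
})
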