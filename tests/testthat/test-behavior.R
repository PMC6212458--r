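test_that("Euclidean error obeys basic geometry", {
  expect_equal(euclidean_error(c(1, 2), c(1, 2)), 0)
  expect_equal(euclidean_error(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_error(c(3, 4), c(0, 0)),
               euclidean_error(c(0, 0), c(3, 4)))
  m <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  expect_equal(euclidean_error(m, m + 1), c(sqrt(2), sqrt(2)))
  expect_error(euclidean_error(c(NA, 1), c(0, 0)), "finite")
})

test_that("priority summary shows graded errors and exposes the ANOVA table", {
  sp <- model_spec(2, "flexible")
  tr <- generate_experiment(sp, flex_theta2(p_high = 0.55, p_med = 0.3),
                            design_config(n_trials = 500,
                                          n_participants = 3), seed = 6)
  ps <- priority_summary(tr)
  expect_true(ps$monotonic[["error"]])
  expect_true(ps$monotonic[["radius"]])
  expect_equal(nrow(ps$by_participant), 9)  # 3 participants x 3 priorities
  expect_equal(ps$summary$priority, c(0.6, 0.3, 0.1))
  # SEM = sd of participant means / sqrt(n)
  hi <- ps$by_participant[ps$by_participant$priority == 0.6, "error"]
  expect_equal(ps$summary$sem_error[1], stats::sd(hi) / sqrt(3))
  expect_error(priority_summary(tr[tr$priority == 0.6, ]), "priority")
})

test_that("per-participant standardization is idempotent and offset-free", {
  sp <- model_spec(2, "flexible")
  tr <- generate_experiment(sp, flex_theta2(),
                            design_config(n_trials = 200,
                                          n_participants = 2), seed = 3)
  z1 <- vpalloc:::standardize_trials(tr)
  z2 <- vpalloc:::standardize_trials(
    transform(tr, error = z1$z_error, radius = z1$z_radius))
  expect_equal(z1$z_error, z2$z_error, tolerance = 1e-12)
  # adding participant-specific offsets to both variables leaves the pooled
  # standardized Spearman correlation unchanged
  rho0 <- within_priority_correlation(tr)$pooled$rho
  off <- ifelse(tr$participant == "S01", 5, -2)
  tr2 <- transform(tr, error = error + off, radius = radius + off)
  expect_equal(within_priority_correlation(tr2)$pooled$rho, rho0,
               tolerance = 1e-12)
})

test_that("within-priority correlations track the generative coupling", {
  sp <- model_spec(2, "flexible")
  tr <- generate_experiment(sp, flex_theta2(),
                            design_config(n_trials = 900,
                                          n_participants = 2), seed = 14)
  wc <- within_priority_correlation(tr)
  expect_true(all(wc$pooled$rho > 0))
  # degenerate check: radius equal to error gives rho = 1
  tr_eq <- tr; tr_eq$radius <- tr_eq$error
  expect_true(all(within_priority_correlation(tr_eq)$pooled$rho == 1))
  # independent radius: correlation near zero
  tr_ind <- tr
  set.seed(5); tr_ind$radius <- sample(tr_ind$radius)
  # smallest cell has ~180 trials, so sampling noise is about 1/sqrt(180)
  expect_true(all(abs(within_priority_correlation(tr_ind)$pooled$rho) < 0.15))
  # tiny cells are dropped with a warning
  tr_small <- tr[c(which(tr$priority == 0.6 & tr$participant == "S01")[1:2],
                   which(tr$priority != 0.6 | tr$participant != "S01")), ]
  expect_warning(within_priority_correlation(tr_small), "omitted")
})

test_that("stratified permutation preserves covariate-driven structure", {
  # radius and error depend on delay only: the delay-stratified null keeps
  # that dependence, so the observed correlation sits inside the null
  set.seed(42)
  n <- 600
  delay <- sample(seq(1000, 4000, by = 500), n, replace = TRUE)
  tr <- data.frame(participant = "S01",
                   priority = sample(c(0.6, 0.3, 0.1), n, TRUE,
                                     prob = c(0.6, 0.3, 0.1)),
                   target_x = stats::runif(n, 5, 10),
                   target_y = stats::runif(n, 5, 10),
                   delay = delay,
                   error = 0.001 * delay + stats::rnorm(n, sd = 0.3),
                   radius = 0.001 * delay + stats::rnorm(n, sd = 0.3))
  pn <- permutation_null(tr, "delay", n_perm = 400, seed = 11)
  expect_true(all(abs(pn$table$observed - pn$table$null_median) < 0.12))
  expect_true(all(pn$table$p_value > 0.01))
})

test_that("shared-precision coupling beats the stratified nulls", {
  sp <- model_spec(2, "flexible")
  tr <- generate_experiment(sp, flex_theta2(),
                            design_config(n_trials = 700), seed = 23)
  for (cov in c("location", "delay")) {
    # sparse angular bins legitimately warn about singleton strata
    pn <- suppressWarnings(permutation_null(tr, cov, n_perm = 400, seed = 7))
    if (cov == "delay") {
      expect_true(all(abs(pn$table$null_median) < 0.05))
    } else {
      # singleton angle bins keep part of the coupling, so the location
      # null sits above zero but well below the observed correlation
      expect_true(all(pn$table$null_median < pn$table$observed / 2))
    }
    expect_true(all(pn$table$observed > pn$table$null_median))
    expect_gte(sum(pn$table$p_value < 0.025), 2)  # most of 3 cells
  }
  # determinism under a fixed seed
  pn1 <- permutation_null(tr, "delay", n_perm = 100, seed = 3)
  pn2 <- permutation_null(tr, "delay", n_perm = 100, seed = 3)
  expect_identical(pn1$table, pn2$table)
})

test_that("signed-rank comparison against null medians behaves at the edges", {
  x <- c(0.2, 0.25, 0.3, 0.22, 0.28, 0.31, 0.19)
  res_id <- signed_rank_vs_null(x, x)
  expect_true(res_id$degenerate)
  expect_equal(res_id$p_value, 1)
  # strong positive shift, n = 14
  set.seed(2)
  obs <- stats::runif(14, 0.2, 0.4)
  nm <- obs - stats::runif(14, 0.15, 0.3)
  res <- signed_rank_vs_null(obs, nm)
  expect_lt(res$p_value, 0.001)
  # two-sided p is symmetric under swapping the pair order
  expect_equal(signed_rank_vs_null(nm, obs)$p_value, res$p_value)
  expect_error(signed_rank_vs_null(1:3, 2:4), "length")
})
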