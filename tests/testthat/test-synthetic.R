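test_that("targets respect the angular grid, jitter bound, and quadrants", {
  tg <- generate_targets(design_config(), n = 400, seed = 5)
  # polar angle of every target stays off the cardinal axes
  ang <- tg$angle_deg %% 90
  expect_true(all(pmin(ang, 90 - ang) > 5))
  expect_true(all(tg$ecc >= 9 & tg$ecc <= 11))
  recomputed_ecc <- sqrt(tg$x^2 + tg$y^2)
  expect_equal(recomputed_ecc, tg$ecc, tolerance = 1e-10)
  quads <- tapply(tg$quadrant, tg$trial, function(q) length(unique(q)))
  expect_true(all(quads == 4))
})

test_that("generated experiments follow the probe probabilities and moments", {
  sp <- model_spec(1, "flexible")
  th <- flex_theta1()
  tr <- generate_experiment(sp, th, design_config(n_trials = 8000), seed = 1)
  freq <- table(factor(tr$priority, levels = c(0.6, 0.3, 0.1))) / nrow(tr)
  se <- sqrt(c(0.6, 0.3, 0.1) * c(0.4, 0.7, 0.9) / nrow(tr))
  expect_true(all(abs(as.vector(freq) - c(0.6, 0.3, 0.1)) < 4 * se))
  # per-condition mean error matches the closed-form first moment
  for (i in 1:3) {
    p_i <- c(0.49, 0.28, 0.23)[i]
    cond <- c(0.6, 0.3, 0.1)[i]
    eps <- tr$error[tr$priority == cond]
    m_th <- expected_error_power(precision_dist(p_i * 4, 1), 1)
    expect_lt(abs(mean(eps) - m_th), 4 * stats::sd(eps) / sqrt(length(eps)))
  }
  # recorded error is consistent with coordinates
  d <- euclidean_error(cbind(tr$target_x, tr$target_y),
                       cbind(tr$endpoint_x, tr$endpoint_y))
  expect_equal(d, tr$error, tolerance = 1e-9)
})

test_that("generation is reproducible and validates parameters", {
  sp <- model_spec(2, "flexible")
  th <- flex_theta2()
  a <- generate_experiment(sp, th, design_config(n_trials = 100), seed = 33)
  b <- generate_experiment(sp, th, design_config(n_trials = 100), seed = 33)
  expect_identical(a, b)
  expect_error(generate_experiment(sp, c(Jbar_total = -1, tau = 1,
                                         p_high = 0.5, p_med = 0.3,
                                         lam = 5),
                                   design_config(n_trials = 10), seed = 1))
  # Exp-2 points respect the payoff-rule-with-hit-indicator contract
  hit <- a$error <= a$radius
  expect_equal(a$points, wager_points(a$radius) * hit, tolerance = 1e-12)
})

test_that("delay-decay hook and dropout shape the generated table", {
  sp <- model_spec(1, "proportional")
  th <- c(Jbar_total = 6, tau = 1)
  tr <- generate_experiment(sp, th,
                            design_config(n_trials = 6000, delay_decay = 0.5),
                            seed = 9)
  m <- stats::aggregate(error ~ delay, tr, mean)
  expect_gt(m$error[nrow(m)], m$error[1])  # errors grow with delay
  tr2 <- generate_experiment(sp, th,
                             design_config(n_trials = 2000, dropout = 0.05),
                             seed = 9)
  expect_lt(nrow(tr2), 2000)
  expect_gt(nrow(tr2), 2000 * 0.9)
})

test_that("trial tables round-trip through CSV with schema validation", {
  sp <- model_spec(2, "flexible")
  tr <- generate_experiment(sp, flex_theta2(),
                            design_config(n_trials = 60), seed = 3)
  path <- tempfile(fileext = ".csv")
  write_trials(tr, path, meta = list(seed = 3))
  back <- read_trials(path)
  expect_equal(back, tr, tolerance = 1e-12)
  expect_true(file.exists(paste0(path, ".json")))
  # Exp-1 tables without a radius column pass validation
  tr1 <- tr[, setdiff(names(tr), c("radius", "points"))]
  path1 <- tempfile(fileext = ".csv")
  write_trials(tr1, path1)
  expect_silent(read_trials(path1))
  # corrupted error column is rejected with row information
  bad <- tr; bad$error[7] <- bad$error[7] + 0.5
  path2 <- tempfile(fileext = ".csv")
  write_trials(bad, path2)
  expect_error(read_trials(path2), "row 7")
  # missing required column
  path3 <- tempfile(fileext = ".csv")
  utils::write.csv(tr[, -2], path3, row.names = FALSE)
  expect_error(read_trials(path3), "missing required")
})
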