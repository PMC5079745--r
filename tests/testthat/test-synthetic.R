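test_that("displays honor the minimum same-feature separation", {
  d <- generate_displays(48, 3, 62.04, seed = 19)
  expect_equal(nrow(d), 48 * 3)
  circ_d <- function(a, b) pmin(abs(a - b) %% 360, 360 - abs(a - b) %% 360)
  for (disp in 1:48) {
    v <- d[d$display == disp, ]
    for (f in c("color", "orientation", "location")) {
      pairs <- combn(3, 2)
      expect_true(all(circ_d(v[[f]][pairs[1, ]], v[[f]][pairs[2, ]]) >= 62.04))
    }
  }
  # min_dist = 0 degenerates to plain uniform draws; infeasible spacing errors
  expect_silent(generate_displays(5, 3, 0, seed = 2))
  expect_error(generate_displays(5, 6, 62.04), "infeasible")
  expect_identical(generate_displays(10, 3, 62.04, seed = 4),
                   generate_displays(10, 3, 62.04, seed = 4))
})

test_that("feature-order schedule is balanced and run-limited", {
  sched <- feature_order_schedule(96, seed = 29)
  perms <- apply(sched, 1, paste, collapse = "-")
  expect_equal(length(unique(perms)), 6)
  expect_true(all(table(perms) == 16))
  expect_true(check_schedule(sched))
  # a deliberately bad schedule (same feature first 5 slots) is rejected
  bad <- sched
  bad[1:5, ] <- matrix(rep(c("color", "orientation", "location"), each = 5),
                       ncol = 3)
  expect_false(check_schedule(bad))
  expect_identical(feature_order_schedule(48, seed = 8),
                   feature_order_schedule(48, seed = 8))
  expect_error(feature_order_schedule(50), "divisible")
})

test_that("subject models reproduce the population moments and copula correlation", {
  big <- generate_subject_models(2000, seed = 47)
  expect_equal(mean(big$p_target), 0.62, tolerance = 0.02)
  expect_equal(sd(big$p_target), 0.16, tolerance = 0.02)
  expect_equal(mean(big$kappa), 10.05, tolerance = 0.35)
  expect_equal(sd(big$kappa), 3.41, tolerance = 0.35)
  expect_equal(mean(big$vividness_mean), 48.23, tolerance = 1.5)
  # mapped-measure correlations near the latent target
  cors <- cor(big[, c("p_target", "kappa", "vividness_mean")])
  expect_true(all(abs(cors[upper.tri(cors)] - 0.5) < 0.07))
  # independence and degenerate-population limits
  indep <- generate_subject_models(2000, target_corr = 0, seed = 48)
  ci <- cor(indep[, c("p_target", "kappa", "vividness_mean")])
  expect_true(all(abs(ci[upper.tri(ci)]) < 0.06))
  pop0 <- default_population()
  pop0$p_target_sd <- 0; pop0$kappa_sd <- 0; pop0$vividness_sd <- 0
  same <- generate_subject_models(5, pop0, seed = 49)
  expect_equal(sd(same$p_target), 0)
  expect_equal(sd(same$kappa), 0)
  expect_error(generate_subject_models(5, target_corr = 1.5), "positive definite")
})

test_that("simulated trial and rating counts match the design arithmetic", {
  sim <- simulate_experiment(seed = 311)
  # 20 subjects x 8 blocks x 6 displays x 2 objects x 3 features, minus one
  # subject's excluded first block (36 trials, 6 ratings)
  expect_equal(nrow(sim$trials), 20 * 8 * 6 * 2 * 3 - 36)
  expect_equal(nrow(sim$ratings), 20 * 48 - 6)
  expect_false(any(sim$trials$subject == 1 & sim$trials$block == 1))
  # stored error equals the wrapped response - target difference
  expect_equal(sim$trials$error,
               wrap_error(sim$trials$response_deg, sim$trials$target_deg))
  expect_true(all(sim$ratings$vividness >= 0 & sim$ratings$vividness <= 100))
  # no excluded block: full 5760 / 960
  des <- experiment_design(missing_block = NULL)
  models <- sim$subject_models
  tr <- simulate_responses(des, models, sim$displays, seed = 5)
  expect_equal(nrow(tr), 5760)
})

test_that("generated errors follow the requested mixture", {
  des <- experiment_design(n_subjects = 2, missing_block = NULL)
  pop <- default_population()
  pop$p_target_sd <- 0; pop$kappa_sd <- 0; pop$vividness_sd <- 0
  models <- generate_subject_models(2, pop, seed = 51)
  # p_target = 0 everywhere: errors are uniform on the circle
  models0 <- models; models0$p_target <- 0
  tr0 <- simulate_responses(des, models0, model_id = "M2", seed = 52)
  expect_gt(suppressWarnings(
    ks.test(tr0$error, "punif", -180, 180)$p.value), 0.01)
  # M3 concentrates the swap mass near the non-target offsets
  models3 <- models; models3$p_target <- 0.3
  tr3 <- simulate_responses(des, models3, model_id = "M3",
                            p_nontarget = 0.6, seed = 53)
  off <- pmin(abs(tr3$error - wrap_error(tr3$nontarget1_deg, tr3$target_deg)),
              abs(tr3$error - wrap_error(tr3$nontarget2_deg, tr3$target_deg)))
  # far more trials land near a non-target value than uniform guessing allows
  expect_gt(mean(off < 20), 0.25)
})

test_that("vividness ratings are clamped, quantized, and honor exclusions", {
  des <- experiment_design(n_subjects = 3)
  pop <- default_population()
  models <- generate_subject_models(3, pop, seed = 57)
  models$vividness_within_sd <- 0
  v <- simulate_vividness(des, models, seed = 58)
  expect_equal(nrow(v), 3 * 48 - 6)
  # zero noise: every rating equals the subject mean (on the 100-point grid)
  for (s in 1:3)
    expect_true(all(v$vividness[v$subject == s] ==
                      round(models$vividness_mean[s])))
  # clamping: a subject mean beyond the scale saturates at 100
  models$vividness_mean <- 120
  models$vividness_within_sd <- 5
  v2 <- simulate_vividness(des, models, seed = 59)
  expect_true(all(v2$vividness == 100))
  expect_true(all(v$vividness == floor(v$vividness)))
})
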