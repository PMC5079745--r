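test_that("negative log-likelihood matches limits, nesting, and a summation oracle", {
  err100 <- make_m2_errors(100, seed = 5)
  es <- error_set(err100)
  # kappa = 0 under M1 is the uniform likelihood: n * ln(360)
  expect_equal(neg_log_lik("M1_VM", list(kappa = 0), es), 100 * log(360))
  # M2 with no uniform mass equals M1 at the same parameters
  p <- list(kappa = 7.3, mu = 0)
  expect_equal(neg_log_lik("M2_VM_UNIF", c(p, p_target = 1, p_uniform = 0), es),
               neg_log_lik("M1_VM", p, es))
  # independent per-trial summation oracle on a 50-trial fixture, M2 and M3
  es50 <- make_error_set_with_offsets(50, seed = 21)
  pm2 <- list(p_target = 0.55, p_uniform = 0.45, kappa = 8.2, mu = 0)
  expect_equal(neg_log_lik("M2_VM_UNIF", pm2, es50),
               oracle_nll(pm2, es50$errors), tolerance = 1e-8)
  pm3 <- list(p_target = 0.5, p_uniform = 0.35, p_nontarget = 0.15,
              kappa = 8.2, mu = 0)
  expect_equal(neg_log_lik("M3_VM_UNIF_NT", pm3, es50),
               oracle_nll(pm3, es50$errors, es50$nontarget_offsets),
               tolerance = 1e-8)
  # swap model without offsets is a configuration error
  expect_error(neg_log_lik("M3_VM_UNIF_NT", pm3, es), "non-target")
})

test_that("EM fitting is deterministic, monotone, and honors generative structure", {
  es <- error_set(make_m2_errors(2000, seed = 31))
  f1 <- fit_model(es, "M2_VM_UNIF", n_starts = 5, seed = 77)
  f2 <- fit_model(es, "M2_VM_UNIF", n_starts = 5, seed = 77)
  expect_identical(f1, f2)
  # EM never increases the negative log-likelihood across iterations
  expect_true(all(diff(f1$nll_trace) <= 1e-7))
  # mixture bookkeeping invariants
  expect_equal(f1$p_target + f1$p_uniform + f1$p_nontarget, 1,
               tolerance = 1e-9)
  expect_equal(f1$aic, 2 * f1$n_params - 2 * f1$log_lik)
  expect_equal(f1$bic, f1$n_params * log(f1$n_trials) - 2 * f1$log_lik)
  # purely uniform data: essentially no target mass
  set.seed(41)
  fu <- fit_model(error_set(runif(5000, -179.999, 180)), "M2_VM_UNIF",
                  n_starts = 5, seed = 42)
  expect_lt(fu$p_target, 0.05)
})

test_that("fitted solution beats a dense grid over (kappa, p_target)", {
  es <- error_set(make_m2_errors(200, seed = 55))
  fit <- fit_model(es, "M2_VM_UNIF", n_starts = 10, seed = 56)
  kappas <- exp(seq(log(0.5), log(50), length.out = 100))
  pts <- seq(0, 1, length.out = 101)
  grid_min <- Inf
  for (k in kappas) {
    dvm <- vonmises_pdf(es$errors, 0, k)
    for (p in pts) {
      nll <- -sum(log(p * dvm + (1 - p) / 360))
      if (nll < grid_min) grid_min <- nll
    }
  }
  expect_lte(-fit$log_lik, grid_min + 1e-3)
})

test_that("parameter recovery across a simulated cohort is unbiased", {
  set.seed(303)
  models <- generate_subject_models(200, seed = 9)
  bias_p <- rel_k <- numeric(200)
  for (i in 1:200) {
    e <- make_m2_errors(286, models$p_target[i], models$kappa[i],
                        seed = 5000 + i)
    ft <- fit_model(error_set(e), "M2_VM_UNIF", n_starts = 5,
                    seed = 1000 + i)
    expect_true(all(diff(ft$nll_trace) <= 1e-7))
    bias_p[i] <- ft$p_target - models$p_target[i]
    rel_k[i] <- ft$kappa / models$kappa[i] - 1
  }
  expect_lt(abs(mean(bias_p)), 0.02)
  expect_lt(abs(mean(rel_k)), 0.10)
})

test_that("model comparison selects the generative model and respects nesting", {
  es <- make_error_set_with_offsets(5000, seed = 61)
  cmp <- compare_models(es, n_starts = 5, seed = 62)
  expect_identical(cmp$winner_aic, "M2_VM_UNIF")
  ll <- vapply(cmp$fits, `[[`, numeric(1), "log_lik")
  # log-likelihood weakly increases with model complexity at the optima
  expect_gte(ll["M2_VM_UNIF"], ll["M1_VM"] - 1e-6)
  expect_gte(ll["M3_VM_UNIF_NT"], ll["M2_VM_UNIF"] - 1e-6)
  # AIC deltas recompute from stored fields: 2*dk - 2*dlnL
  dk <- cmp$fits$M2_VM_UNIF$n_params - cmp$fits$M1_VM$n_params
  expect_equal(cmp$delta_aic["M2_VM_UNIF", "M1_VM"],
               2 * dk - 2 * (ll["M2_VM_UNIF"] - ll["M1_VM"]),
               ignore_attr = TRUE)
  expect_true(all(cmp$delta_aic == -t(cmp$delta_aic)))
  # without offsets only the two nested models are compared
  cmp2 <- compare_models(error_set(make_m2_errors(500, seed = 63)),
                         n_starts = 3, seed = 64)
  expect_named(cmp2$fits, c("M1_VM", "M2_VM_UNIF"))
})

test_that("free-mu mode estimates a response bias and adds a parameter", {
  set.seed(71)
  e <- wrap_error(wrap_angle(make_m2_errors(3000, 0.7, 12, seed = 72) + 15), 0)
  f_fixed <- fit_model(error_set(e), "M2_VM_UNIF", n_starts = 5, seed = 73)
  f_free <- fit_model(error_set(e), "M2_VM_UNIF", n_starts = 5, seed = 73,
                      mu_mode = "free")
  expect_equal(f_free$mu, 15, tolerance = 1.5)
  expect_equal(f_free$n_params, f_fixed$n_params + 1)
  expect_gte(f_free$log_lik, f_fixed$log_lik)
})
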