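test_that("per-study log relative risk matches hand arithmetic", {
  # 255/817 vs 790/847: log((255/817)/(790/847))
  eff <- study_log_rr(list(trial_id = "dp1", events_t = 255, n_t = 817,
                           events_c = 790, n_c = 847))
  expect_equal(eff$log_rr, -1.094708, tolerance = 1e-6)
  expect_equal(eff$var_log_rr, 1 / 255 - 1 / 817 + 1 / 790 - 1 / 847)
  expect_false(eff$corrected)

  # identical arms: zero effect, variance 0.02 exactly
  same <- study_log_rr(list(trial_id = "s", events_t = 50, n_t = 100,
                            events_c = 50, n_c = 100))
  expect_equal(same$log_rr, 0)
  expect_equal(same$var_log_rr, 0.02)

  # zero-cell path: continuity correction gives a finite flagged effect
  zc <- study_log_rr(list(trial_id = "z", events_t = 0, n_t = 10,
                          events_c = 5, n_c = 10), cc = 0.5)
  expect_true(is.finite(zc$log_rr) && zc$var_log_rr > 0)
  expect_true(zc$corrected)
  expect_equal(zc$log_rr, log((0.5 / 11) / (5.5 / 11)))
  expect_error(study_log_rr(list(trial_id = "z", events_t = 0, n_t = 10,
                                 events_c = 5, n_c = 10), cc = 0),
               "undefined")
})

test_that("DerSimonian-Laird pooling matches frozen hand computation and metafor", {
  studies <- data.frame(log_rr = c(-0.5, -1.0, -1.5),
                        var_log_rr = c(0.04, 0.09, 0.16))
  est <- pool_dersimonian_laird(studies)
  # values from an independent evaluation of the moment formulas
  expect_equal(est$q, 5.7377049180, tolerance = 1e-9)
  expect_equal(est$tau2, 0.1572413793, tolerance = 1e-9)
  expect_equal(est$log_rr, -0.9218310230, tolerance = 1e-9)
  expect_equal(est$se_log_rr, 0.2855193322, tolerance = 1e-9)
  expect_equal(est$i2, 0.6514285714, tolerance = 1e-9)
  expect_equal(est$rrr, 1 - est$pooled_rr)

  skip_if_not_installed("metafor")
  ref <- metafor::rma(yi = studies$log_rr, vi = studies$var_log_rr,
                      method = "DL")
  expect_equal(est$log_rr, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(est$tau2, ref$tau2, tolerance = 1e-8)
  expect_equal(unname(est$ci), exp(c(ref$ci.lb, ref$ci.ub)),
               tolerance = 1e-8)

  reml <- pool_dersimonian_laird(studies, method = "REML")
  ref_reml <- metafor::rma(yi = studies$log_rr, vi = studies$var_log_rr,
                           method = "REML")
  expect_equal(reml$tau2, ref_reml$tau2, tolerance = 1e-4)
  expect_equal(reml$log_rr, as.numeric(ref_reml$beta), tolerance = 1e-4)
})

test_that("degenerate pooling cases behave as closed forms require", {
  # a single study passes through with tau^2 = 0
  one <- pool_dersimonian_laird(
    data.frame(log_rr = -1.094708, var_log_rr = 0.0027825))
  expect_equal(one$pooled_rr, exp(-1.094708), tolerance = 1e-6)
  expect_equal(one$tau2, 0)
  expect_true(one$single_study)
  expect_error(pool_dersimonian_laird(data.frame(log_rr = numeric(0),
                                                 var_log_rr = numeric(0))),
               "no studies")

  # two identical studies: no heterogeneity, CI shrinks by 1/sqrt(2)
  two <- pool_dersimonian_laird(data.frame(log_rr = c(-0.7, -0.7),
                                           var_log_rr = c(0.05, 0.05)))
  expect_equal(two$log_rr, -0.7)
  expect_equal(two$q, 0)
  expect_equal(two$tau2, 0)
  expect_equal(two$se_log_rr, sqrt(0.05) / sqrt(2))
})

test_that("pooling invariants hold across generated study sets", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    y <- rnorm(k, -0.8, 0.5)
    v <- runif(k, 0.01, 0.3)
    est <- pool_dersimonian_laird(data.frame(log_rr = y, var_log_rr = v))
    # pooled estimate lies within the study range
    expect_gte(est$log_rr, min(y))
    expect_lte(est$log_rr, max(y))
    # with tau^2 = 0 the random-effects estimate is the fixed-effect one
    if (est$tau2 == 0) {
      expect_equal(est$log_rr, sum(y / v) / sum(1 / v), tolerance = 1e-12)
    }
    expect_true(est$ci[["low"]] <= est$pooled_rr &&
                  est$pooled_rr <= est$ci[["high"]])
  }
})

test_that("inflating equal variances keeps the point estimate and widens the CI", {
  # point estimate is scale-free for an equal-variance pair; the CI widens
  # in the homogeneous regime (tau^2 = 0). When the moment estimator is
  # interior, tau^2 absorbs the rescaling exactly (v + tau^2 = (y1-y2)^2/2),
  # so the total variance - and the CI - is unchanged by design.
  y <- c(-0.70, -0.75)
  base <- pool_dersimonian_laird(data.frame(log_rr = y,
                                            var_log_rr = c(0.05, 0.05)))
  wide <- pool_dersimonian_laird(data.frame(log_rr = y,
                                            var_log_rr = c(0.15, 0.15)))
  expect_equal(base$tau2, 0)
  expect_equal(wide$log_rr, base$log_rr, tolerance = 1e-12)
  expect_gt(log(wide$ci[["high"]]) - log(wide$ci[["low"]]),
            log(base$ci[["high"]]) - log(base$ci[["low"]]))

  het <- c(-0.4, -1.1)
  b2 <- pool_dersimonian_laird(data.frame(log_rr = het,
                                          var_log_rr = c(0.05, 0.05)))
  w2 <- pool_dersimonian_laird(data.frame(log_rr = het,
                                          var_log_rr = c(0.15, 0.15)))
  expect_equal(w2$log_rr, b2$log_rr, tolerance = 1e-12)
  expect_gte(log(w2$ci[["high"]]) - log(w2$ci[["low"]]),
             log(b2$ci[["high"]]) - log(b2$ci[["low"]]) - 1e-12)
})

test_that("pooling recovers the generative mean and heterogeneity at k = 200", {
  s <- sim_scenario(trials_per_intervention = 200L, mu_log_rr = -1.0,
                    tau = 0.3, control_risk = 0.9,
                    arm_size_range = c(500L, 1000L), seed = 42L)
  trials <- simulate_trials(s)
  est <- estimate_effectiveness(trials)[[1]]
  expect_lt(abs(est$log_rr - (-1.0)), 0.05)
  expect_gt(est$tau2, 0.5 * 0.09)
  expect_lt(est$tau2, 1.5 * 0.09)
})
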