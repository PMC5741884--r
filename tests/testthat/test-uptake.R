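test_that("cascade uptake multiplies levels and scales the denominator", {
  r <- cascade_uptake(delayed_cascade())
  expect_equal(r$proportion, (22 / 61) * (48 / 92), tolerance = 1e-15)
  expect_equal(r$numerator, 48L)
  expect_equal(r$effective_denominator, 255L)          # 92 x (61/22)
  expect_equal(r$effective_denominator_exact, 92 * 61 / 22)
  # proportion == numerator / unrounded denominator to machine precision
  expect_equal(r$proportion, r$numerator / r$effective_denominator_exact,
               tolerance = 1e-15)

  single <- cascade_uptake(recruitment_cascade("pct1", "pct", 53L, 345L))
  expect_equal(single$proportion, 53 / 345)
  expect_equal(single$effective_denominator, 345L)

  full <- cascade_uptake(recruitment_cascade("f", "x", 40L, 40L))
  expect_equal(full$proportion, 1)
})

test_that("cascade uptake is invariant to full-participation levels and rejects empty outer levels", {
  base <- cascade_uptake(recruitment_cascade("a", "x", c(10L, 30L),
                                             c(20L, 60L)))
  padded <- cascade_uptake(recruitment_cascade(
    "a", "x", c(10L, 15L, 30L), c(20L, 15L, 60L)))
  expect_equal(padded$proportion, base$proportion, tolerance = 1e-15)

  expect_error(cascade_uptake(recruitment_cascade("z", "x", c(0L, 5L),
                                                  c(20L, 60L))),
               "outer level 1")
})

test_that("binomial intervals agree with brute-force CDF inversion", {
  cases <- rbind(c(48, 255), c(53, 345), c(35, 125), c(3, 17), c(101, 2036))
  for (i in seq_len(nrow(cases))) {
    x <- cases[i, 1]; n <- cases[i, 2]
    got <- binomial_ci(x, n, method = "clopper_pearson")
    want <- cp_ci_bruteforce(x, n)
    expect_equal(unname(got[1:2]), unname(want), tolerance = 1e-8)
  }
  # boundaries
  expect_equal(binomial_ci(0, 10)[["low"]], 0)
  expect_equal(binomial_ci(10, 10)[["high"]], 1)

  # the three methods all cover the observed proportion; the exact interval
  # is the widest (the conservative one). Wald vs Wilson ordering is
  # case-dependent: at 35/125 Wilson is in fact slightly narrower than Wald.
  ci_cp <- binomial_ci(35, 125, method = "clopper_pearson")
  ci_wi <- binomial_ci(35, 125, method = "wilson")
  ci_wa <- binomial_ci(35, 125, method = "wald")
  for (ci in list(ci_cp, ci_wi, ci_wa)) {
    expect_true(ci[["low"]] < 0.28 && 0.28 < ci[["high"]])
  }
  expect_gte(diff(unname(ci_cp[1:2])), diff(unname(ci_wi[1:2])))
  expect_gte(diff(unname(ci_cp[1:2])), diff(unname(ci_wa[1:2])))
  expect_lt(diff(unname(ci_wi[1:2])), diff(unname(ci_wa[1:2])))
})

test_that("Clopper-Pearson attains nominal coverage for small n (exact enumeration)", {
  for (n in c(5L, 12L, 30L)) {
    cis <- t(vapply(0:n, function(x) binomial_ci(x, n), c(low = 0, high = 0)))
    for (p in c(0.1, 0.3, 0.5)) {
      covered <- cis[, "low"] <= p & p <= cis[, "high"]
      coverage <- sum(stats::dbinom(0:n, n, p)[covered])
      expect_gte(coverage, 0.95)
    }
  }
})

test_that("random-intercept pooling agrees with grid-search and lme4 oracles", {
  x <- c(45, 101, 135); n <- c(345, 2036, 1008)
  fit <- uptake_glmm(x, n)
  oracle <- grid_glmm_fit(x, n)
  expect_lt(abs(fit$marginal$mean - oracle$marginal), 1e-4)
  expect_equal(fit$beta0, oracle$beta0, tolerance = 5e-3)
  expect_equal(fit$sigma, oracle$sigma, tolerance = 5e-3)
  expect_true(fit$converged)
  expect_false(fit$boundary)

  skip_if_not_installed("lme4")
  d <- data.frame(x = x, n = n, trial = factor(seq_along(x)))
  ref <- lme4::glmer(cbind(x, n - x) ~ 1 + (1 | trial), data = d,
                     family = stats::binomial(), nAGQ = 25L)
  expect_equal(fit$beta0, unname(lme4::fixef(ref)), tolerance = 1e-3)
  expect_equal(fit$sigma,
               sqrt(unname(lme4::VarCorr(ref)$trial[1, 1])),
               tolerance = 1e-2)
})

test_that("no between-trial variation drives sigma to the boundary", {
  fit <- uptake_glmm(c(30, 30, 30), c(100, 100, 100))
  expect_true(fit$boundary)
  expect_equal(fit$marginal$mean, 0.30, tolerance = 1e-6)
  # with sigma at 0 the fit reproduces the simple pooled binomial estimate
  fit2 <- uptake_glmm(c(20, 40, 60), c(100, 200, 300))
  if (fit2$boundary) {
    expect_equal(fit2$marginal$mean, 120 / 600, tolerance = 1e-6)
  }
  expect_equal(stats::plogis(fit$beta0), 0.30, tolerance = 1e-6)
})

test_that("cascade pooling validates its inputs", {
  cs <- worked_example_cascades()[4:6]
  est <- pool_uptake_glmm(cs)
  expect_s3_class(est$fit, "uptake_glmm")
  expect_equal(est$numerator, 281L)
  expect_equal(est$effective_denominator, 3389L)
  expect_identical(est$method, "pooled_glmm")

  expect_error(pool_uptake_glmm(cs[1]), "cascade_uptake")

  np <- recruitment_cascade("ac1", "shared_decision_making", 9L, 10L,
                            population_based = FALSE)
  expect_warning(est2 <- pool_uptake_glmm(c(cs, list(np))),
                 "non-population-based")
  expect_equal(est2$n_trials, 3L)
})

test_that("uptake dispatch: single trials get binomial CIs, multiple get the GLMM", {
  ests <- estimate_uptake(worked_example_cascades())
  expect_identical(ests$delayed_prescribing$method, "single_trial")
  expect_identical(ests$shared_decision_making$method, "pooled_glmm")
  expect_equal(ests$delayed_prescribing$ci[["low"]], 0.142173,
               tolerance = 1e-4)
  expect_equal(ests$crp$proportion, 0.28)
})

test_that("the pooled model recovers its generative parameters", {
  s <- sim_scenario(trials_per_intervention = 50L,
                    uptake_beta0 = -1.8, uptake_sigma = 0.5,
                    practices_approached_range = c(300L, 300L),
                    recruitment_levels = 1L, seed = 19L)
  cs <- simulate_recruitment(s)
  fit <- pool_uptake_glmm(cs)$fit
  expect_lt(abs(fit$beta0 - (-1.8)), 0.15)
  expect_lt(abs(fit$sigma - 0.5), 0.2)
})
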