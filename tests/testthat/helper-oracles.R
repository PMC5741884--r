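# Independent oracles, kept deliberately separate from the package's own
# code paths: the exact binomial interval is found by root-finding on the
# binomial CDF itself, and the random-intercept model by brute-force grid
# search with trapezoid integration of the marginal likelihood.

# Clopper-Pearson bounds by direct inversion of the binomial tails
cp_ci_bruteforce <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  low <- if (x == 0) 0 else {
    stats::uniroot(function(p) 1 - stats::pbinom(x - 1, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  high <- if (x == n) 1 else {
    stats::uniroot(function(p) stats::pbinom(x, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(low = low, high = high)
}

# log marginal likelihood of the random-intercept binomial model by dense
# trapezoid integration over the random effect
grid_glmm_loglik <- function(beta0, sigma, x, n, width = 6, m = 2001L) {
  us <- seq(-width * sigma, width * sigma, length.out = m)
  du <- us[2] - us[1]
  sum(vapply(seq_along(x), function(j) {
    log(sum(stats::dbinom(x[j], n[j], stats::plogis(beta0 + us)) *
              stats::dnorm(us, 0, sigma)) * du)
  }, 0))
}

# coarse-to-fine grid maximisation of the marginal likelihood
grid_glmm_fit <- function(x, n, b0_range = c(-4, 0), s_range = c(0.05, 1.5)) {
  b0s <- seq(b0_range[1], b0_range[2], by = 0.02)
  ss <- seq(s_range[1], s_range[2], by = 0.02)
  ll <- outer(b0s, ss, Vectorize(function(b, s) grid_glmm_loglik(b, s, x, n)))
  ij <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  b0c <- b0s[ij[1]]; sc <- ss[ij[2]]
  b0f <- seq(b0c - 0.03, b0c + 0.03, by = 0.001)
  sf <- seq(max(0.005, sc - 0.03), sc + 0.03, by = 0.001)
  ll2 <- outer(b0f, sf, Vectorize(function(b, s) grid_glmm_loglik(b, s, x, n)))
  ij2 <- which(ll2 == max(ll2), arr.ind = TRUE)[1, ]
  beta0 <- b0f[ij2[1]]; sigma <- sf[ij2[2]]
  us <- seq(-6 * sigma, 6 * sigma, length.out = 4001L)
  marg <- sum(stats::plogis(beta0 + us) * stats::dnorm(us, 0, sigma)) *
    (us[2] - us[1])
  list(beta0 = beta0, sigma = sigma, marginal = marg)
}

# small fixture builders
delayed_cascade <- function() {
  recruitment_cascade("dp1", "delayed_prescribing", c(22L, 48L), c(61L, 92L),
                      c("practice", "clinician"))
}

worked_example_effects <- function() {
  list(delayed_prescribing = effect_estimate("delayed_prescribing",
                                             0.36, 0.27, 0.48),
       procalcitonin = effect_estimate("procalcitonin", 0.39, 0.17, 0.86),
       crp = effect_estimate("crp", 0.78, 0.66, 0.92),
       shared_decision_making = effect_estimate("shared_decision_making",
                                                0.61, 0.55, 0.68))
}

worked_example_cascades <- function() {
  list(delayed_cascade(),
       recruitment_cascade("pct1", "procalcitonin", 53L, 345L),
       recruitment_cascade("crp1", "crp", 35L, 125L),
       recruitment_cascade("sdm1", "shared_decision_making", 45L, 345L),
       recruitment_cascade("sdm2", "shared_decision_making", 101L, 2036L),
       recruitment_cascade("sdm3r", "shared_decision_making", 135L, 1008L))
}

worked_example_model <- function(mc_draws = 2000L) {
  estimate_impact(effects = worked_example_effects(),
                  recruitment = worked_example_cascades(),
                  config = run_config(mc_draws = mc_draws, seed = 7L))
}
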