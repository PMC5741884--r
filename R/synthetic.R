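# Synthetic multi-trial data with the generative structure the analysis
# assumes: heterogeneous true log relative risks across trials (normal
# random effects), binomial arm outcomes, and trial-level normal random
# effects on the participation log-odds of the recruitment process.
# Defaults emulate the antibiotic-prescribing setting: control-arm event
# risk ~0.9 (most patients prescribed under usual care), true RR ~0.36,
# moderate heterogeneity, ~19% clinician participation.

#' Simulation scenario
#'
#' Collects the generative parameters for [simulate_trials()] and
#' [simulate_recruitment()]. One shared `seed` governs a per-trial splittable
#' stream (trial `j` uses `seed + 1000 j`), so trials are independent yet the
#' whole dataset is reproducible.
#'
#' @param n_interventions number of interventions.
#' @param trials_per_intervention trials per intervention.
#' @param mu_log_rr mean true log relative risk (default `log(0.36)`).
#' @param tau between-trial SD of the log relative risk (default 0.3).
#' @param control_risk control-arm event probability (default 0.9).
#' @param arm_size_range integer range for per-arm sample sizes.
#' @param uptake_beta0 mean participation log-odds (default `qlogis(0.19)`).
#' @param uptake_sigma between-trial SD of the participation log-odds.
#' @param practices_approached_range integer range for outer-level units
#'   approached per trial (for single-level cascades, the clinicians
#'   approached).
#' @param clinicians_per_practice_range integer range for clinicians per
#'   participating practice (used when `recruitment_levels = 2`).
#' @param recruitment_levels 1 (clinicians approached directly, default) or
#'   2 (practices then clinicians; each level gets its own random effect, so
#'   the cascade product is the product of two participation probabilities).
#' @param seed base seed.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_interventions = 1L, trials_per_intervention = 5L,
                         mu_log_rr = log(0.36), tau = 0.3,
                         control_risk = 0.9, arm_size_range = c(200L, 800L),
                         uptake_beta0 = stats::qlogis(0.19),
                         uptake_sigma = 0.5,
                         practices_approached_range = c(20L, 60L),
                         clinicians_per_practice_range = c(2L, 6L),
                         recruitment_levels = 1L, seed = 1L) {
  stopifnot(n_interventions >= 1, trials_per_intervention >= 1,
            tau >= 0, control_risk > 0, control_risk < 1,
            uptake_sigma >= 0,
            arm_size_range[1] >= 1, arm_size_range[2] >= arm_size_range[1],
            practices_approached_range[1] >= 1,
            practices_approached_range[2] >= practices_approached_range[1],
            clinicians_per_practice_range[1] >= 1,
            recruitment_levels %in% c(1L, 2L))
  structure(list(n_interventions = as.integer(n_interventions),
                 trials_per_intervention = as.integer(trials_per_intervention),
                 mu_log_rr = mu_log_rr, tau = tau,
                 control_risk = control_risk,
                 arm_size_range = as.integer(arm_size_range),
                 uptake_beta0 = uptake_beta0, uptake_sigma = uptake_sigma,
                 practices_approached_range =
                   as.integer(practices_approached_range),
                 clinicians_per_practice_range =
                   as.integer(clinicians_per_practice_range),
                 recruitment_levels = as.integer(recruitment_levels),
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

.sim_ids <- function(s) {
  idx <- 0L
  out <- vector("list", s$n_interventions * s$trials_per_intervention)
  for (i in seq_len(s$n_interventions)) {
    for (j in seq_len(s$trials_per_intervention)) {
      idx <- idx + 1L
      out[[idx]] <- list(idx = idx,
                         trial_id = sprintf("sim%02d_t%03d", i, j),
                         intervention_id = sprintf("int%02d", i))
    }
  }
  out
}

.draw_int <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1L)
}

#' Simulate trial outcome tables
#'
#' Per trial: draw a true log relative risk from
#' `Normal(mu_log_rr, tau^2)`, draw per-arm sizes, then control events
#' `~ Binomial(n_c, control_risk)` and treated events
#' `~ Binomial(n_t, control_risk * exp(logRR))`, with the treated risk
#' clipped at 1 (a warning names the trial when clipping occurs).
#'
#' @param s a [sim_scenario()].
#' @return A validated `trial_outcomes` data frame.
#' @export
simulate_trials <- function(s) {
  rows <- lapply(.sim_ids(s), function(tr) {
    set.seed(s$seed + 1000L * tr$idx)
    lrr <- stats::rnorm(1, s$mu_log_rr, s$tau)
    n_t <- .draw_int(s$arm_size_range)
    n_c <- .draw_int(s$arm_size_range)
    p_t <- s$control_risk * exp(lrr)
    if (p_t > 1) {
      warning("treated risk clipped at 1 for trial '", tr$trial_id, "'",
              call. = FALSE)
      p_t <- 1
    }
    data.frame(trial_id = tr$trial_id, intervention_id = tr$intervention_id,
               events_t = stats::rbinom(1, n_t, p_t), n_t = n_t,
               events_c = stats::rbinom(1, n_c, s$control_risk), n_c = n_c,
               stringsAsFactors = FALSE)
  })
  validate_trials(do.call(rbind, rows))
}

#' Simulate recruitment cascades
#'
#' Per trial: draw a trial-level random effect `u ~ Normal(0,
#' uptake_sigma^2)` and participation counts
#' `~ Binomial(approached, expit(uptake_beta0 + u))`. With
#' `recruitment_levels = 2` the practice level is drawn first; participating
#' practices times a per-practice clinician count gives the clinicians
#' approached, who participate with their own random effect. A two-level
#' cascade whose practice level ends with zero participating practices
#' cannot be scaled and is flagged `usable = FALSE` (matching the
#' [cascade_uptake()] error path).
#'
#' @param s a [sim_scenario()].
#' @return List of [recruitment_cascade()] objects; unusable cascades carry
#'   attribute-like element `usable = FALSE`.
#' @export
simulate_recruitment <- function(s) {
  lapply(.sim_ids(s), function(tr) {
    set.seed(s$seed + 1000L * tr$idx + 500L)
    if (s$recruitment_levels == 1L) {
      a <- .draw_int(s$practices_approached_range)
      u <- stats::rnorm(1, 0, s$uptake_sigma)
      part <- stats::rbinom(1, a, stats::plogis(s$uptake_beta0 + u))
      cs <- recruitment_cascade(tr$trial_id, tr$intervention_id,
                                part, a, "clinician")
      cs$usable <- TRUE
      cs
    } else {
      a_p <- .draw_int(s$practices_approached_range)
      u_p <- stats::rnorm(1, 0, s$uptake_sigma)
      part_p <- stats::rbinom(1, a_p, stats::plogis(s$uptake_beta0 + u_p))
      if (part_p == 0L) {
        warning("trial '", tr$trial_id, "': no participating practices; ",
                "cascade flagged unusable", call. = FALSE)
        cs <- recruitment_cascade(tr$trial_id, tr$intervention_id,
                                  c(0L, 0L), c(a_p, 1L),
                                  c("practice", "clinician"))
        cs$usable <- FALSE
        return(cs)
      }
      a_c <- part_p * .draw_int(s$clinicians_per_practice_range)
      u_c <- stats::rnorm(1, 0, s$uptake_sigma)
      part_c <- stats::rbinom(1, a_c, stats::plogis(s$uptake_beta0 + u_c))
      cs <- recruitment_cascade(tr$trial_id, tr$intervention_id,
                                c(part_p, part_c), c(a_p, a_c),
                                c("practice", "clinician"))
      cs$usable <- TRUE
      cs
    }
  })
}
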