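# Population impact: RRR x uptake, with an encounter-level decomposition.
# For a population of encounters that would receive the outcome (e.g. an
# antibiotic prescription) without the intervention:
#   averted           = uptake x RRR        (intervention used and effective)
#   uptake, no effect = uptake x RR         (used, outcome still occurs)
#   no uptake         = 1 - uptake          (intervention not taken up)
# The three strata always sum to 1.

#' Encounter-level decomposition of impact
#'
#' @param u uptake proportion in `[0, 1]`.
#' @param rr relative risk in `[0, 1]`.
#' @return Named numeric `(averted, uptake_no_effect, no_uptake)`; sums to 1.
#' @examples
#' decompose_encounters(48 / 255, 0.36)  # ~ 12% / 7% / 81%
#' @export
decompose_encounters <- function(u, rr) {
  stopifnot(u >= 0, u <= 1, rr >= 0, rr <= 1)
  c(averted = u * (1 - rr),
    uptake_no_effect = u * rr,
    no_uptake = 1 - u)
}

#' Population impact of one intervention
#'
#' Multiplies the relative risk reduction by the uptake proportion and
#' attaches the encounter decomposition. A negative RRR (harmful
#' intervention) is propagated as-is with a warning, never clipped.
#'
#' @param effect an `effect_estimate` (see [pool_dersimonian_laird()],
#'   [effect_estimate()]).
#' @param uptake an `uptake_estimate` (see [estimate_uptake()]).
#' @return An object of class `impact_estimate` with `intervention_id`,
#'   `rrr`, `rr`, `uptake`, `impact = rrr * uptake`, `strata`, and slots
#'   `ci`/`rank` filled later by [impact_ci_mc()] / [rank_interventions()].
#' @export
population_impact <- function(effect, uptake) {
  u <- uptake$proportion
  stopifnot(u >= 0, u <= 1)
  rrr <- effect$rrr
  if (rrr < 0) {
    warning("negative relative risk reduction for '", effect$intervention_id,
            "' (harmful intervention): impact propagated as-is", call. = FALSE)
  }
  strata <- if (rrr >= 0) decompose_encounters(u, effect$pooled_rr) else
    c(averted = u * rrr, uptake_no_effect = u * (1 - rrr), no_uptake = 1 - u)
  structure(list(intervention_id = effect$intervention_id,
                 rrr = rrr, rr = effect$pooled_rr, uptake = u,
                 impact = rrr * u,
                 strata = strata,
                 ci = c(low = NA_real_, high = NA_real_),
                 rank = NA_integer_,
                 effect = effect, uptake_est = uptake),
            class = "impact_estimate")
}

#' Monte Carlo confidence interval for population impact
#'
#' Propagates the effectiveness and uptake uncertainty to the impact scale
#' assuming independence between the two: the log relative risk is drawn
#' from a normal with SE recovered from the RR confidence interval, uptake
#' is drawn on the logit scale with SE recovered from its CI by the delta
#' method, and each draw's impact is `(1 - RR) x uptake`. Returns the
#' percentile interval, lower bound floored at 0 (for a beneficial
#' intervention). Deterministic given `seed`; the caller's RNG state is
#' preserved.
#'
#' @inheritParams population_impact
#' @param draws number of Monte Carlo draws (>= 1000).
#' @param seed integer seed.
#' @param level confidence level.
#' @return Named numeric `c(low, high)`.
#' @export
impact_ci_mc <- function(effect, uptake, draws = 100000L, seed = 1L,
                         level = 0.95) {
  stopifnot(draws >= 1000)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se_log_rr <- if (!is.null(effect$se_log_rr) && is.finite(effect$se_log_rr)) {
    effect$se_log_rr
  } else {
    (log(effect$ci[["high"]]) - log(effect$ci[["low"]])) / (2 * z)
  }
  p <- uptake$proportion
  lo <- uptake$ci[["low"]]; hi <- uptake$ci[["high"]]
  se_logit <- if (lo > 0 && hi < 1) {
    (stats::qlogis(hi) - stats::qlogis(lo)) / (2 * z)
  } else if (hi < 1) {
    # floored lower bound: recover the SE from the upper half-width alone
    (stats::qlogis(hi) - stats::qlogis(p)) / z
  } else {
    (stats::qlogis(p) - stats::qlogis(lo)) / z
  }

  point <- effect$rrr * p
  if (se_log_rr == 0 && se_logit == 0) {
    warning("degenerate (zero-width) input intervals: returning point mass",
            call. = FALSE)
    return(c(low = point, high = point))
  }

  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  log_rr <- stats::rnorm(draws, effect$log_rr, se_log_rr)
  u <- stats::plogis(stats::rnorm(draws, stats::qlogis(p), se_logit))
  imp <- (1 - exp(log_rr)) * u
  qs <- unname(stats::quantile(imp, c((1 - level) / 2, 1 - (1 - level) / 2)))
  if (effect$rrr >= 0) qs[1] <- max(0, qs[1])
  c(low = qs[1], high = qs[2])
}

#' Rank interventions by population impact
#'
#' Descending by impact; ties broken by higher uptake, then by
#' `intervention_id` alphabetically. Rank 1 is the largest impact.
#'
#' @param impacts list of `impact_estimate` objects.
#' @return The same list (same order) with `rank` filled; a permutation of
#'   `1..K`.
#' @export
rank_interventions <- function(impacts) {
  stopifnot(length(impacts) >= 1L)
  imp <- vapply(impacts, function(x) x$impact, 0)
  upt <- vapply(impacts, function(x) x$uptake, 0)
  id <- vapply(impacts, function(x) x$intervention_id, "")
  ord <- order(-imp, -upt, id)
  rk <- integer(length(ord))
  rk[ord] <- seq_along(ord)
  for (i in seq_along(impacts)) impacts[[i]]$rank <- rk[i]
  impacts
}

#' @export
print.impact_estimate <- function(x, ...) {
  cat(sprintf("Impact for '%s': RRR %.1f%% x uptake %.1f%% = %.1f%%",
              x$intervention_id, 100 * x$rrr, 100 * x$uptake,
              100 * x$impact))
  if (is.finite(x$ci[["low"]])) {
    cat(sprintf(" (CI %.1f%%-%.1f%%)", 100 * x$ci[["low"]],
                100 * x$ci[["high"]]))
  }
  if (!is.na(x$rank)) cat(sprintf(", rank %d", x$rank))
  cat("\n")
  invisible(x)
}

# ---- top-level fit ------------------------------------------------------

#' Estimate the population impact of a set of interventions
#'
#' The full pipeline: per-intervention pooled effectiveness (computed from
#' trial counts or supplied as reported pooled relative risks), uptake from
#' recruitment cascades (single-trial binomial or pooled random-intercept
#' model), the impact product with its encounter decomposition, Monte Carlo
#' confidence intervals, and ranking.
#'
#' Exactly one of `trials`/`effects` must be given; uptake comes from
#' `recruitment` (cascades) or a precomputed `uptake` list.
#'
#' @param trials a `trial_outcomes` data frame ([read_trials()]);
#'   effectiveness is then meta-analysed per intervention.
#' @param effects named list of `effect_estimate` objects (e.g. from
#'   [read_effects()]), used as-is.
#' @param recruitment list of [recruitment_cascade()] objects
#'   ([read_recruitment()]).
#' @param uptake named list of `uptake_estimate` objects, used as-is.
#' @param config a [run_config()].
#' @return An object of class `impact_model`: `estimates` (named list of
#'   ranked `impact_estimate`s), `effects`, `uptake`, `config`. Methods:
#'   `print`, `summary`, `coef` (impact proportions), `plot` (stacked
#'   decomposition bars).
#' @examples
#' eff <- list(a = effect_estimate("a", 0.36, 0.27, 0.48))
#' cs <- list(recruitment_cascade("t1", "a", c(22, 48), c(61, 92),
#'                                c("practice", "clinician")))
#' fit <- estimate_impact(effects = eff, recruitment = cs)
#' coef(fit)
#' @export
estimate_impact <- function(trials = NULL, effects = NULL,
                            recruitment = NULL, uptake = NULL,
                            config = run_config()) {
  if (is.null(effects) == is.null(trials)) {
    stop("supply exactly one of 'trials' or 'effects'", call. = FALSE)
  }
  if (is.null(uptake) == is.null(recruitment)) {
    stop("supply exactly one of 'recruitment' or 'uptake'", call. = FALSE)
  }
  if (is.null(effects)) {
    effects <- estimate_effectiveness(trials, level = config$ci_level)
  }
  if (is.null(uptake)) {
    uptake <- estimate_uptake(recruitment, level = config$ci_level,
                              ci_method = config$ci_method)
  }
  e_ids <- vapply(effects, function(x) x$intervention_id, "")
  u_ids <- vapply(uptake, function(x) x$intervention_id, "")
  unmatched <- c(setdiff(e_ids, u_ids), setdiff(u_ids, e_ids))
  if (length(unmatched) > 0L) {
    stop("intervention_id mismatch between effects and uptake: ",
         paste(unique(unmatched), collapse = ", "), call. = FALSE)
  }
  names(effects) <- e_ids
  names(uptake) <- u_ids
  estimates <- lapply(seq_along(e_ids), function(i) {
    id <- e_ids[i]
    est <- population_impact(effects[[id]], uptake[[id]])
    est$ci <- impact_ci_mc(effects[[id]], uptake[[id]],
                           draws = config$mc_draws,
                           seed = config$seed + i - 1L,
                           level = config$ci_level)
    est
  })
  estimates <- rank_interventions(estimates)
  names(estimates) <- e_ids
  structure(list(estimates = estimates, effects = effects, uptake = uptake,
                 config = config),
            class = "impact_model")
}

#' @export
print.impact_model <- function(x, ...) {
  cat("Population impact model (", length(x$estimates),
      " intervention(s))\n\n", sep = "")
  tbl <- render_summary_table(x)
  print(tbl, row.names = FALSE)
  fn <- attr(tbl, "footnotes")
  if (length(fn)) cat("\n", paste0("  ", fn, collapse = "\n"), "\n", sep = "")
  invisible(x)
}

#' @export
summary.impact_model <- function(object, ...) {
  cat("Population impact = relative risk reduction x uptake\n\n")
  for (est in object$estimates[order(vapply(object$estimates,
                                            function(e) e$rank, 0L))]) {
    print(est)
    eff <- est$effect
    if (!is.na(eff$tau2)) {
      cat(sprintf("    effectiveness: k = %d, tau^2 = %.4f, I^2 = %.1f%%\n",
                  eff$k, eff$tau2, 100 * eff$i2))
    }
    ue <- est$uptake_est
    if (ue$method == "pooled_glmm") {
      cat(sprintf("    uptake: %d trials pooled, sigma = %.3f%s\n",
                  ue$n_trials, ue$fit$sigma,
                  if (ue$fit$boundary) " (boundary)" else ""))
    }
  }
  invisible(object)
}

#' @export
coef.impact_model <- function(object, ...) {
  vapply(object$estimates, function(e) e$impact, 0)
}

#' @export
plot.impact_model <- function(x, ...) {
  dec <- render_decomposition(x)
  ids <- unique(dec$intervention_id)
  m <- vapply(ids, function(id)
    dec$fraction[dec$intervention_id == id], numeric(3))
  rownames(m) <- c("averted", "uptake, no effect", "no uptake")
  graphics::barplot(m, legend.text = rownames(m),
                    col = c("#1b7837", "#a6dba0", "#c2a5cf"),
                    ylab = "fraction of encounters",
                    args.legend = list(x = "topright", bg = "white"), ...)
  invisible(x)
}
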