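# Random-effects meta-analysis of relative risks: per-study log-RR with
# sampling variance, DerSimonian-Laird (or REML) between-study variance,
# inverse-variance pooling with a Wald interval on the log scale.

#' Per-study log relative risk
#'
#' Computes the natural-log relative risk and its large-sample variance from
#' one trial's 2x2 counts:
#' `log RR = log((a/n1)/(c/n2))`, `var = 1/a - 1/n1 + 1/c - 1/n2`.
#' When either event count is zero, the continuity correction `cc` is added
#' to all four cells (each arm's events and non-events, so totals grow by
#' `2 cc`) before computing, and the result is flagged `corrected`.
#'
#' @param trial a list or one-row data frame with fields `events_t`, `n_t`,
#'   `events_c`, `n_c` and optionally `trial_id`.
#' @param cc continuity correction added to all cells on a zero event count
#'   (default 0.5, the usual convention); `cc = 0` turns the correction off,
#'   in which case a zero cell is an error.
#' @return A one-row data frame with columns `trial_id`, `log_rr`,
#'   `var_log_rr`, `corrected`.
#' @examples
#' study_log_rr(list(trial_id = "dp1", events_t = 255, n_t = 817,
#'                   events_c = 790, n_c = 847))
#' @export
study_log_rr <- function(trial, cc = 0.5) {
  a <- trial$events_t; n1 <- trial$n_t
  b <- trial$events_c; n2 <- trial$n_c
  id <- if (!is.null(trial$trial_id)) as.character(trial$trial_id) else NA_character_
  if (cc < 0) stop("cc must be >= 0", call. = FALSE)
  corrected <- FALSE
  if (a == 0 || b == 0) {
    if (cc == 0) {
      stop("undefined effect for trial '", id,
           "': zero event count and cc = 0", call. = FALSE)
    }
    a <- a + cc; n1 <- n1 + 2 * cc
    b <- b + cc; n2 <- n2 + 2 * cc
    corrected <- TRUE
  }
  log_rr <- log((a / n1) / (b / n2))
  v <- 1 / a - 1 / n1 + 1 / b - 1 / n2
  if (!is.finite(log_rr) || !is.finite(v) || v <= 0) {
    stop("undefined effect for trial '", id,
         "': degenerate counts give non-positive variance", call. = FALSE)
  }
  data.frame(trial_id = id, log_rr = log_rr, var_log_rr = v,
             corrected = corrected, stringsAsFactors = FALSE)
}

#' Log relative risks for a table of trials
#'
#' Applies [study_log_rr()] row-wise, carrying `intervention_id` through.
#'
#' @param trials a `trial_outcomes` data frame (see [read_trials()]).
#' @inheritParams study_log_rr
#' @return Data frame with columns `trial_id`, `intervention_id`, `log_rr`,
#'   `var_log_rr`, `corrected`.
#' @export
study_effects <- function(trials, cc = 0.5) {
  out <- do.call(rbind, lapply(seq_len(nrow(trials)), function(i) {
    eff <- study_log_rr(trials[i, ], cc = cc)
    eff$intervention_id <- trials$intervention_id[i]
    eff
  }))
  out[, c("trial_id", "intervention_id", "log_rr", "var_log_rr", "corrected")]
}

#' Pool study effects with a random-effects model
#'
#' DerSimonian-Laird moment estimation of the between-study variance tau^2,
#' followed by inverse-variance pooling with random-effects weights
#' `1/(v_i + tau^2)` and a Wald confidence interval on the log scale.
#' With fixed-effect weights `w_i = 1/v_i`, Cochran's
#' `Q = sum w_i (y_i - y_FE)^2`,
#' `tau^2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`, and
#' `I^2 = max(0, (Q - (k-1))/Q)`. `method = "REML"` instead maximises the
#' restricted likelihood over tau^2 (Q and I^2 are still the moment-based
#' diagnostics).
#'
#' A single study is passed through unchanged (`tau^2 = 0`) and flagged
#' `single_study`.
#'
#' @param studies data frame with columns `log_rr` and `var_log_rr`
#'   (as from [study_effects()]); one row per study, `k >= 1`.
#' @param level confidence level (default 0.95).
#' @param method `"DL"` (default) or `"REML"`.
#' @param intervention_id optional label carried into the result.
#' @return An object of class `effect_estimate` with elements
#'   `intervention_id`, `k`, `pooled_rr`, `ci`, `rrr` (`1 - pooled_rr`),
#'   `log_rr`, `se_log_rr`, `tau2`, `q`, `i2`, `level`, `method`,
#'   `single_study`.
#' @examples
#' eff <- data.frame(log_rr = c(-0.5, -1.0, -1.5),
#'                   var_log_rr = c(0.04, 0.09, 0.16))
#' pool_dersimonian_laird(eff)
#' @export
pool_dersimonian_laird <- function(studies, level = 0.95,
                                   method = c("DL", "REML"),
                                   intervention_id = NA_character_) {
  method <- match.arg(method)
  y <- studies$log_rr
  v <- studies$var_log_rr
  k <- length(y)
  if (k == 0L) stop("no studies to pool", call. = FALSE)
  stopifnot(all(v > 0))
  z <- stats::qnorm(1 - (1 - level) / 2)

  if (k == 1L) {
    se <- sqrt(v)
    return(.effect_estimate(intervention_id, k, y, se, tau2 = 0, q = 0,
                            i2 = 0, z = z, level = level, method = method,
                            single_study = TRUE))
  }

  w <- 1 / v
  y_fe <- sum(w * y) / sum(w)
  q <- sum(w * (y - y_fe)^2)
  if (method == "DL") {
    denom <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - (k - 1)) / denom)
  } else {
    # profile restricted log-likelihood in tau^2
    rll <- function(t2) {
      wt <- 1 / (v + t2)
      mu <- sum(wt * y) / sum(wt)
      -0.5 * (sum(log(v + t2)) + log(sum(wt)) + sum(wt * (y - mu)^2))
    }
    opt <- stats::optimize(function(t2) -rll(t2),
                           interval = c(0, 10 * (max(v) + stats::var(y))))
    tau2 <- if (rll(0) >= rll(opt$minimum)) 0 else opt$minimum
  }
  ws <- 1 / (v + tau2)
  mu <- sum(ws * y) / sum(ws)
  se <- sqrt(1 / sum(ws))
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) else 0
  .effect_estimate(intervention_id, k, mu, se, tau2, q, i2, z, level, method,
                   single_study = FALSE)
}

.effect_estimate <- function(intervention_id, k, mu, se, tau2, q, i2, z,
                             level, method, single_study) {
  rr <- exp(mu)
  structure(list(intervention_id = intervention_id, k = k,
                 pooled_rr = rr,
                 ci = c(low = exp(mu - z * se), high = exp(mu + z * se)),
                 rrr = 1 - rr,
                 log_rr = mu, se_log_rr = se,
                 tau2 = tau2, q = q, i2 = i2,
                 level = level, method = method,
                 single_study = single_study),
            class = "effect_estimate")
}

#' Effect estimate from a reported pooled relative risk
#'
#' Wraps a published pooled RR with its confidence interval as an
#' `effect_estimate`, recovering the log-scale standard error from the CI
#' width. Used when per-study counts live in external reviews and only the
#' pooled summary is available as input.
#'
#' @param intervention_id label.
#' @param rr pooled relative risk.
#' @param ci_low,ci_high confidence bounds for `rr`.
#' @param level the level those bounds correspond to (default 0.95).
#' @param k number of studies behind the estimate, if known.
#' @return An `effect_estimate` with `tau2`, `q`, `i2` set to `NA` and
#'   `method = "reported"`.
#' @export
effect_estimate <- function(intervention_id, rr, ci_low, ci_high,
                            level = 0.95, k = NA_integer_) {
  stopifnot(rr > 0, ci_low > 0, ci_high >= ci_low)
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(intervention_id = intervention_id, k = k,
                 pooled_rr = rr, ci = c(low = ci_low, high = ci_high),
                 rrr = 1 - rr,
                 log_rr = log(rr),
                 se_log_rr = (log(ci_high) - log(ci_low)) / (2 * z),
                 tau2 = NA_real_, q = NA_real_, i2 = NA_real_,
                 level = level, method = "reported", single_study = NA),
            class = "effect_estimate")
}

#' Read reported pooled effects
#'
#' CSV schema: `intervention_id,rr,ci_low,ci_high` with an optional `k`
#' column. Each row becomes an [effect_estimate()].
#'
#' @param path path to the CSV file.
#' @param level confidence level of the reported intervals.
#' @return Named list of `effect_estimate` objects.
#' @export
read_effects <- function(path, level = 0.95) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("intervention_id", "rr", "ci_low", "ci_high"),
                 "effects table")
  if (!"k" %in% names(df)) df$k <- NA_integer_
  out <- lapply(seq_len(nrow(df)), function(i) {
    effect_estimate(df$intervention_id[i], df$rr[i], df$ci_low[i],
                    df$ci_high[i], level = level, k = df$k[i])
  })
  names(out) <- df$intervention_id
  message("read ", nrow(df), " pooled effect(s) from ", path)
  out
}

#' Meta-analyse effectiveness per intervention
#'
#' Groups a trial table by `intervention_id`, converts each trial to a log
#' relative risk and pools with [pool_dersimonian_laird()].
#'
#' @inheritParams study_effects
#' @inheritParams pool_dersimonian_laird
#' @return Named list of `effect_estimate` objects, one per intervention.
#' @export
estimate_effectiveness <- function(trials, cc = 0.5, level = 0.95,
                                   method = c("DL", "REML")) {
  method <- match.arg(method)
  eff <- study_effects(trials, cc = cc)
  ids <- unique(eff$intervention_id)
  out <- lapply(ids, function(id) {
    pool_dersimonian_laird(eff[eff$intervention_id == id, , drop = FALSE],
                           level = level, method = method,
                           intervention_id = id)
  })
  names(out) <- ids
  out
}

#' @export
print.effect_estimate <- function(x, digits = 3, ...) {
  cat("Pooled effect", if (!is.na(x$intervention_id))
    paste0(" for '", x$intervention_id, "'"), " (", x$method, ")\n", sep = "")
  cat(sprintf("  RR = %.*f (%.0f%% CI %.*f-%.*f), RRR = %.1f%%\n",
              digits, x$pooled_rr, 100 * x$level, digits, x$ci[["low"]],
              digits, x$ci[["high"]], 100 * x$rrr))
  if (!is.na(x$tau2)) {
    cat(sprintf("  k = %d, tau^2 = %.4f, Q = %.2f, I^2 = %.1f%%\n",
                x$k, x$tau2, x$q, 100 * x$i2))
  }
  if (isTRUE(x$single_study)) cat("  (single study: pooled = study estimate)\n")
  invisible(x)
}
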