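# Clinician uptake from trial recruitment cascades.
#
# A cascade's uptake is the product of per-level participation proportions;
# the matching count pair is (innermost participated) out of an "effective
# denominator" that scales the innermost approached count up by the inverse
# participation at the outer levels (e.g. 48 of 92 x (61/22) = 255 potential
# clinicians). Single trials get a binomial CI; several trials are pooled
# with a random-intercept binomial logistic model fitted by adaptive
# Gauss-Hermite quadrature.

#' Uptake of one recruitment cascade
#'
#' Multiplies the per-level participation proportions and forms the
#' effective-denominator count pair: `numerator` is the innermost
#' participated count and the (unrounded) effective denominator is the
#' innermost approached count times `prod(approached/participated)` over the
#' outer levels, so that `proportion == numerator / effective denominator`
#' to machine precision. The denominator is additionally reported rounded to
#' the nearest integer for tabulation and for use as a binomial `n`.
#'
#' @param cascade a [recruitment_cascade()].
#' @return List with `proportion`, `numerator`, `effective_denominator`
#'   (integer), `effective_denominator_exact`, and `n_levels`.
#' @examples
#' cs <- recruitment_cascade("dp1", "delayed", c(22, 48), c(61, 92),
#'                           c("practice", "clinician"))
#' cascade_uptake(cs)  # 48 / 255 potential clinicians
#' @export
cascade_uptake <- function(cascade) {
  lv <- cascade$levels
  m <- nrow(lv)
  outer <- seq_len(m - 1L)
  if (m > 1L && any(lv$participated[outer] == 0L)) {
    bad <- which(lv$participated[outer] == 0L)[1L]
    stop("cannot scale cascade for trial '", cascade$trial_id,
         "': zero participating units at outer level ", bad, " (",
         lv$unit_label[bad], ")", call. = FALSE)
  }
  proportion <- prod(lv$participated / lv$approached)
  denom <- lv$approached[m] *
    prod(lv$approached[outer] / lv$participated[outer])
  list(proportion = proportion,
       numerator = lv$participated[m],
       effective_denominator = as.integer(round(denom)),
       effective_denominator_exact = denom,
       n_levels = m)
}

#' Binomial confidence interval for a single proportion
#'
#' Clopper-Pearson (exact, via the beta-quantile form of inverting the
#' binomial tails), Wilson score, or Wald. Bounds are clamped to `[0, 1]`.
#'
#' @param x successes, `0 <= x <= n`.
#' @param n trials, `n >= 1`.
#' @param level two-sided confidence level.
#' @param method `"clopper_pearson"` (default), `"wilson"` or `"wald"`.
#' @return Named numeric `c(low, high)`.
#' @examples
#' binomial_ci(48, 255)               # c. 0.142 - 0.242
#' binomial_ci(48, 255, method = "wald")
#' @export
binomial_ci <- function(x, n, level = 0.95,
                        method = c("clopper_pearson", "wilson", "wald")) {
  method <- match.arg(method)
  stopifnot(n >= 1, x >= 0, x <= n)
  alpha <- 1 - level
  p <- x / n
  ci <- switch(method,
    clopper_pearson = c(
      if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1),
      if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)),
    wilson = {
      z <- stats::qnorm(1 - alpha / 2)
      centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
      c(centre - half, centre + half)
    },
    wald = {
      z <- stats::qnorm(1 - alpha / 2)
      p + c(-1, 1) * z * sqrt(p * (1 - p) / n)
    })
  out <- c(low = max(0, ci[1]), high = min(1, ci[2]))
  attr(out, "floored") <- ci[1] < 0
  out
}

# ---- random-intercept binomial GLMM ------------------------------------

# log marginal likelihood of x_j ~ Binomial(n_j, plogis(beta0 + u_j)),
# u_j ~ N(0, sigma^2), by adaptive Gauss-Hermite quadrature: each trial's
# integrand is recentred at its mode and rescaled by the curvature there,
# which keeps the nodes inside the integrand's mass even for large n_j.
.glmm_loglik <- function(beta0, sigma, x, n, gh) {
  if (sigma < 1e-8) {
    return(sum(stats::dbinom(x, n, stats::plogis(beta0), log = TRUE)))
  }
  ll <- 0
  for (j in seq_along(x)) {
    lf <- function(u) {
      stats::dbinom(x[j], n[j], stats::plogis(beta0 + u), log = TRUE) +
        stats::dnorm(u, 0, sigma, log = TRUE)
    }
    opt <- stats::optimize(function(u) {
                             v <- -lf(u)
                             if (is.finite(v)) v else 1e10
                           },
                           interval = c(-10 * sigma - 5, 10 * sigma + 5),
                           tol = 1e-8)
    u_hat <- opt$minimum
    h <- -(lf(u_hat + 1e-4) - 2 * lf(u_hat) + lf(u_hat - 1e-4)) / 1e-8
    if (!is.finite(h) || h <= 0) h <- 1 / sigma^2
    s <- 1 / sqrt(h)
    nodes <- u_hat + sqrt(2) * s * gh$x
    ll <- ll + log(sqrt(2) * s *
                     sum(gh$w * exp(gh$x^2 + vapply(nodes, lf, 0))))
  }
  ll
}

# population-averaged participation probability E[plogis(beta0 + sigma Z)]
.glmm_marginal_mean <- function(beta0, sigma, gh) {
  sum(gh$w / sqrt(pi) * stats::plogis(beta0 + sigma * sqrt(2) * gh$x))
}

#' Pool uptake counts with a random-intercept logistic model
#'
#' Fits the one-observation-per-trial binomial GLMM
#' `logit(p_j) = beta0 + u_j`, `u_j ~ N(0, sigma^2)` by maximising the
#' marginal likelihood with adaptive Gauss-Hermite quadrature (`n_quad`
#' nodes). The optimiser is restarted from three fixed starting values of
#' `sigma` and the best fit kept; `sigma` is estimated on `[0, 10]`, and a
#' solution at 0 is a valid fit flagged `boundary`.
#'
#' The reported uptake is the population-averaged (marginal) mean
#' `E[expit(beta0 + u)]`, computed by the same quadrature; its Wald CI
#' transforms `beta0 +/- z se(beta0)` through that marginalisation, with the
#' lower bound floored at 0. The conditional (median-trial) estimate
#' `expit(beta0)` is also returned, with a delta-method interval on the
#' proportion scale using a t quantile on `k - 1` degrees of freedom —
#' the convention of mixed-model software such as SAS PROC NLMIXED, whose
#' output this mirrors.
#'
#' @param x,n integer vectors of participated / potential counts, one entry
#'   per trial (`length >= 2`).
#' @param level confidence level.
#' @param n_quad number of quadrature nodes (default 21).
#' @return An object of class `uptake_glmm`: `beta0`, `sigma`, `se_beta0`,
#'   `loglik`, `converged`, `boundary`, `n_quadrature`, `k`,
#'   `marginal` (list: `mean`, `ci`), `conditional` (list: `mean`, `ci`,
#'   `ci_floored`), plus the input counts.
#' @examples
#' fit <- uptake_glmm(c(45, 101, 135), c(345, 2036, 1008))
#' fit$marginal$mean
#' @export
uptake_glmm <- function(x, n, level = 0.95, n_quad = 21L) {
  stopifnot(length(x) == length(n), length(x) >= 2L,
            all(x >= 0), all(x <= n), all(n >= 1))
  gh <- pracma::gaussHermite(n_quad)
  # clamp underflowed likelihoods so the bounded optimiser sees a finite,
  # very unfavourable objective rather than -Inf
  nll <- function(par) {
    v <- -.glmm_loglik(par[1], par[2], x, n, gh)
    if (!is.finite(v)) v <- 1e10
    v
  }
  p_pool <- min(max(sum(x) / sum(n), 1e-6), 1 - 1e-6)
  starts <- list(c(stats::qlogis(p_pool), 0.1),
                 c(stats::qlogis(p_pool), 0.5),
                 c(stats::qlogis(p_pool), 1.5))
  fits <- lapply(starts, function(st) {
    tryCatch(stats::optim(st, nll, method = "L-BFGS-B",
                          lower = c(-20, 0), upper = c(20, 10)),
             error = function(e) list(value = Inf, convergence = 999L))
  })
  vals <- vapply(fits, function(f) f$value, 0)
  if (!any(is.finite(vals)) || !any(vapply(fits, function(f)
      identical(f$convergence, 0L), TRUE))) {
    stop("uptake GLMM failed to converge from all starting points; ",
         "optimiser codes: ",
         paste(vapply(fits, function(f) as.character(f$convergence), ""),
               collapse = ", "), call. = FALSE)
  }
  best <- fits[[which.min(vals)]]
  beta0 <- best$par[1]
  sigma <- best$par[2]
  boundary <- sigma < 1e-4

  # curvature-based SE for beta0; at the sigma = 0 boundary the binomial
  # Fisher information sum(n p (1-p)) is exact
  se_beta0 <- if (boundary) {
    p0 <- stats::plogis(beta0)
    1 / sqrt(sum(n * p0 * (1 - p0)))
  } else {
    H <- stats::optimHess(best$par, nll)
    V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 2, 2))
    sqrt(V[1, 1])
  }

  z <- stats::qnorm(1 - (1 - level) / 2)
  marg <- .glmm_marginal_mean(beta0, sigma, gh)
  marg_ci <- c(low = max(0, .glmm_marginal_mean(beta0 - z * se_beta0, sigma, gh)),
               high = min(1, .glmm_marginal_mean(beta0 + z * se_beta0, sigma, gh)))

  k <- length(x)
  p_cond <- stats::plogis(beta0)
  se_cond <- p_cond * (1 - p_cond) * se_beta0
  tq <- stats::qt(1 - (1 - level) / 2, df = max(1L, k - 1L))
  cond_raw <- p_cond + c(-1, 1) * tq * se_cond
  cond_ci <- c(low = max(0, cond_raw[1]), high = min(1, cond_raw[2]))

  structure(list(beta0 = beta0, sigma = sigma, se_beta0 = se_beta0,
                 loglik = -best$value, converged = TRUE,
                 boundary = boundary, n_quadrature = as.integer(n_quad),
                 k = k, x = x, n = n, level = level,
                 marginal = list(mean = marg, ci = marg_ci),
                 conditional = list(mean = p_cond, ci = cond_ci,
                                    ci_floored = cond_raw[1] < 0)),
            class = "uptake_glmm")
}

#' @export
print.uptake_glmm <- function(x, ...) {
  cat(sprintf("Random-intercept uptake model (%d trials, %d-node adaptive GH)\n",
              x$k, x$n_quadrature))
  cat(sprintf("  beta0 = %.4f (SE %.4f), sigma = %.4f%s\n", x$beta0,
              x$se_beta0, x$sigma, if (x$boundary) " [boundary]" else ""))
  cat(sprintf("  marginal uptake = %.3f (%.0f%% CI %.3f-%.3f)\n",
              x$marginal$mean, 100 * x$level,
              x$marginal$ci[["low"]], x$marginal$ci[["high"]]))
  cat(sprintf("  conditional expit(beta0) = %.3f (%.3f-%.3f)%s\n",
              x$conditional$mean, x$conditional$ci[["low"]],
              x$conditional$ci[["high"]],
              if (x$conditional$ci_floored) " [lower CI set >= 0]" else ""))
  invisible(x)
}

#' @export
coef.uptake_glmm <- function(object, ...) {
  c(beta0 = object$beta0, sigma = object$sigma)
}

.uptake_estimate <- function(intervention_id, proportion, numerator,
                             effective_denominator, ci, method, ci_method,
                             ci_floored = FALSE, n_trials = 1L,
                             scaled_denominator = FALSE, fit = NULL) {
  structure(list(intervention_id = intervention_id, proportion = proportion,
                 numerator = as.integer(numerator),
                 effective_denominator = as.integer(effective_denominator),
                 ci = ci, method = method, ci_method = ci_method,
                 ci_floored = ci_floored, n_trials = as.integer(n_trials),
                 scaled_denominator = scaled_denominator, fit = fit),
            class = "uptake_estimate")
}

#' @export
print.uptake_estimate <- function(x, ...) {
  cat(sprintf("Uptake for '%s': %d/%d = %.1f%% (CI %.0f%%-%.0f%%) [%s, %s]\n",
              x$intervention_id, x$numerator, x$effective_denominator,
              100 * x$proportion, 100 * x$ci[["low"]], 100 * x$ci[["high"]],
              x$method, x$ci_method))
  invisible(x)
}

#' Pool uptake across several trials' cascades
#'
#' Reduces each population-based cascade to its effective count pair via
#' [cascade_uptake()] (denominators rounded to integers) and fits
#' [uptake_glmm()]. At least two population-based cascades are required; for
#' a single trial use [cascade_uptake()] with [binomial_ci()] (or
#' [estimate_uptake()], which dispatches automatically).
#'
#' @param cascades list of [recruitment_cascade()] objects for one
#'   intervention; non-population-based cascades are dropped with a warning.
#' @inheritParams uptake_glmm
#' @return An `uptake_estimate` (method `"pooled_glmm"`; `proportion` is the
#'   marginal mean, `numerator`/`effective_denominator` are sums across
#'   trials) with the `uptake_glmm` fit attached as `$fit`.
#' @export
pool_uptake_glmm <- function(cascades, level = 0.95, n_quad = 21L) {
  pb <- vapply(cascades, function(cs) cs$population_based, TRUE)
  if (any(!pb)) {
    warning("dropping ", sum(!pb), " non-population-based cascade(s): ",
            paste(vapply(cascades[!pb], function(cs) cs$trial_id, ""),
                  collapse = ", "), call. = FALSE)
    cascades <- cascades[pb]
  }
  if (length(cascades) < 2L) {
    stop("pooling needs >= 2 population-based cascades; for a single trial ",
         "use cascade_uptake() with binomial_ci()", call. = FALSE)
  }
  red <- lapply(cascades, cascade_uptake)
  x <- vapply(red, function(r) as.numeric(r$numerator), 0)
  n <- vapply(red, function(r) as.numeric(r$effective_denominator), 0)
  fit <- uptake_glmm(x, n, level = level, n_quad = n_quad)
  id <- unique(vapply(cascades, function(cs) cs$intervention_id, ""))
  .uptake_estimate(paste(id, collapse = "+"),
                   proportion = fit$marginal$mean,
                   numerator = sum(x), effective_denominator = sum(n),
                   ci = fit$marginal$ci, method = "pooled_glmm",
                   ci_method = "glmm_wald_marginal",
                   ci_floored = FALSE, n_trials = length(cascades),
                   scaled_denominator = any(vapply(red, function(r)
                     r$n_levels > 1L, TRUE)),
                   fit = fit)
}

#' Estimate uptake per intervention
#'
#' Groups cascades by intervention, drops non-population-based trials, and
#' dispatches: a single trial gets the exact product-of-proportions uptake
#' with a binomial CI on (numerator, rounded effective denominator); two or
#' more trials are pooled with [pool_uptake_glmm()].
#'
#' @param cascades list of [recruitment_cascade()] objects (any mix of
#'   interventions).
#' @param level confidence level.
#' @param ci_method single-trial CI method passed to [binomial_ci()].
#' @param n_quad quadrature nodes for the pooled model.
#' @return Named list of `uptake_estimate` objects.
#' @export
estimate_uptake <- function(cascades, level = 0.95,
                            ci_method = c("clopper_pearson", "wilson", "wald"),
                            n_quad = 21L) {
  ci_method <- match.arg(ci_method)
  ids <- unique(vapply(cascades, function(cs) cs$intervention_id, ""))
  out <- lapply(ids, function(id) {
    cs <- Filter(function(c.) c.$intervention_id == id, cascades)
    pb <- Filter(function(c.) c.$population_based, cs)
    if (length(pb) < length(cs)) {
      message("intervention '", id, "': excluded ",
              length(cs) - length(pb), " non-population-based trial(s)")
    }
    if (length(pb) == 0L) {
      stop("intervention '", id, "' has no population-based cascades",
           call. = FALSE)
    }
    if (length(pb) == 1L) {
      r <- cascade_uptake(pb[[1L]])
      raw <- binomial_ci(r$numerator, r$effective_denominator,
                         level = level, method = ci_method)
      .uptake_estimate(id, r$proportion, r$numerator,
                       r$effective_denominator,
                       c(low = raw[["low"]], high = raw[["high"]]),
                       method = "single_trial", ci_method = ci_method,
                       ci_floored = isTRUE(attr(raw, "floored")),
                       n_trials = 1L,
                       scaled_denominator = r$n_levels > 1L)
    } else {
      est <- pool_uptake_glmm(pb, level = level, n_quad = n_quad)
      est$intervention_id <- id
      est
    }
  })
  names(out) <- ids
  out
}
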