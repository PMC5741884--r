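# Reporting layer: summary table (one row per intervention) and the
# long-format encounter decomposition. Rendering is pure formatting of the
# stored unrounded values, so re-rendering is idempotent.

.fmt_pct <- function(x, digits) {
  sprintf(paste0("%.", digits, "f"), 100 * x)
}

#' Render the intervention summary table
#'
#' One row per intervention: pooled relative risk with CI, relative risk
#' reduction, participating / potential clinician counts, uptake with CI,
#' impact, and rank. Uptake is shown to whole percent and impact to one
#' decimal percent by default (`config` in the model controls both).
#' Footnotes record the CI method used per intervention, where an effective
#' denominator was scaled from a multi-level cascade, and any CI lower bound
#' floored at 0.
#'
#' @param model an `impact_model` from [estimate_impact()].
#' @return A data frame (character columns are formatted for display) with a
#'   `footnotes` character-vector attribute.
#' @export
render_summary_table <- function(model) {
  stopifnot(inherits(model, "impact_model"))
  cfg <- model$config
  ests <- model$estimates
  ids <- vapply(ests, function(e) e$intervention_id, "")
  miss <- c(setdiff(ids, names(model$effects)),
            setdiff(ids, names(model$uptake)))
  if (length(miss) > 0L) {
    stop("intervention_id mismatch in model components: ",
         paste(unique(miss), collapse = ", "), call. = FALSE)
  }
  if (length(ests) == 0L) {
    out <- data.frame(intervention_id = character(0), rr = character(0),
                      rrr_pct = character(0), participating = integer(0),
                      potential = integer(0), uptake_pct = character(0),
                      impact_pct = character(0), rank = integer(0),
                      stringsAsFactors = FALSE)
    attr(out, "footnotes") <- character(0)
    return(out)
  }
  footnotes <- character(0)
  rows <- lapply(ests, function(e) {
    ue <- e$uptake_est
    eff <- e$effect
    data.frame(
      intervention_id = e$intervention_id,
      rr = sprintf("%.2f (%.2f-%.2f)", eff$pooled_rr, eff$ci[["low"]],
                   eff$ci[["high"]]),
      rrr_pct = .fmt_pct(e$rrr, 0),
      participating = ue$numerator,
      potential = ue$effective_denominator,
      uptake_pct = sprintf("%s (%s-%s)",
                           .fmt_pct(ue$proportion, cfg$digits_uptake),
                           .fmt_pct(ue$ci[["low"]], cfg$digits_uptake),
                           .fmt_pct(ue$ci[["high"]], cfg$digits_uptake)),
      impact_pct = .fmt_pct(e$impact, cfg$digits_impact),
      rank = e$rank,
      stringsAsFactors = FALSE)
  })
  for (e in ests) {
    ue <- e$uptake_est
    footnotes <- c(footnotes, sprintf(
      "%s: uptake CI by %s%s", e$intervention_id, ue$ci_method,
      if (ue$method == "pooled_glmm")
        sprintf(" (%d trials pooled, random-intercept model)", ue$n_trials)
      else ""))
    if (isTRUE(ue$scaled_denominator)) {
      footnotes <- c(footnotes, sprintf(
        "%s: potential clinicians scaled from a multi-level cascade",
        e$intervention_id))
    }
    floored <- isTRUE(ue$ci_floored) ||
      (ue$method == "pooled_glmm" && isTRUE(ue$fit$conditional$ci_floored))
    if (floored) {
      footnotes <- c(footnotes,
                     sprintf("%s: lower CI set as >= 0", e$intervention_id))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$rank), , drop = FALSE]
  attr(out, "footnotes") <- footnotes
  out
}

#' Render the encounter decomposition in long format
#'
#' Three rows per intervention (`averted`, `uptake_no_effect`, `no_uptake`)
#' with unrounded fractions summing to 1 within each intervention.
#'
#' @param model an `impact_model`.
#' @return Data frame with columns `intervention_id`, `stratum`, `fraction`.
#' @export
render_decomposition <- function(model) {
  stopifnot(inherits(model, "impact_model"))
  if (length(model$estimates) == 0L) {
    return(data.frame(intervention_id = character(0), stratum = character(0),
                      fraction = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(model$estimates, function(e) {
    data.frame(intervention_id = e$intervention_id,
               stratum = names(e$strata),
               fraction = unname(e$strata),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Write a rendered summary table
#'
#' @param tbl output of [render_summary_table()].
#' @param path output path.
#' @param format `"tsv"` (default) or `"md"` (pipe table); footnotes are
#'   appended as comment/plain lines.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(tbl, path, format = c("tsv", "md")) {
  format <- match.arg(format)
  fn <- attr(tbl, "footnotes")
  if (format == "tsv") {
    utils::write.table(tbl, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    if (length(fn)) cat(paste0("# ", fn), file = path, sep = "\n",
                        append = TRUE)
  } else {
    cols <- names(tbl)
    lines <- c(paste0("| ", paste(cols, collapse = " | "), " |"),
               paste0("|", paste(rep("---", length(cols)), collapse = "|"),
                      "|"),
               vapply(seq_len(nrow(tbl)), function(i) {
                 paste0("| ", paste(vapply(tbl[i, ], as.character, ""),
                                    collapse = " | "), " |")
               }, ""))
    if (length(fn)) lines <- c(lines, "", paste0("- ", fn))
    writeLines(lines, path)
  }
  invisible(path)
}
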