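#' popimpact: population impact from trial effectiveness and uptake
#'
#' Tools to estimate the population impact of a clinical intervention as
#' `impact = RRR x uptake`, where the relative risk reduction (RRR) comes
#' from random-effects meta-analysis of pragmatic trials and uptake is
#' estimated from the trials' clinician recruitment cascades.
#'
#' The main entry point is [estimate_impact()]; the building blocks
#' ([estimate_effectiveness()], [estimate_uptake()], [pool_uptake_glmm()],
#' [population_impact()]) are exported for direct use.
#'
#' @keywords internal
"_PACKAGE"

# ---- validation helpers ------------------------------------------------

.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("schema error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

.check_count <- function(x, name, trial_id, min = 0L) {
  if (any(!is.finite(x)) || any(x != round(x)) || any(x < min)) {
    stop("validation error in trial '", trial_id, "': field '", name,
         "' must be an integer >= ", min, call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a table of two-arm trial outcomes
#'
#' Checks the column schema and per-trial count invariants
#' (`0 <= events <= total`, `total >= 1` in each arm). Called by
#' [read_trials()] and by the synthetic generator; useful directly when
#' trial counts are assembled in code.
#'
#' @param trials data frame with columns `trial_id`, `intervention_id`,
#'   `events_t`, `n_t`, `events_c`, `n_c`.
#' @return The input, invisibly, with class `trial_outcomes` prepended.
#' @export
validate_trials <- function(trials) {
  .check_columns(trials,
                 c("trial_id", "intervention_id",
                   "events_t", "n_t", "events_c", "n_c"),
                 "trial outcome table")
  for (i in seq_len(nrow(trials))) {
    id <- trials$trial_id[i]
    if (is.na(id) || !nzchar(id)) {
      stop("validation error: empty trial_id in row ", i, call. = FALSE)
    }
    .check_count(trials$n_t[i], "n_t", id, min = 1L)
    .check_count(trials$n_c[i], "n_c", id, min = 1L)
    .check_count(trials$events_t[i], "events_t", id)
    .check_count(trials$events_c[i], "events_c", id)
    if (trials$events_t[i] > trials$n_t[i]) {
      stop("validation error in trial '", id,
           "': events_t exceeds n_t", call. = FALSE)
    }
    if (trials$events_c[i] > trials$n_c[i]) {
      stop("validation error in trial '", id,
           "': events_c exceeds n_c", call. = FALSE)
    }
  }
  if (anyDuplicated(trials$trial_id)) {
    stop("validation error: duplicated trial_id '",
         trials$trial_id[anyDuplicated(trials$trial_id)], "'", call. = FALSE)
  }
  class(trials) <- unique(c("trial_outcomes", class(trials)))
  invisible(trials)
}

#' Read two-arm trial outcome counts
#'
#' Reads one row per trial with event/total counts in each arm, the unit of
#' the effectiveness meta-analysis. The CSV schema is
#' `trial_id,intervention_id,events_t,n_t,events_c,n_c`; the JSON form is an
#' array of objects with the same fields.
#'
#' @param path path to a CSV or JSON file.
#' @param format input format, `"csv"` (default) or `"json"`.
#' @return A validated `trial_outcomes` data frame (possibly zero rows).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("trial_id,intervention_id,events_t,n_t,events_c,n_c",
#'              "dp1,delayed,255,817,790,847"), f)
#' read_trials(f)
#' @export
read_trials <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- switch(format,
    csv  = utils::read.csv(path, stringsAsFactors = FALSE),
    json = as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  )
  if (nrow(df) == 0L) {
    .check_columns(df, c("trial_id", "intervention_id",
                         "events_t", "n_t", "events_c", "n_c"),
                   "trial outcome table")
  }
  df$trial_id <- as.character(df$trial_id)
  df$intervention_id <- as.character(df$intervention_id)
  out <- validate_trials(df)
  message("read ", nrow(df), " trial outcome row(s) from ", path)
  out
}

#' Write trial outcomes to CSV or JSON
#'
#' @param trials a `trial_outcomes` data frame (see [read_trials()]).
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, format = c("csv", "json")) {
  format <- match.arg(format)
  cols <- c("trial_id", "intervention_id", "events_t", "n_t", "events_c", "n_c")
  df <- as.data.frame(trials)[, cols]
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# ---- recruitment cascades ----------------------------------------------

#' Construct a recruitment cascade
#'
#' A recruitment cascade records, for one trial, how many units participated
#' out of those approached at each nested recruitment level, ordered from the
#' outermost (e.g. practices) to the innermost (e.g. clinicians within
#' participating practices). Single-level cascades (clinicians approached
#' directly) are common.
#'
#' @param trial_id,intervention_id identifiers (nonempty strings).
#' @param participated,approached integer vectors, outermost level first;
#'   `0 <= participated <= approached`, `approached >= 1`.
#' @param unit_label character vector naming each level (recycled).
#' @param population_based logical; `FALSE` marks trials whose recruitment was
#'   not population-based (e.g. academic volunteers only). Such cascades are
#'   excluded from uptake pooling.
#' @return An object of class `recruitment_cascade`.
#' @examples
#' # 22/61 practices participated; 48/92 clinicians within them
#' recruitment_cascade("dp1", "delayed", c(22, 48), c(61, 92),
#'                     c("practice", "clinician"))
#' @export
recruitment_cascade <- function(trial_id, intervention_id,
                                participated, approached,
                                unit_label = "clinician",
                                population_based = TRUE) {
  stopifnot(length(participated) == length(approached),
            length(participated) >= 1L)
  if (!nzchar(trial_id)) stop("trial_id must be nonempty", call. = FALSE)
  unit_label <- rep_len(as.character(unit_label), length(participated))
  for (i in seq_along(participated)) {
    .check_count(approached[i], "approached", trial_id, min = 1L)
    .check_count(participated[i], "participated", trial_id)
    if (participated[i] > approached[i]) {
      stop("validation error in trial '", trial_id, "': participated > ",
           "approached at level ", i, " (", unit_label[i], ")", call. = FALSE)
    }
  }
  structure(
    list(trial_id = as.character(trial_id),
         intervention_id = as.character(intervention_id),
         levels = data.frame(level_order = seq_along(participated),
                             unit_label = unit_label,
                             participated = as.integer(participated),
                             approached = as.integer(approached),
                             stringsAsFactors = FALSE),
         population_based = isTRUE(population_based)),
    class = "recruitment_cascade")
}

#' @export
print.recruitment_cascade <- function(x, ...) {
  cat("Recruitment cascade for trial '", x$trial_id, "' (",
      x$intervention_id, ")\n", sep = "")
  for (i in seq_len(nrow(x$levels))) {
    cat(sprintf("  level %d: %d/%d %s\n", x$levels$level_order[i],
                x$levels$participated[i], x$levels$approached[i],
                x$levels$unit_label[i]))
  }
  if (!x$population_based) cat("  (not population-based: excluded from pooling)\n")
  invisible(x)
}

#' Read recruitment cascades
#'
#' Reads a long-format CSV with one row per recruitment level, schema
#' `trial_id,intervention_id,level_order,unit_label,participated,approached`
#' plus an optional `population_based` column (assumed `TRUE` with a warning
#' when absent). Rows are grouped by trial and sorted by `level_order`
#' (outermost level = 1).
#'
#' @param path path to the CSV file.
#' @return A list of [recruitment_cascade()] objects, in file order of first
#'   appearance of each trial.
#' @export
read_recruitment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("trial_id", "intervention_id", "level_order",
                       "unit_label", "participated", "approached"),
                 "recruitment table")
  if (!"population_based" %in% names(df)) {
    warning("column 'population_based' absent: assuming TRUE for all trials",
            call. = FALSE)
    df$population_based <- TRUE
  }
  key <- paste(df$trial_id, df$level_order, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- df$trial_id[anyDuplicated(key)]
    stop("duplicate (trial_id, level_order) for trial '", bad, "'",
         call. = FALSE)
  }
  ids <- unique(df$trial_id)
  cascades <- lapply(ids, function(id) {
    rows <- df[df$trial_id == id, , drop = FALSE]
    rows <- rows[order(rows$level_order), , drop = FALSE]
    if (length(unique(rows$intervention_id)) != 1L) {
      stop("trial '", id, "' maps to multiple intervention_id values",
           call. = FALSE)
    }
    recruitment_cascade(id, rows$intervention_id[1L],
                        rows$participated, rows$approached,
                        rows$unit_label,
                        isTRUE(as.logical(rows$population_based[1L])))
  })
  message("read ", nrow(df), " recruitment row(s) (", length(cascades),
          " cascade(s)) from ", path)
  cascades
}

#' Write recruitment cascades to CSV
#'
#' Inverse of [read_recruitment()]: one row per level, `level_order`
#' explicit.
#'
#' @param cascades list of `recruitment_cascade` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recruitment <- function(cascades, path) {
  rows <- do.call(rbind, lapply(cascades, function(cs) {
    cbind(data.frame(trial_id = cs$trial_id,
                     intervention_id = cs$intervention_id,
                     stringsAsFactors = FALSE),
          cs$levels,
          population_based = cs$population_based)
  }))
  rows <- rows[, c("trial_id", "intervention_id", "level_order", "unit_label",
                   "participated", "approached", "population_based")]
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- run configuration --------------------------------------------------

#' Run configuration
#'
#' Bundles the reporting and uncertainty-propagation settings shared across a
#' run: the single-proportion CI method, the confidence level, the Monte
#' Carlo draw count and seed, and the reporting precision (uptake to whole
#' percent, impact to one decimal percent by default, matching the summary
#' table conventions).
#'
#' @param ci_method single-trial uptake CI method: `"clopper_pearson"`
#'   (exact, default), `"wilson"` or `"wald"`.
#' @param ci_level two-sided confidence level, in (0, 1).
#' @param mc_draws Monte Carlo draws for the impact CI (>= 1000).
#' @param seed integer seed for the Monte Carlo step.
#' @param digits_uptake,digits_impact decimal places (on the percent scale)
#'   used by the reporting layer.
#' @return An object of class `run_config`.
#' @export
run_config <- function(ci_method = c("clopper_pearson", "wilson", "wald"),
                       ci_level = 0.95, mc_draws = 100000L, seed = 1L,
                       digits_uptake = 0L, digits_impact = 1L) {
  ci_method <- match.arg(ci_method)
  if (!(ci_level > 0 && ci_level < 1)) {
    stop("ci_level must be in (0, 1)", call. = FALSE)
  }
  if (mc_draws < 1000) stop("mc_draws must be >= 1000", call. = FALSE)
  structure(list(ci_method = ci_method, ci_level = ci_level,
                 mc_draws = as.integer(mc_draws), seed = as.integer(seed),
                 digits_uptake = as.integer(digits_uptake),
                 digits_impact = as.integer(digits_impact)),
            class = "run_config")
}

#' @rdname run_config
#' @param path path to a JSON file holding the fields of [run_config()].
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  do.call(run_config, x[intersect(names(x), names(formals(run_config)))])
}

#' @rdname run_config
#' @param config a `run_config` object.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
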