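#' Validate campaign input files
#'
#' Schema and sanity checks on the four-file CSV layout: required columns,
#' PM concentrations within 0-1000 ug/m3, heart rate within 30-220 bpm,
#' strictly increasing timestamps per volunteer, and mass-fraction
#' consistency (PM10 >= PM2.5; violations are warnings, the rows are
#' retained with a flag).
#'
#' @param dir directory holding `heart_rate.csv`, `pm.csv`, `labels.csv`,
#'   `profiles.csv`.
#' @return data frame of issues: `file`, `severity` ("error"/"warning"),
#'   `message`; zero rows means a clean pass.
#' @export
validate_inputs <- function(dir) {
  issues <- list()
  note <- function(file, severity, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      file = file, severity = severity, message = message,
      stringsAsFactors = FALSE)

  specs <- list(
    heart_rate = c("volunteer_id", "timestamp_s", "hr_bpm"),
    pm = c("volunteer_id", "timestamp_s", "pm25_ugm3", "pm10_ugm3"),
    labels = c("volunteer_id", "interval_index", "state"),
    profiles = c("volunteer_id", "gender", "age_group", "height_m",
                 "weight_kg", "baseline_hr"))
  tabs <- list()
  for (nm in names(specs)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      note(nm, "error", "file missing")
      next
    }
    tab <- utils::read.csv(path)
    missing <- setdiff(specs[[nm]], names(tab))
    if (length(missing)) {
      note(nm, "error",
           paste("missing required column(s):",
                 paste(missing, collapse = ", ")))
      next
    }
    tabs[[nm]] <- tab
  }
  check_monotone <- function(tab, nm) {
    bad <- vapply(split(tab$timestamp_s, tab$volunteer_id),
                  function(ts) any(diff(ts) <= 0), logical(1))
    if (any(bad))
      note(nm, "error",
           paste("non-increasing timestamps for:",
                 paste(names(bad)[bad], collapse = ", ")))
  }
  if (!is.null(tabs$heart_rate)) {
    hr <- tabs$heart_rate
    out <- which(hr$hr_bpm < 30 | hr$hr_bpm > 220 | is.na(hr$hr_bpm))
    if (length(out))
      note("heart_rate", "error",
           paste("heart rate outside 30-220 bpm at row(s):",
                 paste(utils::head(out, 5), collapse = ", ")))
    check_monotone(hr, "heart_rate")
  }
  if (!is.null(tabs$pm)) {
    pm <- tabs$pm
    out <- which(pm$pm25_ugm3 < 0 | pm$pm25_ugm3 > 1000 |
                   pm$pm10_ugm3 < 0 | pm$pm10_ugm3 > 1000)
    if (length(out))
      note("pm", "error",
           paste("PM outside 0-1000 ug/m3 at row(s):",
                 paste(utils::head(out, 5), collapse = ", ")))
    inv <- which(pm$pm10_ugm3 < pm$pm25_ugm3)
    if (length(inv))
      note("pm", "warning",
           paste("PM10 < PM2.5 (rows retained, flagged) at row(s):",
                 paste(utils::head(inv, 5), collapse = ", ")))
    check_monotone(pm, "pm")
  }
  if (!is.null(tabs$labels)) {
    if (!all(tabs$labels$state %in% c(0, 1)))
      note("labels", "error", "state must be 0 (safe) or 1 (risk)")
  }
  if (!is.null(tabs$profiles)) {
    p <- tabs$profiles
    if (!all(p$gender %in% c("male", "female")))
      note("profiles", "error", "gender must be male/female")
    if (!all(p$age_group %in% c("youth", "middle_aged")))
      note("profiles", "error", "age_group must be youth/middle_aged")
    if (any(p$baseline_hr <= 0 | p$height_m <= 0 | p$weight_kg <= 0))
      note("profiles", "error",
           "baseline_hr, height_m and weight_kg must be positive")
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(file = character(), severity = character(),
                  message = character(), stringsAsFactors = FALSE)
}

#' End-to-end pipeline run
#'
#' Orchestrates the full analysis: simulate a cohort (or ingest CSV data),
#' aggregate the series into intervals, derive per-volunteer HR% and PM2.5
#' thresholds, classify interval states, fit the five-covariate binary
#' logit, and evaluate group risk curves.  Identical configuration and
#' seed give identical outputs.
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"ingest"`
#'   (read the four-file CSV layout from `input_dir`).
#' @param config a [sim_config()] (simulate mode; ignored when ingesting).
#' @param input_dir directory of input CSVs (ingest mode).
#' @param output_dir if non-`NULL`, all stage outputs are written there as
#'   CSV/JSON.
#' @param interval_s aggregation interval, seconds.
#' @param roc_step ROC threshold grid spacing (HR% fraction).
#' @param auc_gate AUC reliability cutoff.
#' @param exclude_unreliable drop unreliable volunteers before the logit.
#' @param hr_for_curves HR% (percentage points) substituted into the risk
#'   curves.
#' @param seed overrides `config$seed` when given (simulate mode).
#' @return list of class `walkrisk_run`: `profiles`, `intervals`,
#'   `thresholds`, `threshold_summary`, `fit`, `coefficients` (Wald/odds
#'   table), `curves`, `report`.
#' @examples
#' \donttest{
#' cfg <- sim_config(group_sizes = c(male_youth = 8, female_youth = 8,
#'                                   male_middle_aged = 8,
#'                                   female_middle_aged = 8),
#'                   seed = 7, walk_duration = 1800)
#' run <- run_pipeline(config = cfg)
#' run$report$fit
#' }
#' @export
run_pipeline <- function(mode = c("simulate", "ingest"), config = NULL,
                         input_dir = NULL, output_dir = NULL,
                         interval_s = 60, roc_step = 0.005,
                         auc_gate = 0.9, exclude_unreliable = FALSE,
                         hr_for_curves = 35, seed = NULL) {
  mode <- match.arg(mode)
  stage <- "configuration"
  result <- tryCatch({
    if (mode == "simulate") {
      config <- config %||% sim_config()
      if (!is.null(seed)) config$seed <- as.integer(seed)
      validate_sim_config(config)
      stage <- "simulation"
      profiles <- generate_cohort(config)
      recordings <- simulate_cohort_walks(profiles, config)
    } else {
      if (is.null(input_dir)) stop("ingest mode needs `input_dir`")
      stage <- "validation"
      issues <- validate_inputs(input_dir)
      if (any(issues$severity == "error"))
        stop("input validation failed: ",
             paste(issues$message[issues$severity == "error"],
                   collapse = "; "))
      stage <- "ingest"
      inp <- read_recordings(input_dir, label_interval = interval_s)
      profiles <- inp$profiles
      recordings <- inp$recordings
    }
    stage <- "aggregation"
    intervals <- aggregate_cohort(recordings, profiles, interval_s)
    stage <- "thresholds"
    thresholds <- cohort_thresholds(intervals, step = roc_step,
                                    auc_gate = auc_gate)
    tsum <- threshold_summary(thresholds, profiles)
    stage <- "classification"
    classified <- classify_states(intervals, thresholds,
                                  exclude_unreliable = exclude_unreliable)
    stage <- "logit"
    design <- design_matrix(classified, profiles)
    fit <- fit_logit(design)
    coefs <- wald_and_or(fit)
    stage <- "curves"
    curves <- risk_curves(fit, hr_pct = hr_for_curves)

    report <- list(
      mode = mode,
      seed = if (mode == "simulate") config$seed else NA_integer_,
      interval_s = interval_s, roc_step = roc_step, auc_gate = auc_gate,
      exclude_unreliable = exclude_unreliable,
      hr_for_curves = hr_for_curves,
      counts = list(volunteers = nrow(profiles),
                    intervals = nrow(intervals),
                    classified = nrow(classified),
                    risk_intervals = sum(classified$y)),
      reliability = tsum[c("n", "n_reliable", "frac_reliable")],
      fit = list(loglik = fit$loglik, iterations = fit$iterations,
                 converged = fit$converged, n = fit$n,
                 class_balance = mean(fit$y)))
    out <- structure(list(profiles = profiles, intervals = intervals,
                          thresholds = thresholds,
                          threshold_summary = tsum, fit = fit,
                          coefficients = coefs, curves = curves,
                          report = report),
                     class = "walkrisk_run")
    if (!is.null(output_dir)) {
      dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
      written <- c(
        intervals = file.path(output_dir, "intervals.csv"),
        thresholds = file.path(output_dir, "thresholds.csv"),
        coefficients = file.path(output_dir, "coefficients.csv"),
        curves = file.path(output_dir, "risk_curves.csv"),
        report = file.path(output_dir, "report.json"))
      utils::write.csv(intervals, written[["intervals"]],
                       row.names = FALSE)
      utils::write.csv(as.data.frame(thresholds), written[["thresholds"]],
                       row.names = FALSE)
      utils::write.csv(coefs, written[["coefficients"]],
                       row.names = FALSE)
      utils::write.csv(curves, written[["curves"]], row.names = FALSE)
      jsonlite::write_json(report, written[["report"]], auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      out$report$artifacts <- as.list(written)
    }
    out
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage `%s`: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

#' @export
print.walkrisk_run <- function(x, ...) {
  r <- x$report
  cat("walkrisk pipeline run (", r$mode, " mode)\n", sep = "")
  cat(sprintf("  volunteers: %d, intervals: %d (%d classified, %d risk)\n",
              r$counts$volunteers, r$counts$intervals, r$counts$classified,
              r$counts$risk_intervals))
  cat(sprintf("  reliable thresholds (AUC > %.2f): %d / %d (%.1f%%)\n",
              r$auc_gate, r$reliability$n_reliable, r$reliability$n,
              100 * r$reliability$frac_reliable))
  cat(sprintf("  logit: loglik %.2f in %d iterations, converged: %s\n",
              r$fit$loglik, r$fit$iterations, r$fit$converged))
  invisible(x)
}
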