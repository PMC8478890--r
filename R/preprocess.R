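#' Heart-rate change rate (HR%)
#'
#' The relative deviation of an interval's mean heart rate from the
#' volunteer's resting baseline, \eqn{r_i = (t_i - t) / t}, where \eqn{t}
#' is the mean heart rate measured over 10 minutes at rest and \eqn{t_i}
#' the mean heart rate in interval \eqn{i}.  Returned as a dimensionless
#' fraction (0.30 for a 30\% elevation); it may be negative.
#'
#' @param mean_hr interval mean heart rate, bpm.
#' @param baseline_hr resting baseline heart rate, bpm (> 0).
#' @return numeric fraction, same length as `mean_hr`.
#' @examples
#' compute_hr_percent(91, 70)   # 0.30
#' @export
compute_hr_percent <- function(mean_hr, baseline_hr) {
  if (any(baseline_hr <= 0)) stop("baseline_hr must be positive",
                                  call. = FALSE)
  (mean_hr - baseline_hr) / baseline_hr
}

#' Body Mass Index and the healthy band
#'
#' BMI = weight / height^2 (kg/m2); the healthy band is 18.5 to 24
#' inclusive at both ends.
#'
#' @param weight_kg weight in kilograms (> 0).
#' @param height_m height in metres (> 0).
#' @return data frame with columns `bmi` and logical `healthy`.
#' @examples
#' compute_bmi(70, 1.75)
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0) || any(height_m <= 0))
    stop("weight and height must be positive", call. = FALSE)
  bmi <- weight_kg / height_m^2
  data.frame(bmi = bmi, healthy = bmi >= 18.5 & bmi <= 24)
}

#' Aggregate a walk recording into fixed intervals
#'
#' Tiles the recording with half-open windows
#' \eqn{[k \cdot s, (k+1) \cdot s)} of `interval_s` seconds, averaging the
#' 1 Hz heart-rate samples and the PM samples whose timestamps fall in each
#' window.  A trailing partial window shorter than half an interval is
#' dropped; longer partials are kept.  Windows without any PM sample are
#' excluded with a warning.  Subjective labels are joined by interval index
#' when the aggregation interval matches the recording's label interval;
#' otherwise `state` is `NA` (unlabeled).
#'
#' @param recording a `walk_recording`.
#' @param profile the volunteer's profile row (for `baseline_hr`).
#' @param interval_s window length, seconds (> 0).
#' @return data frame of interval records: `volunteer_id`,
#'   `interval_index`, `mean_hr`, `hr_percent` (fraction), `mean_pm25`,
#'   `mean_pm10`, `state` (0 safe / 1 risk / NA unlabeled).
#' @export
aggregate_intervals <- function(recording, profile, interval_s = 60) {
  if (interval_s <= 0) stop("interval_s must be positive", call. = FALSE)
  hr <- recording$hr; pm <- recording$pm
  if (!nrow(hr) || !nrow(pm)) stop("empty series in recording",
                                   call. = FALSE)
  profile <- as.list(profile)
  duration <- max(hr$timestamp_s) + 1
  n_full <- floor(duration / interval_s)
  tail_len <- duration - n_full * interval_s
  n_win <- n_full + (tail_len >= interval_s / 2)
  if (n_win < 1) stop("recording shorter than half an interval",
                      call. = FALSE)

  widx_hr <- floor(hr$timestamp_s / interval_s)
  widx_pm <- floor(pm$timestamp_s / interval_s)
  keep <- seq_len(n_win) - 1L
  mean_hr <- tapply(hr$hr_bpm[widx_hr %in% keep],
                    widx_hr[widx_hr %in% keep], mean)
  sel_pm <- widx_pm %in% keep
  mean_pm25 <- tapply(pm$pm25_ugm3[sel_pm], widx_pm[sel_pm], mean)
  mean_pm10 <- tapply(pm$pm10_ugm3[sel_pm], widx_pm[sel_pm], mean)

  out <- data.frame(interval_index = as.integer(names(mean_hr)),
                    mean_hr = as.numeric(mean_hr))
  out$mean_pm25 <- as.numeric(mean_pm25[match(out$interval_index,
                                              as.integer(names(mean_pm25)))])
  out$mean_pm10 <- as.numeric(mean_pm10[match(out$interval_index,
                                              as.integer(names(mean_pm10)))])
  no_pm <- is.na(out$mean_pm25)
  if (any(no_pm)) {
    warning(sum(no_pm), " interval(s) without a PM sample excluded",
            call. = FALSE)
    out <- out[!no_pm, , drop = FALSE]
  }
  out$hr_percent <- compute_hr_percent(out$mean_hr, profile$baseline_hr)

  out$state <- NA_integer_
  if (!is.null(recording$labels) && nrow(recording$labels) &&
      isTRUE(all.equal(recording$label_interval %||% interval_s,
                       interval_s))) {
    m <- match(out$interval_index, recording$labels$interval_index)
    out$state <- recording$labels$state[m]
  }
  data.frame(volunteer_id = recording$volunteer_id,
             out[, c("interval_index", "mean_hr", "hr_percent",
                     "mean_pm25", "mean_pm10", "state")],
             stringsAsFactors = FALSE)
}

#' Aggregate a whole cohort of recordings
#'
#' @param recordings list of `walk_recording` objects.
#' @param profiles cohort/profile data frame.
#' @param interval_s window length, seconds.
#' @return one stacked data frame of interval records.
#' @export
aggregate_cohort <- function(recordings, profiles, interval_s = 60) {
  rows <- lapply(recordings, function(r) {
    p <- profiles[profiles$volunteer_id == r$volunteer_id, , drop = FALSE]
    if (!nrow(p)) stop("no profile for volunteer ", r$volunteer_id,
                       call. = FALSE)
    aggregate_intervals(r, p[1, ], interval_s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Interval-length selection diagnostic
#'
#' For each candidate aggregation interval, pools the interval records of
#' all recordings and regresses interval-mean heart rate on interval-mean
#' PM2.5 (simple linear regression across volunteers); the regression F
#' statistic and its p-value (sig. F) quantify how clearly the
#' concentration-heart-rate relation shows through at that resolution.
#' Short intervals inflate random fluctuation, long ones blur the trend;
#' the table lets the analyst pick the working interval (60 s is the
#' package default throughout).
#'
#' @param recordings list of `walk_recording` objects.
#' @param profiles profile data frame.
#' @param candidate_intervals seconds; default `c(30, 60, 120, 180, 240,
#'   300)`.
#' @return data frame `interval_s`, `f_value`, `sig_f`, ordered by
#'   interval.  Candidates with a degenerate regression (constant PM2.5)
#'   are omitted with a warning.
#' @export
interval_diagnostics <- function(recordings, profiles,
                                 candidate_intervals = c(30, 60, 120, 180,
                                                         240, 300)) {
  if (length(recordings) < 2)
    stop("need at least two recordings", call. = FALSE)
  rows <- lapply(candidate_intervals, function(s) {
    # windows without a PM sample are expected at intervals shorter than
    # the PM sampling spacing; their exclusion warnings are routine here
    rec <- suppressWarnings(aggregate_cohort(recordings, profiles, s))
    if (length(unique(rec$mean_pm25)) < 2 || nrow(rec) < 3) {
      warning("degenerate regression at interval ", s, " s; omitted",
              call. = FALSE)
      return(NULL)
    }
    fit <- stats::lm(mean_hr ~ mean_pm25, data = rec)
    fs <- summary(fit)$fstatistic
    data.frame(interval_s = s, f_value = unname(fs[1]),
               sig_f = unname(stats::pf(fs[1], fs[2], fs[3],
                                        lower.tail = FALSE)))
  })
  out <- do.call(rbind, rows)
  out[order(out$interval_s), , drop = FALSE]
}

#' Absolute Pearson correlation screen of the explanatory variables
#'
#' Computes the matrix of absolute Pearson correlation coefficients over
#' the five logit covariates -- HR\%, PM2.5, gender (male = 1), age
#' (youth = 1) and BMI band (healthy = 1) -- to check for collinearity
#' before modelling.  Coefficients are reported as |r| and banded in 0.2
#' steps from very weak to very strong (see [correlation_strength()]).
#'
#' @param records interval records (from [aggregate_cohort()]).
#' @param profiles profile data frame with `gender`, `age_group`,
#'   `height_m`, `weight_kg`.
#' @return 5x5 symmetric matrix of |r| with unit diagonal; columns with
#'   zero variance get `NA` correlations and a warning.
#' @export
pearson_matrix <- function(records, profiles) {
  if (nrow(records) < 3) stop("need at least three records", call. = FALSE)
  d <- design_matrix(records, profiles)
  X <- cbind(`HR%` = d$hr_pct, PM2.5 = d$pm25, gender = d$male,
             age = d$youth, BMI = d$bmi_healthy)
  degen <- apply(X, 2, function(col) stats::var(col) == 0)
  if (any(degen))
    warning("zero-variance column(s): ",
            paste(colnames(X)[degen], collapse = ", "),
            "; correlations undefined", call. = FALSE)
  r <- suppressWarnings(abs(stats::cor(X)))
  diag(r) <- 1
  r
}

#' Verbal strength band of a correlation coefficient
#'
#' Bands |r| in 0.2 steps: very weak, weak, moderate, strong, very strong.
#'
#' @param r correlation coefficient(s); the absolute value is banded.
#' @return character vector of band labels.
#' @export
correlation_strength <- function(r) {
  cut(abs(r), breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1),
      labels = c("very weak", "weak", "moderate", "strong", "very strong"),
      include.lowest = TRUE)
}
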