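#' Confusion counts at an HR% threshold
#'
#' An interval is judged "risk" exactly when its HR% is at or above the
#' threshold (higher heart-rate elevation is riskier).  The judgement is
#' cross-tabulated against the subjective label: Z_TP risk intervals judged
#' risk, Z_FN risk intervals judged safe, Z_FP safe intervals judged risk,
#' Z_TN safe intervals judged safe.  The four counts always sum to the
#' number of labeled intervals.
#'
#' @param hr_percent numeric HR% scores (fractions).
#' @param state 0/1 labels (0 safe, 1 risk).
#' @param threshold HR% cutpoint.
#' @return named integer vector `c(tp, fn, fp, tn)`.
#' @examples
#' confusion_counts(c(0.40, 0.35, 0.20, 0.10), c(1, 1, 0, 0), 0.30)
#' @export
confusion_counts <- function(hr_percent, state, threshold) {
  keep <- !is.na(state)
  hr_percent <- hr_percent[keep]; state <- state[keep]
  if (!length(state)) stop("no labeled records", call. = FALSE)
  if (!all(state %in% c(0, 1))) stop("labels must be 0 or 1", call. = FALSE)
  judged <- hr_percent >= threshold
  c(tp = sum(judged & state == 1), fn = sum(!judged & state == 1),
    fp = sum(judged & state == 0), tn = sum(!judged & state == 0))
}

#' Per-volunteer ROC curve over an HR% threshold grid
#'
#' Sweeps candidate HR% thresholds on a regular grid of spacing `step`
#' (default 0.005, the standard discriminant interval for HR%) spanning the
#' observed HR% range padded by one step, so both degenerate extremes
#' (everything judged risk / everything judged safe) appear on the curve.
#' At each threshold the sensitivity \eqn{T = Z_{TP}/(Z_{TP}+Z_{FN})},
#' the false-positive rate \eqn{F = Z_{FP}/(Z_{FP}+Z_{TN})} and the Youden
#' index \eqn{T - F} are computed; the AUC is the trapezoidal area under
#' the (F, T) points sorted by F with the anchors (0,0) and (1,1)
#' appended.  An AUC above `auc_gate` (default 0.9) marks the curve as
#' reliable.
#'
#' @param records data frame with `hr_percent` and `state` columns (rows
#'   with `NA` state are ignored).
#' @param step threshold grid spacing in HR% fraction units.
#' @param auc_gate reliability cutoff on the AUC.
#' @param volunteer_id optional identifier stored on the curve.
#' @return object of class `walkrisk_roc`: list with `points` (data frame
#'   `threshold`, `tpr`, `fpr`, `youden`, `tp`, `fn`, `fp`, `tn`), `auc`
#'   (`NA` for single-class labels), `reliable`, `volunteer_id`, `n`.
#' @export
roc_curve <- function(records, step = 0.005, auc_gate = 0.9,
                      volunteer_id = records$volunteer_id[1]) {
  if (step <= 0) stop("step must be positive", call. = FALSE)
  keep <- !is.na(records$state)
  hr <- records$hr_percent[keep]
  st <- records$state[keep]
  if (!length(st)) stop("no labeled records", call. = FALSE)
  grid <- seq(min(hr) - step, max(hr) + step + step * 1e-9, by = step)
  counts <- t(vapply(grid, function(th) confusion_counts(hr, st, th),
                     c(tp = 0, fn = 0, fp = 0, tn = 0)))
  n_pos <- sum(st == 1); n_neg <- sum(st == 0)
  tpr <- if (n_pos > 0) counts[, "tp"] / n_pos else rep(NA_real_, nrow(counts))
  fpr <- if (n_neg > 0) counts[, "fp"] / n_neg else rep(NA_real_, nrow(counts))
  points <- data.frame(threshold = grid, tpr = tpr, fpr = fpr,
                       youden = tpr - fpr, counts)
  single_class <- n_pos == 0 || n_neg == 0
  auc <- if (single_class) NA_real_ else trapezoid_auc(fpr, tpr)
  structure(list(volunteer_id = volunteer_id %||% NA_character_,
                 points = points, auc = auc,
                 reliable = isTRUE(auc > auc_gate),
                 single_class = single_class,
                 n = length(st)),
            class = "walkrisk_roc")
}

# Trapezoidal area under the (fpr, tpr) points, sorted by fpr (ties by
# tpr), with (0,0) and (1,1) anchors appended.
trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  x <- c(0, fpr[o], 1); y <- c(0, tpr[o], 1)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' @export
print.walkrisk_roc <- function(x, ...) {
  cat("ROC curve", if (!is.na(x$volunteer_id)) paste("for", x$volunteer_id),
      sprintf("(%d labeled intervals, %d thresholds)\n", x$n,
              nrow(x$points)))
  cat(sprintf("  AUC = %s; reliable (> gate): %s\n",
              if (is.na(x$auc)) "undefined (single-class labels)"
              else formatC(x$auc, digits = 4, format = "f"),
              x$reliable))
  invisible(x)
}

#' Youden-optimal HR% threshold of an ROC curve
#'
#' Selects the grid threshold maximizing the Youden index
#' (sensitivity + specificity - 1); ties are broken toward the upper-left
#' corner of the ROC plane, i.e. by smaller false-positive rate and then by
#' smaller threshold.
#'
#' @param curve a [roc_curve()] object.
#' @return list `hr_threshold`, `youden_max`, `auc`, `reliable`,
#'   `volunteer_id`.
#' @export
optimal_threshold <- function(curve) {
  p <- curve$points
  ok <- !is.na(p$youden)
  if (!any(ok)) stop("Youden index undefined at every threshold",
                     call. = FALSE)
  p <- p[ok, , drop = FALSE]
  p <- p[order(-p$youden, p$fpr, p$threshold), , drop = FALSE]
  list(volunteer_id = curve$volunteer_id, hr_threshold = p$threshold[1],
       youden_max = p$youden[1], auc = curve$auc,
       reliable = curve$reliable)
}

#' Map an HR% threshold to a PM2.5 concentration
#'
#' The HR% value at the optimal cutpoint generally corresponds to several
#' observed PM2.5 concentrations (the series fluctuates); the mapped
#' threshold is the arithmetic mean of `mean_pm25` over the interval
#' records whose HR% lies within `tolerance` of the cutpoint.  If no record
#' falls inside the tolerance it is doubled (with a message) until at least
#' one does.
#'
#' @param records interval records with `hr_percent` and `mean_pm25`.
#' @param hr_threshold HR% cutpoint (fraction).
#' @param tolerance initial half-width of the HR% matching band; defaults
#'   to half the ROC grid step.
#' @return PM2.5 threshold in ug/m3.
#' @export
map_hr_to_pm25 <- function(records, hr_threshold, tolerance = 0.005 / 2) {
  if (!nrow(records)) stop("no records", call. = FALSE)
  if (tolerance <= 0) stop("tolerance must be positive", call. = FALSE)
  repeat {
    sel <- abs(records$hr_percent - hr_threshold) <= tolerance
    if (any(sel)) return(mean(records$mean_pm25[sel]))
    tolerance <- tolerance * 2
    message("no record within tolerance; widened to ", tolerance)
  }
}

#' Per-volunteer thresholds for a whole cohort
#'
#' Runs the full threshold procedure independently for every volunteer:
#' ROC curve on the labeled intervals, Youden-optimal HR% cutpoint,
#' reliability gate on the AUC, and mapping of the cutpoint to a PM2.5
#' concentration.  Volunteers whose labels contain a single class have no
#' defined curve and are excluded (and listed in the `excluded` attribute).
#'
#' @param records stacked interval records for all volunteers.
#' @param step ROC grid spacing (HR% fraction).
#' @param auc_gate reliability cutoff on the AUC.
#' @return data frame of class `walkrisk_thresholds` with one row per
#'   volunteer: `volunteer_id`, `hr_threshold`, `pm25_threshold`,
#'   `youden_max`, `auc`, `reliable`; attribute `excluded` lists volunteers
#'   without a defined curve.
#' @export
cohort_thresholds <- function(records, step = 0.005, auc_gate = 0.9) {
  ids <- unique(records$volunteer_id)
  if (!length(ids)) stop("no volunteers in records", call. = FALSE)
  excluded <- character()
  rows <- lapply(ids, function(id) {
    rec <- records[records$volunteer_id == id & !is.na(records$state), ,
                   drop = FALSE]
    if (!nrow(rec) || length(unique(rec$state)) < 2) {
      excluded <<- c(excluded, id)
      return(NULL)
    }
    cur <- roc_curve(rec, step = step, auc_gate = auc_gate,
                     volunteer_id = id)
    opt <- optimal_threshold(cur)
    pm <- map_hr_to_pm25(rec, opt$hr_threshold, tolerance = step / 2)
    data.frame(volunteer_id = id, hr_threshold = opt$hr_threshold,
               pm25_threshold = pm, youden_max = opt$youden_max,
               auc = cur$auc, reliable = cur$reliable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no volunteer has both label classes; thresholds undefined",
         call. = FALSE)
  rownames(out) <- NULL
  if (length(excluded))
    warning("excluded volunteer(s) with single-class labels: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  attr(out, "excluded") <- excluded
  class(out) <- c("walkrisk_thresholds", "data.frame")
  out
}

#' Cohort reliability and group-threshold summary
#'
#' Counts reliable volunteers (AUC above the gate) and reports mean PM2.5
#' thresholds by gender, age group and BMI band margins.
#'
#' @param thresholds a [cohort_thresholds()] result.
#' @param profiles profile data frame (`gender`, `age_group`, `height_m`,
#'   `weight_kg`).
#' @return list: `n`, `n_reliable`, `frac_reliable`, `excluded`, and
#'   `group_means`, a data frame of margin-level mean PM2.5 thresholds.
#' @export
threshold_summary <- function(thresholds, profiles) {
  m <- match(thresholds$volunteer_id, profiles$volunteer_id)
  if (anyNA(m)) stop("thresholds contain volunteers absent from profiles",
                     call. = FALSE)
  prof <- profiles[m, , drop = FALSE]
  healthy <- compute_bmi(prof$weight_kg, prof$height_m)$healthy
  margin <- function(name, level, sel) {
    if (!any(sel)) return(NULL)
    data.frame(margin = name, level = level, n = sum(sel),
               mean_pm25_threshold = mean(thresholds$pm25_threshold[sel]),
               mean_hr_threshold = mean(thresholds$hr_threshold[sel]),
               stringsAsFactors = FALSE)
  }
  gm <- rbind(margin("gender", "male", prof$gender == "male"),
              margin("gender", "female", prof$gender == "female"),
              margin("age_group", "youth", prof$age_group == "youth"),
              margin("age_group", "middle_aged",
                     prof$age_group == "middle_aged"),
              margin("bmi", "healthy", healthy),
              margin("bmi", "non_healthy", !healthy))
  list(n = nrow(thresholds), n_reliable = sum(thresholds$reliable),
       frac_reliable = mean(thresholds$reliable),
       excluded = attr(thresholds, "excluded") %||% character(),
       group_means = gm)
}
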