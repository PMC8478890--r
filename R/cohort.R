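#' Generate a synthetic volunteer cohort
#'
#' Draws one volunteer profile per configured slot: gender and age group
#' from the group sizes, height from a gender-specific normal, weight via a
#' BMI draw (so the cohort spans the healthy BMI band 18.5-24 and both
#' sides of it), a resting baseline heart rate from the group-specific
#' distribution, and a latent PM2.5 risk threshold (the concentration at
#' which the volunteer's subjective judgement switches from safe to risk).
#' A per-volunteer RNG substream seed is drawn once here, so later walk
#' simulation is reproducible regardless of the order volunteers are
#' processed in.
#'
#' @param config a [sim_config()] object.
#' @return a data frame of class `walkrisk_cohort` with one row per
#'   volunteer: `volunteer_id`, `gender`, `age_group`, `height_m`,
#'   `weight_kg`, `baseline_hr`, plus the simulation ground truth
#'   `latent_threshold` (ug/m3) and the internal `rng_seed`.
#' @examples
#' cohort <- generate_cohort(sim_config(seed = 1))
#' table(cohort$gender, cohort$age_group)
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  with_local_seed(config$seed, {
    rows <- lapply(group_levels(), function(g) {
      n <- config$group_sizes[[g]]
      if (n == 0L) return(NULL)
      gender <- if (startsWith(g, "male")) "male" else "female"
      age_group <- if (endsWith(g, "youth")) "youth" else "middle_aged"
      height <- rnorm(n, config$height_params[[gender]],
                      config$height_params[["sd"]])
      height <- pmin(pmax(height, 1.2), 2.2)
      bmi <- rnorm(n, config$bmi_params[["mean"]], config$bmi_params[["sd"]])
      weight <- pmin(pmax(bmi * height^2, 35), 160)
      bhp <- config$baseline_hr_params[[g]]
      baseline <- pmin(pmax(rnorm(n, bhp[["mean"]], bhp[["sd"]]), 45), 110)
      ltp <- config$latent_threshold_params[[g]]
      latent <- pmin(pmax(rnorm(n, ltp[["mean"]], ltp[["sd"]]),
                          config$pm_range[1] + 1), config$pm_range[2] - 1)
      data.frame(gender = gender, age_group = age_group,
                 height_m = height, weight_kg = weight,
                 baseline_hr = baseline, latent_threshold = latent,
                 stringsAsFactors = FALSE)
    })
    cohort <- do.call(rbind, rows)
    if (is.null(cohort)) {
      cohort <- data.frame(volunteer_id = character(), gender = character(),
                           age_group = character(), height_m = numeric(),
                           weight_kg = numeric(), baseline_hr = numeric(),
                           latent_threshold = numeric(),
                           rng_seed = integer(), stringsAsFactors = FALSE)
    } else {
      cohort <- cbind(volunteer_id = sprintf("V%03d", seq_len(nrow(cohort))),
                      cohort, stringsAsFactors = FALSE)
      cohort$rng_seed <- sample.int(.Machine$integer.max, nrow(cohort))
    }
    rownames(cohort) <- NULL
    class(cohort) <- c("walkrisk_cohort", "data.frame")
    cohort
  })
}

# Group-specific HR% response to an instantaneous PM2.5 concentration.
# Young males respond affinely; the other groups follow a monotone sum of
# two logistic terms with inflections at the configured concentrations.
hr_response_fraction <- function(pm25, gender, age_group, config) {
  if (gender == "male" && age_group == "youth") {
    p <- config$hr_response$male_youth
    p[["intercept"]] + p[["slope"]] * pm25
  } else {
    p <- config$hr_response$s_curve
    p[["amp1"]] * plogis((pm25 - p[["infl1"]]) / p[["scale"]]) +
      p[["amp2"]] * plogis((pm25 - p[["infl2"]]) / p[["scale"]])
  }
}

#' Simulate one volunteer's walk
#'
#' Produces a 1 Hz heart-rate series, a 1-minute PM2.5/PM10 series and
#' per-interval subjective safe/risk labels for a single volunteer.  The
#' PM2.5 trajectory is a bounded random walk at 60-s steps reflecting at
#' the configured range edges (street-level concentrations are strongly
#' autocorrelated), expanded to 1 Hz as a zero-order hold to drive the
#' heart-rate response (each 1-minute reading is the integrated
#' concentration for that minute); PM10 is an affine function of PM2.5
#' plus noise, clipped so
#' that PM10 >= PM2.5 at every sample.  An interval is labelled risk (1)
#' exactly when its mean PM2.5 exceeds the volunteer's latent threshold;
#' labels are then flipped independently with probability `label_noise`.
#'
#' @param profile one-row data frame (or list) with at least `volunteer_id`,
#'   `gender`, `age_group`, `baseline_hr`, `latent_threshold`; profiles from
#'   [generate_cohort()] also carry `rng_seed`, used as the volunteer's RNG
#'   substream (otherwise the root `config$seed` is used).
#' @param config a [sim_config()] object.
#' @return an object of class `walk_recording`: a list with data frames
#'   `hr` (`timestamp_s`, `hr_bpm` at 1 Hz), `pm` (`timestamp_s`,
#'   `pm25_ugm3`, `pm10_ugm3` at 60-s spacing) and `labels`
#'   (`interval_index`, `state` with safe = 0, risk = 1), plus
#'   `volunteer_id` and the `label_interval` used.
#' @export
simulate_walk <- function(profile, config) {
  validate_sim_config(config)
  profile <- as.list(profile)
  for (f in c("volunteer_id", "gender", "age_group", "baseline_hr",
              "latent_threshold"))
    if (is.null(profile[[f]]))
      stop_field("profile", paste("missing field", f))
  if (config$walk_duration < config$label_interval)
    stop_field("walk_duration", "shorter than one aggregation interval")
  seed <- profile$rng_seed %||% config$seed
  with_local_seed(seed, {
    n_min <- floor(config$walk_duration / 60)
    lo <- config$pm_range[1]; hi <- config$pm_range[2]

    # reflecting random walk at 60-s resolution
    steps <- rnorm(n_min, 0, config$pm_step_sd)
    pm25 <- numeric(n_min)
    pm25[1] <- runif(1, lo, hi)
    for (k in seq_len(n_min - 1L)) {
      x <- pm25[k] + steps[k]
      # reflect into [lo, hi]
      while (x < lo || x > hi) x <- if (x < lo) 2 * lo - x else 2 * hi - x
      pm25[k + 1L] <- x
    }
    prp <- config$pm10_ratio_params
    pm10 <- prp[["intercept"]] + prp[["slope"]] * pm25 +
      rnorm(n_min, 0, prp[["noise_sd"]])
    pm10 <- pmax(pm10, pm25)
    pm_ts <- (seq_len(n_min) - 1L) * 60L

    # 1 Hz heart rate driven by PM2.5 held constant over each sampling
    # minute (the 1-min particle reading is an integrated concentration
    # for that minute, not an instantaneous point value)
    hr_ts <- seq.int(0L, n_min * 60L - 1L)
    pm25_1hz <- approx(pm_ts, pm25, xout = hr_ts, rule = 2,
                       method = "constant", f = 0)$y
    frac <- hr_response_fraction(pm25_1hz, profile$gender, profile$age_group,
                                 config)
    hr <- profile$baseline_hr * (1 + frac)
    if (config$hr_noise_sd > 0)
      hr <- hr + rnorm(length(hr), 0, config$hr_noise_sd)

    # per-interval subjective labels from the latent PM2.5 threshold
    iv <- config$label_interval
    idx <- floor(pm_ts / iv)
    mean_pm <- tapply(pm25, idx, mean)
    state <- as.integer(mean_pm > profile$latent_threshold)
    if (config$label_noise > 0) {
      flip <- runif(length(state)) < config$label_noise
      state[flip] <- 1L - state[flip]
    }
    labels <- data.frame(interval_index = as.integer(names(mean_pm)),
                         state = state)

    structure(list(
      volunteer_id = profile$volunteer_id,
      hr = data.frame(timestamp_s = hr_ts, hr_bpm = hr),
      pm = data.frame(timestamp_s = pm_ts, pm25_ugm3 = pm25,
                      pm10_ugm3 = pm10),
      labels = labels,
      label_interval = iv), class = "walk_recording")
  })
}

#' Simulate walks for a whole cohort
#'
#' @param cohort a [generate_cohort()] data frame.
#' @param config the matching [sim_config()].
#' @return a named list of [simulate_walk()] recordings, one per volunteer.
#' @export
simulate_cohort_walks <- function(cohort, config) {
  recs <- lapply(seq_len(nrow(cohort)),
                 function(i) simulate_walk(cohort[i, ], config))
  names(recs) <- cohort$volunteer_id
  recs
}

#' Group-level heart-rate summary
#'
#' Pools the 1 Hz heart-rate samples of all recordings per demographic
#' group and reports mean, standard deviation, maximum and minimum, the
#' standard campaign summary table.
#'
#' @param recordings list of `walk_recording` objects.
#' @param cohort the cohort data frame carrying `gender`/`age_group` per
#'   volunteer.
#' @return data frame with one row per non-empty group: `group`, `n_volunteers`,
#'   `mean`, `sd`, `max`, `min` (bpm).  Groups without recordings are
#'   omitted with a warning.
#' @export
cohort_summary <- function(recordings, cohort) {
  ids <- vapply(recordings, function(r) r$volunteer_id, character(1))
  m <- match(ids, cohort$volunteer_id)
  if (anyNA(m)) stop("recordings contain volunteers absent from the cohort",
                     call. = FALSE)
  grp <- group_key(cohort$gender[m], cohort$age_group[m])
  out <- lapply(group_levels(), function(g) {
    sel <- which(grp == g)
    if (!length(sel)) return(NULL)
    hr <- unlist(lapply(recordings[sel], function(r) r$hr$hr_bpm),
                 use.names = FALSE)
    data.frame(group = g, n_volunteers = length(sel), mean = mean(hr),
               sd = sd(hr), max = max(hr), min = min(hr),
               stringsAsFactors = FALSE)
  })
  missing <- group_levels()[vapply(out, is.null, logical(1))]
  if (length(missing))
    warning("no recordings for group(s): ", paste(missing, collapse = ", "),
            call. = FALSE)
  do.call(rbind, out)
}

#' Write cohort recordings to delimited text files
#'
#' Writes the four-campaign-file layout: `heart_rate.csv` (volunteer_id,
#' timestamp_s, hr_bpm), `pm.csv` (volunteer_id, timestamp_s, pm25_ugm3,
#' pm10_ugm3), `labels.csv` (volunteer_id, interval_index, state) and
#' `profiles.csv` (volunteer_id, gender, age_group, height_m, weight_kg,
#' baseline_hr).  Real campaign data in the same schemas is accepted by
#' [read_recordings()] / [run_pipeline()] interchangeably.
#'
#' @param recordings list of `walk_recording` objects.
#' @param cohort the cohort data frame.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_recordings <- function(recordings, cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bind <- function(extract) {
    do.call(rbind, lapply(recordings, function(r)
      cbind(volunteer_id = r$volunteer_id, extract(r),
            stringsAsFactors = FALSE)))
  }
  hr <- bind(function(r) r$hr)
  pm <- bind(function(r) r$pm)
  lb <- bind(function(r) r$labels)
  prof <- cohort[, c("volunteer_id", "gender", "age_group", "height_m",
                     "weight_kg", "baseline_hr")]
  paths <- c(heart_rate = file.path(dir, "heart_rate.csv"),
             pm = file.path(dir, "pm.csv"),
             labels = file.path(dir, "labels.csv"),
             profiles = file.path(dir, "profiles.csv"))
  utils::write.csv(hr, paths[["heart_rate"]], row.names = FALSE)
  utils::write.csv(pm, paths[["pm"]], row.names = FALSE)
  utils::write.csv(lb, paths[["labels"]], row.names = FALSE)
  utils::write.csv(prof, paths[["profiles"]], row.names = FALSE)
  invisible(paths)
}

#' Read recordings back from the delimited-text layout
#'
#' @param dir directory containing the files written by
#'   [write_recordings()] (or real data in the same schemas).
#' @param label_interval seconds per label interval (default 60).
#' @return list with `recordings` (list of `walk_recording`) and `profiles`
#'   (data frame).
#' @export
read_recordings <- function(dir, label_interval = 60) {
  paths <- file.path(dir, c("heart_rate.csv", "pm.csv", "labels.csv",
                            "profiles.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  hr <- utils::read.csv(paths[1]); pm <- utils::read.csv(paths[2])
  lb <- utils::read.csv(paths[3]); prof <- utils::read.csv(paths[4])
  ids <- unique(prof$volunteer_id)
  recs <- lapply(ids, function(id) {
    structure(list(
      volunteer_id = id,
      hr = hr[hr$volunteer_id == id, c("timestamp_s", "hr_bpm")],
      pm = pm[pm$volunteer_id == id,
              c("timestamp_s", "pm25_ugm3", "pm10_ugm3")],
      labels = lb[lb$volunteer_id == id, c("interval_index", "state")],
      label_interval = label_interval), class = "walk_recording")
  })
  names(recs) <- ids
  list(recordings = recs, profiles = prof)
}
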