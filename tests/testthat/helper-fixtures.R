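# Shared fixtures: small configurations and hand-built records.

tiny_config <- function(n = 4, seed = 7, walk_duration = 1800, ...) {
  sim_config(group_sizes = c(male_youth = n, female_youth = n,
                             male_middle_aged = n, female_middle_aged = n),
             seed = seed, walk_duration = walk_duration, ...)
}

# A hand-built walk recording: constant or supplied HR at 1 Hz, PM at 60-s
# spacing, optional labels.
manual_recording <- function(hr_bpm, pm25, pm10 = pm25 * 1.5 + 10,
                             labels = NULL, id = "T01",
                             label_interval = 60) {
  n <- length(hr_bpm)
  structure(list(
    volunteer_id = id,
    hr = data.frame(timestamp_s = seq_len(n) - 1L, hr_bpm = hr_bpm),
    pm = data.frame(timestamp_s = (seq_along(pm25) - 1L) * 60L,
                    pm25_ugm3 = pm25, pm10_ugm3 = pm10),
    labels = labels,
    label_interval = label_interval), class = "walk_recording")
}

manual_profile <- function(id = "T01", baseline = 75, gender = "male",
                           age_group = "youth", height = 1.75,
                           weight = 70) {
  data.frame(volunteer_id = id, gender = gender, age_group = age_group,
             height_m = height, weight_kg = weight, baseline_hr = baseline,
             stringsAsFactors = FALSE)
}

# Interval-record data frame straight from numbers.
manual_intervals <- function(hr_percent, state, pm25 = seq_along(hr_percent),
                             id = "T01") {
  data.frame(volunteer_id = id,
             interval_index = seq_along(hr_percent) - 1L,
             mean_hr = 75 * (1 + hr_percent), hr_percent = hr_percent,
             mean_pm25 = pm25, mean_pm10 = pm25 * 1.5, state = state,
             stringsAsFactors = FALSE)
}

# Exhaustive Mann-Whitney AUC: proportion of (positive, negative) pairs
# ranked correctly, ties counting one half.
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}
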