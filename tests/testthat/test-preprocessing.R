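test_that("HR% is the relative deviation from baseline", {
  expect_equal(compute_hr_percent(91, 70), 0.30)
  expect_equal(compute_hr_percent(70, 70), 0)
  expect_equal(compute_hr_percent(94.4, 80), 0.18)
  expect_lt(compute_hr_percent(60, 75), 0)      # may be negative
  expect_error(compute_hr_percent(80, 0), "baseline")
})

test_that("BMI and the healthy band follow the standard definition", {
  b <- compute_bmi(70, 1.75)
  expect_equal(b$bmi, 70 / 1.75^2)
  expect_true(b$healthy)
  expect_true(compute_bmi(18.5, 1)$healthy)     # inclusive lower bound
  expect_true(compute_bmi(24, 1)$healthy)       # inclusive upper bound
  b2 <- compute_bmi(90, 1.70)
  expect_equal(b2$bmi, 90 / 1.7^2)
  expect_false(b2$healthy)
  expect_error(compute_bmi(-1, 1.7), "positive")
})

test_that("interval aggregation averages within half-open windows", {
  rec <- manual_recording(rep(90, 120), c(40, 60))
  iv <- aggregate_intervals(rec, manual_profile(baseline = 75), 60)
  expect_equal(nrow(iv), 2)
  expect_equal(iv$mean_hr, c(90, 90))
  expect_equal(iv$hr_percent, c(0.20, 0.20))
  expect_equal(iv$mean_pm25, c(40, 60))

  rec2 <- manual_recording(c(rep(80, 30), rep(100, 30)), 55)
  iv2 <- aggregate_intervals(rec2, manual_profile(baseline = 75), 60)
  expect_equal(iv2$mean_hr, 90)
})

test_that("trailing partial windows follow the half-length rule", {
  # 150 s: trailing 30 s window is exactly half an interval -> kept
  rec <- manual_recording(rep(80, 150), c(40, 50, 60))
  expect_equal(nrow(aggregate_intervals(rec, manual_profile(), 60)), 3)
  # 149 s: trailing 29 s window is shorter than half -> dropped
  rec2 <- manual_recording(rep(80, 149), c(40, 50, 60))
  expect_equal(nrow(aggregate_intervals(rec2, manual_profile(), 60)), 2)
})

test_that("windows without any PM sample are excluded with a warning", {
  rec <- manual_recording(rep(80, 120), 40)   # PM only at t = 0
  expect_warning(iv <- aggregate_intervals(rec, manual_profile(), 60),
                 "without a PM sample")
  expect_equal(nrow(iv), 1)
  expect_error(aggregate_intervals(
    structure(list(volunteer_id = "x",
                   hr = data.frame(timestamp_s = numeric(),
                                   hr_bpm = numeric()),
                   pm = data.frame(timestamp_s = 0, pm25_ugm3 = 1,
                                   pm10_ugm3 = 2)),
              class = "walk_recording"),
    manual_profile(), 60), "empty")
})

test_that("window tiling assigns no sample twice and covers kept samples once", {
  cfg <- tiny_config(seed = 31)
  cohort <- generate_cohort(cfg)
  rec <- simulate_walk(cohort[1, ], cfg)
  for (s in c(30, 60, 90, 300)) {
    iv <- suppressWarnings(aggregate_intervals(rec, cohort[1, ], s))
    expect_false(any(duplicated(iv$interval_index)))
    # reconstructing window membership: every HR sample maps to at most one
    # kept window, and kept windows' sample counts sum to <= series length
    counts <- table(floor(rec$hr$timestamp_s / s))
    expect_lte(sum(counts[names(counts) %in% iv$interval_index]),
               nrow(rec$hr))
  }
})

test_that("aggregation at one-second intervals reproduces the raw series", {
  hr <- 70 + sin(seq_len(180) / 9) * 8
  rec <- manual_recording(hr, c(40, 50, 60))
  rec$pm <- data.frame(timestamp_s = seq_len(180) - 1L,
                       pm25_ugm3 = rep(50, 180),
                       pm10_ugm3 = rep(80, 180))
  iv <- aggregate_intervals(rec, manual_profile(baseline = 70), 1)
  expect_equal(iv$mean_hr, hr)
  expect_equal(iv$hr_percent, (hr - 70) / 70)
})

test_that("interval diagnostic flags a perfect linear HR-PM relation", {
  pm <- list(seq(20, 280, length.out = 30), seq(280, 20, length.out = 30))
  recs <- lapply(1:2, function(i) {
    conc <- rep(pm[[i]], each = 60)
    manual_recording(60 + 0.1 * conc, pm[[i]], id = paste0("L", i))
  })
  profs <- rbind(manual_profile("L1"), manual_profile("L2"))
  # summary.lm warns on an essentially perfect fit; that is the point here
  d <- suppressWarnings(interval_diagnostics(recs, profs, c(60, 120, 300)))
  expect_equal(d$interval_s, c(60, 120, 300))
  expect_true(all(d$sig_f < 1e-10))
  expect_true(all(d$f_value > 0))
  expect_true(all(d$sig_f >= 0 & d$sig_f <= 1))
})

test_that("interval diagnostic does not reject when HR is independent of PM", {
  set.seed(404)
  recs <- lapply(1:6, function(i) {
    manual_recording(rnorm(1800, 75, 5), runif(30, 20, 280),
                     id = paste0("N", i))
  })
  profs <- do.call(rbind, lapply(1:6, function(i)
    manual_profile(paste0("N", i))))
  d <- interval_diagnostics(recs, profs, c(30, 60, 120, 180, 240, 300))
  expect_equal(nrow(d), 6)            # one row per candidate interval
  # under independence rejections at the 5% level should be rare
  expect_gte(sum(d$sig_f > 0.05), 5)
})

test_that("correlation screen uses absolute coefficients with unit diagonal", {
  # perfectly anticorrelated HR% and PM2.5 must report |r| = 1
  iv <- manual_intervals(hr_percent = seq(0.5, 0.1, length.out = 5),
                         state = c(0, 0, 1, 1, 1),
                         pm25 = seq(100, 300, length.out = 5))
  iv2 <- iv; iv2$volunteer_id <- "T02"
  recs <- rbind(iv, iv2)
  profs <- rbind(manual_profile("T01", gender = "male", weight = 70),
                 manual_profile("T02", gender = "female", weight = 95,
                                age_group = "middle_aged"))
  m <- pearson_matrix(recs, profs)
  expect_equal(diag(m), rep(1, 5), ignore_attr = TRUE)
  expect_equal(m, t(m))
  expect_equal(m["HR%", "PM2.5"], 1)
  expect_true(all(m >= 0 & m <= 1, na.rm = TRUE))

  # zero-variance column flagged as undefined
  profs2 <- profs; profs2$gender <- "male"
  expect_warning(m2 <- pearson_matrix(recs, profs2), "zero-variance")
  expect_true(all(is.na(m2["gender", setdiff(colnames(m2), "gender")])))
})

test_that("correlation screen matches a two-pass covariance computation", {
  set.seed(52)
  n <- 40
  iv <- manual_intervals(hr_percent = runif(n, 0, 0.6),
                         state = rbinom(n, 1, 0.5),
                         pm25 = runif(n, 0, 300))
  prof <- manual_profile("T01")
  # single volunteer: constant dummy columns are flagged, which is fine here
  m <- suppressWarnings(pearson_matrix(iv, prof))
  x <- iv$hr_percent * 100; y <- iv$mean_pm25
  cov_xy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  r_oracle <- abs(cov_xy / sqrt(sum((x - mean(x))^2) / (n - 1)) /
                    sqrt(sum((y - mean(y))^2) / (n - 1)))
  expect_equal(m["HR%", "PM2.5"], r_oracle, tolerance = 1e-12)
})

test_that("independent covariates show near-zero sample correlation", {
  set.seed(61)
  n <- 1e4
  iv <- manual_intervals(hr_percent = rnorm(n), state = rbinom(n, 1, 0.5),
                         pm25 = rnorm(n))
  m <- suppressWarnings(pearson_matrix(iv, manual_profile("T01")))
  expect_lt(m["HR%", "PM2.5"], 0.05)
})

test_that("correlation strength bands step by 0.2", {
  expect_equal(as.character(correlation_strength(c(0.1, 0.3, 0.5, 0.7, 0.95))),
               c("very weak", "weak", "moderate", "strong", "very strong"))
})
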