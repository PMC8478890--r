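test_that("state classification uses the at-or-above convention", {
  th <- data.frame(volunteer_id = c("A", "B"),
                   hr_threshold = c(0.30, 0.20),
                   pm25_threshold = c(120, 100), youden_max = 1,
                   auc = 1, reliable = TRUE, stringsAsFactors = FALSE)
  iv <- rbind(manual_intervals(c(0.30, 0.29, 0.45), c(1, 0, 1), id = "A"),
              manual_intervals(c(0.10, 0.20, 0.19), c(0, 1, 0), id = "B"))
  out <- classify_states(iv, th)
  expect_equal(out$y, c(1L, 0L, 1L, 0L, 1L, 0L))  # boundary counts as risk

  # all HR% below all thresholds -> all safe
  low <- manual_intervals(c(0.01, 0.05), c(0, 0), id = "A")
  expect_equal(classify_states(low, th)$y, c(0L, 0L))

  # volunteers without a threshold are dropped with a message
  extra <- rbind(iv, manual_intervals(0.5, 1, id = "Z"))
  expect_message(kept <- classify_states(extra, th), "without a threshold")
  expect_false("Z" %in% kept$volunteer_id)
})

test_that("design matrix codes dummies and HR% percentage points", {
  iv <- manual_intervals(c(0.35, 0.10), c(1, 0), pm25 = c(150, 50),
                         id = "A")
  prof <- manual_profile("A", gender = "male", age_group = "youth",
                         height = 1.75, weight = 70)
  iv$y <- c(1L, 0L)
  d <- design_matrix(iv, prof)
  expect_equal(names(d), c("y", "pm25", "male", "youth", "bmi_healthy",
                           "hr_pct"))
  expect_equal(d$male, c(1L, 1L))
  expect_equal(d$youth, c(1L, 1L))
  expect_equal(d$bmi_healthy, c(1L, 1L))        # BMI 22.86 in band
  expect_equal(d$hr_pct, c(35, 10))             # percentage points

  prof2 <- manual_profile("A", gender = "female",
                          age_group = "middle_aged", weight = 95)
  d2 <- design_matrix(iv, prof2)
  expect_equal(d2$male, c(0L, 0L))
  expect_equal(d2$youth, c(0L, 0L))
  expect_equal(d2$bmi_healthy, c(0L, 0L))       # BMI 31 outside band
})

test_that("intercept-only fit reproduces the log-odds of the mean", {
  y <- rep(c(0L, 1L), times = c(30, 10))
  fit <- fit_logit(data.frame(y = y))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), qlogis(mean(y)), tolerance = 1e-8)
})

test_that("a saturated 2x2 table recovers the hand-computed log odds ratio", {
  a <- 17; b <- 9; c_ <- 6; d <- 21     # exposed/unexposed x risk/safe
  y <- c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d))
  x <- c(rep(1, a + b), rep(0, c_ + d))
  fit <- fit_logit(data.frame(y = y, x = x))
  expect_lt(abs(coef(fit)[["x"]] - log(a * d / (b * c_))), 1e-6)
  # Wald standard error: sqrt of summed reciprocal cell counts
  expect_equal(fit$se[["x"]], sqrt(1/a + 1/b + 1/c_ + 1/d),
               tolerance = 1e-6)
})

test_that("the score equation holds at the maximum on arbitrary data", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(40:200, 1)
    d <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
    eta <- -0.3 + 0.8 * d$x1 - 0.5 * d$x2
    d <- cbind(y = rbinom(n, 1, plogis(eta)), d)
    if (length(unique(d$y)) < 2) next
    fit <- fit_logit(d)
    expect_lt(abs(sum(fit$fitted) - sum(d$y)), 1e-6)
  }
})

test_that("Newton-Raphson agrees with an independent IRLS implementation", {
  set.seed(23)
  n <- 300
  d <- data.frame(pm25 = runif(n, 0, 300), male = rbinom(n, 1, 0.5),
                  hr_pct = runif(n, 0, 50))
  eta <- -3 + 0.015 * d$pm25 - 0.4 * d$male + 0.03 * d$hr_pct
  d <- cbind(y = rbinom(n, 1, plogis(eta)), d)
  fit <- fit_logit(d)
  ref <- stats::glm(y ~ pm25 + male + hr_pct, family = stats::binomial(),
                    data = d)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)),
               tolerance = 1e-8)
})

test_that("grid search over the likelihood surface matches Newton-Raphson", {
  # two-stage dense grid (coarse 0.1 sweep, then 0.001 refinement) that
  # never consults the Newton-Raphson estimate
  grid_mle <- function(y, X) {
    ll <- function(beta) {
      eta <- drop(X %*% beta)
      sum(y * eta - pmax(eta, 0) - log1p(exp(-abs(eta))))
    }
    best <- NULL; best_ll <- -Inf
    coarse <- seq(-5, 5, by = 0.1)
    grids <- rep(list(coarse), ncol(X))
    for (stage in 1:2) {
      pts <- as.matrix(expand.grid(grids))
      vals <- apply(pts, 1, ll)
      best <- pts[which.max(vals), ]
      best_ll <- max(vals)
      grids <- lapply(best, function(b) seq(b - 0.1, b + 0.1, by = 0.001))
    }
    list(beta = best, loglik = best_ll)
  }
  set.seed(31)
  for (i in 1:3) {
    n <- 60
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.4 + 0.9 * x))
    if (length(unique(y)) < 2) next
    fit <- fit_logit(data.frame(y = y, x = x))
    oracle <- grid_mle(y, cbind(1, x))
    expect_lt(abs(fit$loglik - oracle$loglik), 1e-4)
    expect_lt(max(abs(coef(fit) - oracle$beta)), 2e-3)
  }
})

test_that("degenerate outcomes and separation are diagnosed", {
  set.seed(55)
  expect_error(fit_logit(data.frame(y = c(1, 1, 1, 1), x = rnorm(4))),
               "single-class")
  # complete separation on a small-scale covariate drives the coefficient
  # past the divergence guard
  d <- data.frame(y = rep(c(0, 1), each = 25),
                  x = c(rnorm(25, -0.1, 0.02), rnorm(25, 0.1, 0.02)))
  expect_error(fit_logit(d), "separation")
  expect_error(fit_logit(data.frame(y = c(0, 1), x = c(0, 1))), "rows")
})

test_that("Wald table reports both conventions and exact odds ratios", {
  set.seed(44)
  n <- 400
  d <- data.frame(x = rnorm(n))
  d <- cbind(y = rbinom(n, 1, plogis(0.2 + 0.6 * d$x)), d)
  fit <- fit_logit(d)
  w <- wald_and_or(fit)
  expect_equal(w$wald_chisq, w$wald_z^2)
  expect_equal(w$exp_beta, exp(w$beta))
  expect_equal(w$df, rep(1L, 2))
  expect_equal(w$p_value, pchisq(w$wald_chisq, 1, lower.tail = FALSE))

  z <- wald_and_or(c(a = 0))
  expect_equal(z$exp_beta, 1)
})

test_that("risk prediction evaluates the logistic of the linear predictor", {
  beta <- reference_coefficients()
  zero <- data.frame(pm25 = 0, male = 0, youth = 0, bmi_healthy = 0,
                     hr_pct = 0)
  expect_equal(predict_risk(beta, zero), plogis(-6.323))
  expect_equal(predict_risk(beta, zero), 0.001791, tolerance = 1e-3)

  # linear predictor 0 -> exactly one half
  b0 <- c(`(Intercept)` = 0, x = 1)
  expect_equal(predict_risk(b0, data.frame(x = 0)), 0.5)

  hot <- data.frame(pm25 = 150, male = 1, youth = 1, bmi_healthy = 1,
                    hr_pct = 35)
  lp <- -6.323 + 0.056 * 150 - 0.264 - 0.393 - 0.327 + 0.108 * 35
  expect_equal(lp, 4.873, tolerance = 1e-12)
  expect_equal(predict_risk(beta, hot), plogis(4.873))
  expect_equal(predict_risk(beta, hot), 0.9924, tolerance = 1e-4)
  expect_error(predict_risk(beta, data.frame(pm25 = 1)), "lacks")
})

test_that("risk probability is monotone in PM2.5 and HR% for positive slopes", {
  beta <- reference_coefficients()
  pm <- seq(0, 300, by = 10)
  p <- predict_risk(beta, data.frame(pm25 = pm, male = 0, youth = 0,
                                     bmi_healthy = 0, hr_pct = 30))
  expect_true(all(diff(p) > 0))
  hr <- seq(0, 60, by = 5)
  p2 <- predict_risk(beta, data.frame(pm25 = 100, male = 0, youth = 0,
                                      bmi_healthy = 0, hr_pct = hr))
  expect_true(all(diff(p2) > 0))
})

test_that("risk curves cover four groups and collapse when the slope is zero", {
  rc <- risk_curves(hr_pct = 35, bmi_healthy = 1)
  expect_equal(length(unique(rc$group)), 4)
  flat <- reference_coefficients()
  flat[["pm25"]] <- 0
  rc0 <- risk_curves(flat, pm_grid = seq(0, 300, by = 50), hr_pct = 35)
  expect_true(all(tapply(rc0$probability, rc0$group, function(p)
    max(p) - min(p)) == 0))
  # curve value at zero concentration equals a direct prediction
  p0 <- rc$probability[rc$group == "male_youth" & rc$pm25 == 0]
  expect_equal(p0, predict_risk(reference_coefficients(),
                                data.frame(pm25 = 0, male = 1, youth = 1,
                                           bmi_healthy = 1, hr_pct = 35)))
  expect_error(risk_curves(pm_grid = numeric()), "grid")
})
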