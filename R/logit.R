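#' Classify intervals into safe/risk states by per-volunteer thresholds
#'
#' Sets the virtual dependent variable of the logit stage: an interval is
#' in the risk state (y = 1) exactly when its HR% is at or above the
#' owning volunteer's HR% threshold — the same boundary convention as the
#' ROC judgement.  Records of volunteers without a threshold are dropped
#' with a message.
#'
#' @param records interval records.
#' @param thresholds a [cohort_thresholds()] result.
#' @param exclude_unreliable drop volunteers whose AUC failed the
#'   reliability gate (default `FALSE`).
#' @return the records with a `y` column appended.
#' @export
classify_states <- function(records, thresholds,
                            exclude_unreliable = FALSE) {
  if (exclude_unreliable)
    thresholds <- thresholds[thresholds$reliable, , drop = FALSE]
  m <- match(records$volunteer_id, thresholds$volunteer_id)
  dropped <- unique(records$volunteer_id[is.na(m)])
  if (length(dropped))
    message("dropping ", length(dropped),
            " volunteer(s) without a threshold: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
  keep <- !is.na(m)
  records <- records[keep, , drop = FALSE]
  records$y <- as.integer(records$hr_percent >=
                            thresholds$hr_threshold[m[keep]])
  records
}

#' Build the five-covariate logit design
#'
#' One row per classified interval: `y` (risk state), `pm25`
#' (concentration, ug/m3), `male` (1 male / 0 female), `youth` (1 youth /
#' 0 middle-aged), `bmi_healthy` (1 if BMI in 18.5-24), and `hr_pct` (HR%
#' in percentage points, i.e. 100 times the stored fraction — the scale on
#' which a one-unit change means one percentage point).  Reference
#' categories are female, middle-aged and non-healthy BMI.
#'
#' @param records interval records (with `y` if produced by
#'   [classify_states()]).
#' @param profiles profile data frame.
#' @return data frame with columns `y` (if present), `pm25`, `male`,
#'   `youth`, `bmi_healthy`, `hr_pct`.
#' @export
design_matrix <- function(records, profiles) {
  m <- match(records$volunteer_id, profiles$volunteer_id)
  if (anyNA(m)) stop("records contain volunteers absent from profiles",
                     call. = FALSE)
  prof <- profiles[m, , drop = FALSE]
  healthy <- compute_bmi(prof$weight_kg, prof$height_m)$healthy
  out <- data.frame(pm25 = records$mean_pm25,
                    male = as.integer(prof$gender == "male"),
                    youth = as.integer(prof$age_group == "youth"),
                    bmi_healthy = as.integer(healthy),
                    hr_pct = 100 * records$hr_percent)
  if (!is.null(records$y)) out <- cbind(y = records$y, out)
  out
}

#' Fit a binary logit by Newton-Raphson maximum likelihood
#'
#' Maximizes the Bernoulli log-likelihood of the logit model
#' \eqn{\ln(p/(1-p)) = \beta_0 + \beta^T x} by Newton-Raphson (iteratively
#' reweighted least squares) with step-halving whenever a full step would
#' decrease the log-likelihood.  Standard errors come from the inverse
#' observed information at the maximum.  Convergence is declared when the
#' log-likelihood change drops below `tol_loglik` or the score max-norm
#' below `tol_grad`, capped at `max_iter` iterations.  A coefficient
#' escaping beyond `beta_bound` while the likelihood still improves is
#' diagnosed as complete separation and raises an error naming the
#' covariate.
#'
#' @param design data frame with a 0/1 column `y` and numeric covariate
#'   columns (an intercept is always added).
#' @param max_iter iteration cap.
#' @param tol_loglik absolute log-likelihood change tolerance.
#' @param tol_grad score max-norm tolerance.
#' @param beta_bound separation guard on |beta|.
#' @return object of class `walkrisk_logit`: `beta`, `se`, `vcov`,
#'   `loglik`, `converged`, `iterations`, `n`, `fitted`, `y`.
#' @examples
#' d <- data.frame(y = rbinom(200, 1, 0.4), x = rnorm(200))
#' fit <- fit_logit(d)
#' coef(fit)
#' @export
fit_logit <- function(design, max_iter = 100, tol_loglik = 1e-8,
                      tol_grad = 1e-6, beta_bound = 50) {
  if (is.null(design$y)) stop("design must contain a `y` column",
                              call. = FALSE)
  y <- design$y
  if (!all(y %in% c(0, 1))) stop("y must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("single-class outcome: logit undefined", call. = FALSE)
  X <- as.matrix(cbind(`(Intercept)` = 1,
                       design[, setdiff(names(design), "y"),
                              drop = FALSE]))
  storage.mode(X) <- "double"
  p <- ncol(X); n <- nrow(X)
  if (n < p + 1) stop("need at least ", p + 1, " rows", call. = FALSE)

  loglik <- function(beta) {
    eta <- drop(X %*% beta)
    # stable log(1 + exp(eta)) = max(eta, 0) + log1p(exp(-|eta|))
    sum(y * eta - pmax(eta, 0) - log1p(exp(-abs(eta))))
  }
  beta <- numeric(p)
  ll <- loglik(beta)
  converged <- FALSE
  iter <- 0L
  info <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- plogis(drop(X %*% beta))
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X * w, X)
    delta <- tryCatch(solve(info, score), error = function(e)
      stop("singular information matrix: covariates collinear or ",
           "degenerate", call. = FALSE))
    # step-halving if the full Newton step overshoots
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- loglik(cand)
      if (ll_new >= ll - 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    improving <- ll_new > ll
    beta <- cand
    dll <- ll_new - ll
    ll <- ll_new
    if (max(abs(beta)) > beta_bound && improving) {
      j <- which.max(abs(beta))
      stop("complete separation suspected: coefficient for `",
           colnames(X)[j], "` exceeds ", beta_bound,
           " while the likelihood still improves", call. = FALSE)
    }
    if (abs(dll) < tol_loglik || max(abs(score)) < tol_grad) {
      converged <- TRUE
      break
    }
  }
  mu <- plogis(drop(X %*% beta))
  info <- crossprod(X * (mu * (1 - mu)), X)
  vcov <- solve(info)
  se <- sqrt(diag(vcov))
  structure(list(beta = setNames(drop(beta), colnames(X)),
                 se = setNames(se, colnames(X)), vcov = vcov,
                 loglik = ll, converged = converged, iterations = iter,
                 n = n, fitted = mu, y = y),
            class = "walkrisk_logit")
}

#' @export
coef.walkrisk_logit <- function(object, ...) object$beta

#' @export
vcov.walkrisk_logit <- function(object, ...) object$vcov

#' @export
logLik.walkrisk_logit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta), class = "logLik")
}

#' @export
print.walkrisk_logit <- function(x, ...) {
  cat(sprintf(
    "Binary logit fit: n = %d, log-likelihood = %.4f, %s in %d iteration(s)\n",
    x$n, x$loglik,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  print(wald_and_or(x), digits = 4)
  invisible(x)
}

#' Wald tests and odds ratios for a logit fit
#'
#' For each coefficient reports the estimate, its standard error, the Wald
#' statistic in both conventions — z = beta/SE and its square as a
#' chi-squared statistic with 1 degree of freedom (the primary column) —
#' the chi-squared tail p-value, and the odds ratio Exp(beta).  A plain
#' named coefficient vector may be supplied instead of a fit, in which
#' case only the odds-ratio column is populated.
#'
#' @param fit a converged [fit_logit()] object, or a named numeric
#'   coefficient vector.
#' @return data frame: `variable`, `beta`, `se`, `wald_z`, `wald_chisq`,
#'   `df`, `p_value`, `exp_beta`.
#' @export
wald_and_or <- function(fit) {
  if (is.numeric(fit)) {
    beta <- fit
    se <- rep(NA_real_, length(beta))
  } else {
    if (!inherits(fit, "walkrisk_logit"))
      stop("fit must be a walkrisk_logit or a coefficient vector",
           call. = FALSE)
    if (!fit$converged) stop("fit did not converge", call. = FALSE)
    beta <- fit$beta; se <- fit$se
  }
  z <- beta / se
  data.frame(variable = names(beta) %||% paste0("beta", seq_along(beta) - 1),
             beta = unname(beta), se = unname(se), wald_z = unname(z),
             wald_chisq = unname(z^2), df = 1L,
             p_value = unname(stats::pchisq(z^2, df = 1,
                                            lower.tail = FALSE)),
             exp_beta = unname(exp(beta)), stringsAsFactors = FALSE)
}

#' Reference calibration of the walking-risk logit
#'
#' The coefficient preset for the five-covariate walking-risk model,
#' log-odds = -6.323 + 0.056 pm25 - 0.264 male - 0.393 youth
#' - 0.327 bmi_healthy + 0.108 hr_pct, with PM2.5 in ug/m3 and HR% in
#' percentage points.  Useful for drawing risk curves and for evaluating
#' risk probabilities without refitting.
#'
#' @return named numeric vector of length 6.
#' @examples
#' exp(reference_coefficients()[-1])   # odds ratios
#' @export
reference_coefficients <- function() {
  c(`(Intercept)` = -6.323, pm25 = 0.056, male = -0.264, youth = -0.393,
    bmi_healthy = -0.327, hr_pct = 0.108)
}

#' Predict the health-risk probability
#'
#' Evaluates p = exp(eta) / (1 + exp(eta)) with eta the linear predictor
#' of the logit model (computed in the numerically stable logistic form).
#'
#' @param fit a [fit_logit()] object, or a named coefficient vector such
#'   as [reference_coefficients()].
#' @param newdata data frame with the covariate columns of the fit
#'   (`pm25`, `male`, `youth`, `bmi_healthy`, `hr_pct` for the standard
#'   model); an intercept is implied.
#' @return numeric vector of risk probabilities in (0, 1).
#' @examples
#' predict_risk(reference_coefficients(),
#'              data.frame(pm25 = 150, male = 1, youth = 1,
#'                         bmi_healthy = 1, hr_pct = 35))
#' @export
predict_risk <- function(fit, newdata) {
  beta <- if (is.numeric(fit)) fit else coef(fit)
  vars <- setdiff(names(beta), "(Intercept)")
  missing <- setdiff(vars, names(newdata))
  if (length(missing))
    stop("newdata lacks covariate(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(newdata[, vars, drop = FALSE]))
  plogis(drop(X %*% beta[c("(Intercept)", vars)]))
}

#' Group risk curves over a PM2.5 grid
#'
#' Evaluates the risk probability along a PM2.5 grid for the four
#' gender-by-age groups at a fixed BMI band and a fixed HR% value, the
#' standard dose-response display of the model.
#'
#' @param fit a [fit_logit()] object or coefficient vector; defaults to
#'   [reference_coefficients()].
#' @param pm_grid increasing PM2.5 grid, ug/m3.
#' @param hr_pct HR% value substituted into every curve, percentage
#'   points.
#' @param bmi_healthy BMI-band flag substituted into every curve.
#' @return data frame: `group`, `gender`, `age_group`, `pm25`,
#'   `probability`, `hr_pct_used`, `bmi_healthy_used`.
#' @export
risk_curves <- function(fit = reference_coefficients(),
                        pm_grid = seq(0, 300, by = 5), hr_pct = 35,
                        bmi_healthy = 1) {
  if (!length(pm_grid)) stop("empty PM2.5 grid", call. = FALSE)
  if (is.unsorted(pm_grid, strictly = TRUE))
    stop("pm_grid must be strictly increasing", call. = FALSE)
  groups <- expand.grid(gender = c("male", "female"),
                        age_group = c("youth", "middle_aged"),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    nd <- data.frame(pm25 = pm_grid,
                     male = as.integer(g$gender == "male"),
                     youth = as.integer(g$age_group == "youth"),
                     bmi_healthy = bmi_healthy, hr_pct = hr_pct)
    data.frame(group = group_key(g$gender, g$age_group),
               gender = g$gender, age_group = g$age_group,
               pm25 = pm_grid, probability = predict_risk(fit, nd),
               hr_pct_used = hr_pct, bmi_healthy_used = bmi_healthy,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
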