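# regression_result builder from an lm fit; vcov_fun overrides the SEs
# (e.g., heteroskedasticity-robust) for the coefficient table
regression_result <- function(fit, vcov_mat = NULL, level = 0.95) {
  if (is.null(vcov_mat)) {
    ct <- stats::coef(summary(fit))
    ci <- stats::confint(fit, level = level)
  } else {
    ct <- lmtest::coeftest(fit, vcov. = vcov_mat)
    ci <- lmtest::coefci(fit, vcov. = vcov_mat, level = level)
    ct <- ct[, , drop = FALSE]
  }
  sm <- summary(fit)
  coefs <- data.frame(
    term = rownames(ct),
    estimate = ct[, 1],
    se = ct[, 2],
    t = ct[, 3],
    ci_low = ci[, 1],
    ci_high = ci[, 2],
    p = ct[, 4],
    row.names = NULL
  )
  fstat <- sm$fstatistic
  structure(list(
    coefficients = coefs,
    fit_stats = list(
      residual_se = sm$sigma,
      r_squared = sm$r.squared,
      adj_r_squared = sm$adj.r.squared,
      f_statistic = unname(fstat[1]),
      f_df = unname(fstat[2:3]),
      f_p = if (!is.null(fstat))
        stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
      else NA_real_
    ),
    formula = deparse(stats::formula(fit)),
    model = fit
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("<regression_result> ", x$formula, "\n", sep = "")
  print(x$coefficients, digits = 3, row.names = FALSE)
  fs <- x$fit_stats
  cat(sprintf("Residual SE %.3f, R2 %.3f (adj %.3f), F(%g,%g) = %.2f, p = %.3g\n",
              fs$residual_se, fs$r_squared, fs$adj_r_squared,
              fs$f_df[1], fs$f_df[2], fs$f_statistic, fs$f_p))
  invisible(x)
}

#' Per-subject EMG noise covariate
#'
#' The absolute log-ratio of EMG RMS between the two segments used in a
#' fingerprinting task: `|log(RMS_seg1) - log(RMS_seg2)|` per subject.
#'
#' @param cohort Cohort covariate table containing columns
#'   `emg_<seg1>` and `emg_<seg2>` (see [cohort_with_emg()]).
#' @param seg1,seg2 Segment labels (e.g. `"N2a"`, `"N2b"`).
#' @return data.frame (subject_id, noise) with attribute `segments`.
#' @export
emg_noise_covariate <- function(cohort, seg1, seg2) {
  c1 <- paste0("emg_", seg1)
  c2 <- paste0("emg_", seg2)
  if (!all(c(c1, c2) %in% names(cohort))) {
    stop(sprintf("cohort table lacks columns %s/%s", c1, c2))
  }
  r1 <- cohort[[c1]]
  r2 <- cohort[[c2]]
  bad <- which(!(r1 > 0) | !(r2 > 0))
  if (length(bad)) {
    stop("non-positive EMG RMS for subject(s): ",
         paste(cohort$subject_id[bad], collapse = ", "))
  }
  out <- data.frame(subject_id = cohort$subject_id,
                    noise = abs(log(r1) - log(r2)),
                    stringsAsFactors = FALSE)
  attr(out, "segments") <- c(seg1, seg2)
  out
}

#' Regression of differentiability scores on cohort covariates
#'
#' Ordinary least squares of the per-subject differentiability score on
#' the EMG noise covariate, sex, age, cap size and the noise-by-sex
#' interaction; for N1-type analyses an age-by-sex interaction is added.
#' Sex is coded with F as reference and cap with the small cap as
#' reference, so coefficients read as sex[M] and cap[FT].
#'
#' @param scores Named per-subject score vector (names = subject ids) or
#'   data.frame (subject_id, score).
#' @param cohort Cohort table with subject_id, age, sex, cap.
#' @param noise Output of [emg_noise_covariate()].
#' @param include_age_sex_interaction Add `sex:age` (the N1 model).
#' @return A `regression_result`.
#' @export
differentiability_regression <- function(scores, cohort, noise,
                                         include_age_sex_interaction = FALSE) {
  if (!is.data.frame(scores)) {
    scores <- data.frame(subject_id = names(scores), score = unname(scores),
                         stringsAsFactors = FALSE)
  }
  df <- merge(merge(scores, cohort, by = "subject_id"), noise,
              by = "subject_id")
  df <- df[stats::complete.cases(df[c("score", "noise", "sex", "age",
                                      "cap")]), ]
  df$sex <- factor(df$sex, levels = c("F", "M"))
  df$cap <- factor(df$cap, levels = c("small", "FT"))
  form <- score ~ noise + sex + age + cap + noise:sex
  if (include_age_sex_interaction) {
    form <- stats::update(form, . ~ . + sex:age)
  }
  # degenerate factor levels (e.g., single-sex cohort) alias terms
  fit <- stats::lm(form, data = df)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop("rank-deficient design; aliased term(s): ",
         paste(names(co)[is.na(co)], collapse = ", "))
  }
  regression_result(fit)
}

#' Polynomial regression of total spectral power on age
#'
#' Fits AUC-of-PSD as a polynomial in age (cubic by default) with
#' heteroskedasticity-robust (HC3) standard errors, capturing the
#' non-linear rise-then-fall of total power across childhood.
#'
#' @param auc Per-subject AUC values.
#' @param age Ages in years.
#' @param degree Polynomial degree (default 3).
#' @return A `regression_result` with robust SEs and CIs.
#' @export
auc_age_regression <- function(auc, age, degree = 3) {
  if (length(auc) <= degree + 1) stop("need n > degree + 1 observations")
  if (length(unique(age)) <= degree) stop("degenerate age values")
  df <- data.frame(auc = auc, age = age)
  fit <- stats::lm(auc ~ poly(age, degree, raw = TRUE), data = df)
  vc <- sandwich::vcovHC(fit, type = "HC3")
  res <- regression_result(fit, vcov_mat = vc)
  res$coefficients$term <- c("(Intercept)",
                             paste0("age^", seq_len(degree)))
  res
}

#' Linear regression of the EMG noise covariate on age
#'
#' Tests whether artifact load changes with age.
#'
#' @param noise Output of [emg_noise_covariate()] or a numeric vector.
#' @param age Ages in years (aligned with `noise`).
#' @return A `regression_result`.
#' @export
artifact_age_regression <- function(noise, age) {
  y <- if (is.data.frame(noise)) noise$noise else noise
  if (length(y) != length(age)) stop("noise and age lengths differ")
  if (length(unique(age)) < 2) stop("degenerate age values")
  fit <- stats::lm(y ~ age, data = data.frame(y = y, age = age))
  regression_result(fit)
}
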