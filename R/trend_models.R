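# Temporal trend models: population-level linear-in-time logistic trends
# for binary outcomes (NV-HAP by either definition, 30-day mortality), a
# GEE comparison of the two NV-HAP definitions with cluster-robust errors,
# a hurdle-NB trend for length of stay, and quarterly observed-vs-fitted
# summaries.  Time is measured in days since the study start internally;
# slopes are reported per year (x 365.25).

DAYS_PER_YEAR <- 365.25

#' Linear-in-time logistic trend for a binary outcome
#'
#' Fits `logit P(Y = 1) = b0 + b1 * t` with `t` = days since
#' `study_start`, and derives the model risks at the start and end of the
#' study with a delta-method confidence interval for their difference.
#'
#' @param dates admission dates.
#' @param y 0/1 outcome per hospitalization.
#' @param study_start,study_end window over which start/end risks are
#'   evaluated; default to the observed date range.
#' @return object of class `nvhap_trend` with coefficients, covariance,
#'   per-year slope and CI, and derived start/end risks and their
#'   difference with 95% CI (probability scale).
#' @export
fit_linear_trend_binary <- function(dates, y,
                                    study_start = min(dates),
                                    study_end = max(dates)) {
  dates <- as.Date(dates)
  if (length(unique(dates)) < 2L)
    stop("need at least two distinct admission dates")
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("outcome has a single level; trend is not estimable")
  t_days <- as.numeric(dates - study_start)
  fit <- glm(y ~ t_days, family = binomial())
  if (!fit$converged || any(!is.finite(sqrt(diag(vcov(fit))))))
    stop("logistic trend fit failed (possible complete separation)")
  beta <- coef(fit)
  V <- vcov(fit)
  t_end <- as.numeric(as.Date(study_end) - study_start)
  ps <- plogis(beta[1L])
  pe <- plogis(beta[1L] + beta[2L] * t_end)
  grad <- c(pe * (1 - pe) - ps * (1 - ps), t_end * pe * (1 - pe))
  se_diff <- sqrt(drop(t(grad) %*% V %*% grad))
  out <- list(coef = beta, vcov = V,
              study_start = study_start, study_end = as.Date(study_end),
              slope_per_year = unname(beta[2L]) * DAYS_PER_YEAR,
              slope_per_year_se = sqrt(V[2L, 2L]) * DAYS_PER_YEAR,
              risk_start = unname(ps), risk_end = unname(pe),
              risk_diff = unname(pe - ps), risk_diff_se = se_diff,
              risk_diff_ci = unname(ci95(pe - ps, se_diff)),
              slope_per_year_ci = unname(ci95(beta[2L] * DAYS_PER_YEAR,
                                              sqrt(V[2L, 2L]) *
                                                DAYS_PER_YEAR)))
  class(out) <- "nvhap_trend"
  out
}

#' Predicted risk from a fitted trend at arbitrary dates
#'
#' @param fit an `nvhap_trend` object.
#' @param dates dates at which to evaluate the fitted inverse-logit.
#' @return probabilities.
#' @export
predict_trend_risk <- function(fit, dates) {
  t_days <- as.numeric(as.Date(dates) - fit$study_start)
  plogis(fit$coef[1L] + fit$coef[2L] * t_days)
}

#' Compare definition-specific trends with a logistic GEE
#'
#' Takes the long table with two rows per hospitalization (one per
#' definition), fits `logit P = b0 + b_def + (b_t + b_int * def) * t` as a
#' GEE with independence working correlation and hospitalization-level
#' clustering (ordinary logistic score equations with robust sandwich
#' covariance), and reports the definition-by-time interaction -- the
#' difference in log-odds slopes per year -- with a robust 95% CI.
#'
#' @param long `data.frame` with columns `hospitalization_id`,
#'   `definition` (two levels; the second level's slope is contrasted
#'   against the first), `indicator` (0/1) and `date`.
#' @param study_start origin for the time axis.
#' @return list with the glm fit's coefficients, robust covariance,
#'   per-year slopes for both definitions and the interaction with CI.
#' @export
compare_definitions_gee <- function(long, study_start = min(long$date)) {
  long <- as.data.table(long)
  counts <- long[, .N, by = hospitalization_id]
  if (any(counts$N != 2L))
    stop("every hospitalization must contribute exactly two rows ",
         "(one per definition); offending ids: ",
         paste(head(counts[N != 2L]$hospitalization_id, 5L),
               collapse = ", "))
  long[, t_days := as.numeric(as.Date(date) - as.Date(study_start))]
  long[, definition := factor(definition)]
  if (nlevels(long$definition) != 2L)
    stop("definition must have exactly two levels")
  fit <- glm(indicator ~ definition * t_days, family = binomial(),
             data = long)
  Vr <- sandwich::vcovCL(fit, cluster = long$hospitalization_id)
  beta <- coef(fit)
  int_idx <- grep(":t_days", names(beta))
  est <- unname(beta[int_idx]) * DAYS_PER_YEAR
  se <- sqrt(Vr[int_idx, int_idx]) * DAYS_PER_YEAR
  slope1 <- unname(beta["t_days"]) * DAYS_PER_YEAR
  slope1_se <- sqrt(Vr["t_days", "t_days"]) * DAYS_PER_YEAR
  slope2 <- slope1 + est
  slope2_se <- sqrt(Vr["t_days", "t_days"] + Vr[int_idx, int_idx] +
                      2 * Vr["t_days", int_idx]) * DAYS_PER_YEAR
  list(coef = beta, vcov_robust = Vr, vcov_naive = vcov(fit),
       definitions = levels(long$definition),
       slope_per_year = c(slope1, slope2),
       slope_per_year_se = c(slope1_se, slope2_se),
       interaction_per_year = est, interaction_se = se,
       interaction_ci = unname(ci95(est, se)))
}

#' Linear-in-time hurdle-NB trend for length of stay
#'
#' Fits [fit_hurdle_los()] with design `(1, t)` and derives the model
#' mean LOS at the study start and end, with a delta-method CI for the
#' difference (gradient by forward finite differences over the stacked
#' hurdle and count parameters).
#'
#' @inheritParams fit_linear_trend_binary
#' @param los length of stay (days).
#' @return list with the hurdle fit and derived start/end means and their
#'   difference with 95% CI (days).
#' @export
fit_los_trend <- function(dates, los, study_start = min(dates),
                          study_end = max(dates)) {
  dates <- as.Date(dates)
  # time in years keeps the count-model optimization well conditioned
  t_years <- as.numeric(dates - study_start) / DAYS_PER_YEAR
  X <- cbind("(Intercept)" = 1, t_years = t_years)
  fit <- fit_hurdle_los(los, X)
  t_end <- as.numeric(as.Date(study_end) - study_start) / DAYS_PER_YEAR
  Xse <- cbind(1, c(0, t_end))
  mean_fun <- function(theta) {
    f2 <- fit
    p <- length(fit$hurdle$coef)
    f2$hurdle$coef <- theta[1:p]
    f2$nb$coef <- theta[(p + 1L):(2L * p)]
    f2$nb$theta <- exp(theta[2L * p + 1L])
    hurdle_mean_los(f2, Xse)
  }
  theta <- c(fit$hurdle$coef, fit$nb$coef, fit$nb$log_theta)
  V <- as.matrix(Matrix_bdiag(list(fit$hurdle$vcov, fit$nb$vcov)))
  base <- mean_fun(theta)
  G <- matrix(0, 2L, length(theta))
  for (j in seq_along(theta)) {
    h <- 1e-5 * max(1, abs(theta[j]))
    tj <- theta; tj[j] <- tj[j] + h
    G[, j] <- (mean_fun(tj) - base) / h
  }
  gd <- G[2L, ] - G[1L, ]
  se <- sqrt(drop(t(gd) %*% V %*% gd))
  diff <- base[2L] - base[1L]
  list(fit = fit, study_start = study_start, study_end = as.Date(study_end),
       mean_start = base[1L], mean_end = base[2L],
       mean_diff = diff, mean_diff_se = se,
       mean_diff_ci = unname(ci95(diff, se)))
}

#' Predicted mean LOS from a fitted LOS trend at arbitrary dates
#'
#' @param los_trend result of [fit_los_trend()].
#' @param dates evaluation dates.
#' @return expected LOS (days).
#' @export
predict_trend_los <- function(los_trend, dates) {
  t_years <- as.numeric(as.Date(dates) - los_trend$study_start) /
    DAYS_PER_YEAR
  hurdle_mean_los(los_trend$fit, cbind(1, t_years))
}

# small block-diagonal helper (avoids a Matrix dependency)
Matrix_bdiag <- function(mats) {
  sizes <- vapply(mats, nrow, 1L)
  out <- matrix(0, sum(sizes), sum(sizes))
  at <- 0L
  for (m in mats) {
    idx <- at + seq_len(nrow(m))
    out[idx, idx] <- as.matrix(m)
    at <- at + nrow(m)
  }
  out
}

#' Observed and model-predicted summaries by calendar quarter
#'
#' Partitions the study window into calendar quarters and reports the
#' observed proportion (or mean) next to the fitted model's prediction at
#' the quarter midpoint.
#'
#' @param dates admission dates.
#' @param y outcome values (0/1 or LOS days, matching the fit).
#' @param fit an `nvhap_trend` object or the result of [fit_los_trend()].
#' @return `data.table` with `quarter_start`, `n`, `observed` and
#'   `predicted`.
#' @export
quarterly_summaries <- function(dates, y, fit) {
  dates <- as.Date(dates)
  qstart <- as.Date(cut(dates, "quarter"))
  dt <- data.table(qstart = qstart, y = as.numeric(y))
  out <- dt[, .(n = .N, observed = mean(y)), by = qstart]
  setorder(out, qstart)
  mid <- out$qstart + 45L
  out[, predicted := if (inherits(fit, "nvhap_trend"))
    predict_trend_risk(fit, mid) else predict_trend_los(fit, mid)]
  setnames(out, "qstart", "quarter_start")
  out[]
}
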