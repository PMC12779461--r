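library(data.table)

test_that("null data give a null slope; two-point designs are closed form", {
  set.seed(1)
  n <- 10000
  dates <- as.Date("2016-01-01") + sample(0:729, n, replace = TRUE)
  y <- rbinom(n, 1, 0.5)
  fit <- fit_linear_trend_binary(dates, y)
  expect_lt(abs(fit$slope_per_year), 3 * fit$slope_per_year_se)

  # perfectly balanced two-date design: fitted slope times the gap equals
  # the empirical logit difference exactly
  d2 <- rep(as.Date(c("2016-01-01", "2017-01-01")), each = 500)
  y2 <- c(rbinom(500, 1, 0.3), rbinom(500, 1, 0.45))
  f2 <- fit_linear_trend_binary(d2, y2)
  gap <- as.numeric(diff(unique(d2)))
  expect_equal(unname(f2$coef[2] * gap),
               qlogis(mean(y2[501:1000])) - qlogis(mean(y2[1:500])),
               tolerance = 1e-8)

  expect_error(fit_linear_trend_binary(dates, rep(0L, n)), "single level")
  expect_error(fit_linear_trend_binary(rep(dates[1], 10),
                                       rbinom(10, 1, 0.5)), "distinct")
})

test_that("a declining log-odds trend is recovered with its endpoints", {
  set.seed(2)
  n <- 60000
  t_days <- runif(n, 0, 4.25 * 365.25)
  slope <- -0.18 / 365.25
  y <- rbinom(n, 1, plogis(qlogis(0.01) + slope * t_days))
  dates <- as.Date("2015-10-01") + t_days
  fit <- fit_linear_trend_binary(dates, y, as.Date("2015-10-01"),
                                 as.Date("2019-12-31"))
  expect_within_3se(fit$slope_per_year, -0.18, fit$slope_per_year_se)
  expect_lt(fit$risk_end, fit$risk_start)
  expect_lt(fit$risk_diff_ci[1], fit$risk_diff)
  expect_gt(fit$risk_diff_ci[2], fit$risk_diff)
  expect_true(all(abs(fit$risk_diff_ci) <= 1))

  # affine invariance: recentering the time origin leaves the slope and
  # derived risks unchanged
  fit2 <- fit_linear_trend_binary(dates, y, as.Date("2014-01-01"),
                                  as.Date("2019-12-31"))
  expect_equal(fit2$slope_per_year, fit$slope_per_year, tolerance = 1e-6)
  expect_equal(fit2$risk_end, fit$risk_end, tolerance = 1e-6)
})

test_that("the definition-comparison GEE recovers the trend contrast", {
  set.seed(3)
  n <- 40000
  t_days <- runif(n, 0, 4.25 * 365.25)
  dates <- as.Date("2015-10-01") + t_days
  # shared latent event induces positive within-hospitalization correlation
  latent <- rbinom(n, 1, plogis(qlogis(0.008)))
  slope_c <- -0.18 / 365.25
  y_elec <- ifelse(latent == 1, rbinom(n, 1, 0.7), rbinom(n, 1, 0.002))
  p_code <- plogis(qlogis(ifelse(latent == 1, 0.6, 0.003)) +
                     slope_c * t_days)
  y_code <- rbinom(n, 1, p_code)
  long <- rbind(
    data.table(hospitalization_id = 1:n, definition = "electronic",
               indicator = y_elec, date = dates),
    data.table(hospitalization_id = 1:n, definition = "coding",
               indicator = y_code, date = dates))
  gee <- compare_definitions_gee(long, as.Date("2015-10-01"))
  # levels sort coding first, so the interaction is electronic - coding
  expect_equal(gee$definitions, c("coding", "electronic"))
  expect_within_3se(gee$interaction_per_year, 0.18, gee$interaction_se)
  # the shared time slope is estimated from both rows of each cluster, so
  # positive within-cluster correlation inflates its robust variance
  expect_gt(gee$vcov_robust["t_days", "t_days"],
            gee$vcov_naive["t_days", "t_days"])

  expect_error(compare_definitions_gee(long[-1]), "exactly two rows")
})

test_that("hurdle LOS fit recovers parameters and satisfies the mean identity", {
  set.seed(4)
  n <- 30000
  x <- rbinom(n, 1, 0.4)
  X <- cbind(`(Intercept)` = 1, x = x)
  p1 <- plogis(-1.4 + 0.4 * x)
  mu <- exp(1.55 + 0.25 * x)
  th <- 1.25
  los <- ifelse(rbinom(n, 1, p1) == 1, 1,
                1 + nvhap:::rztnb(n, mu, th))
  fit <- fit_hurdle_los(los, X)
  hse <- sqrt(diag(fit$hurdle$vcov))
  nse <- sqrt(diag(fit$nb$vcov))
  expect_within_3se(fit$hurdle$coef[1], -1.4, hse[1])
  expect_within_3se(fit$hurdle$coef[2], 0.4, hse[2])
  expect_within_3se(fit$nb$coef[1], 1.55, nse[1])
  expect_within_3se(fit$nb$coef[2], 0.25, nse[2])
  expect_within_3se(fit$nb$log_theta, log(th), nse[3])

  # E[LOS | x] identity against the empirical means
  for (lev in 0:1) {
    sel <- x == lev
    m <- hurdle_mean_los(fit, cbind(1, lev))
    expect_within_3se(m, mean(los[sel]), sd(los[sel]) / sqrt(sum(sel)))
  }
  # intercept-only degenerate example
  f0 <- fit_hurdle_los(c(1, 1, 2, 2, 3))
  expect_equal(unname(plogis(f0$hurdle$coef[1])), 0.4, tolerance = 1e-6)
  expect_error(fit_hurdle_los(rep(3, 100)), "degenerate")
  expect_error(fit_hurdle_los(c(0, 1, 2)), ">= 1")
})

test_that("LOS-mass matrix is a renormalized hurdle-NB distribution", {
  set.seed(5)
  los <- ifelse(rbinom(2000, 1, 0.2) == 1, 1,
                1 + nvhap:::rztnb(2000, 5, 1.2))
  fit <- fit_hurdle_los(los)
  M <- hurdle_los_mass(fit, matrix(1, 3, 1), l_max = 40)
  expect_equal(rowSums(M), rep(1, 3))
  expect_true(all(M >= 0))
  # the l = 1 cell tracks the hurdle probability before renormalization
  expect_equal(M[1, 1], unname(plogis(fit$hurdle$coef[1])),
               tolerance = 0.01)
})

test_that("quarterly summaries conserve events and evaluate the fit", {
  set.seed(6)
  n <- 20000
  dates <- as.Date("2016-01-01") + sample(0:1095, n, replace = TRUE)
  y <- rbinom(n, 1, 0.05)
  fit <- fit_linear_trend_binary(dates, y)
  qs <- quarterly_summaries(dates, y, fit)
  expect_equal(sum(qs$n), n)
  expect_equal(sum(qs$observed * qs$n), sum(y))
  expect_equal(qs$predicted,
               predict_trend_risk(fit, qs$quarter_start + 45L))
  # quarters partition the window
  expect_equal(nrow(qs), 12L)
})

test_that("the LOS trend reports start and end means with a CI", {
  set.seed(7)
  n <- 20000
  dates <- as.Date("2016-01-01") + sample(0:729, n, replace = TRUE)
  t <- as.numeric(dates - as.Date("2016-01-01"))
  mu <- exp(1.5 + 0.0002 * t)
  los <- ifelse(rbinom(n, 1, 0.18) == 1, 1, 1 + nvhap:::rztnb(n, mu, 1.2))
  lt <- fit_los_trend(dates, los)
  expect_gt(lt$mean_end, lt$mean_start)
  expect_true(lt$mean_diff_ci[1] < lt$mean_diff &&
                lt$mean_diff < lt$mean_diff_ci[2])
  qs <- quarterly_summaries(dates, los, lt)
  expect_equal(sum(qs$n), n)
  # observed quarterly means track the fitted trajectory
  expect_lt(max(abs(qs$observed - qs$predicted)), 1)
})
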