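library(data.table)

test_that("pre/post windows are half-open and honor date shifts", {
  impl <- as.Date(c("2018-03-01", "2018-06-01"))
  h <- data.table(
    hospitalization_id = 1:6,
    site = c(1L, 1L, 1L, 2L, 2L, 2L),
    admit_date = as.Date(c("2018-03-01",          # on boundary -> post
                           "2018-02-28",          # day before -> pre
                           "2017-03-01",          # exactly impl-365 -> pre
                           "2018-06-01", "2017-06-02", "2019-06-01")),
    icu_ward = c(0L, 0L, 1L, 0L, 0L, 0L))
  cfgpp <- prepost_config(impl)
  sp <- split_pre_post(h, cfgpp)
  expect_setequal(sp$post$hospitalization_id, c(1L, 4L))
  expect_setequal(sp$pre$hospitalization_id, c(2L, 3L, 5L))
  # id 6 is outside both windows
  expect_false(6L %in% c(sp$pre$hospitalization_id,
                         sp$post$hospitalization_id))

  # brute-force date filter agrees on a generated cohort
  co <- generate_cohort(small_config(n_sites = 3, pps = 5), seed = 8,
                        include_clinical = FALSE)
  hh <- co$hospitalizations
  impl_by_site <- hh[, .(impl = data.table::first(impl_date)),
                     by = site][order(site)]$impl
  sp2 <- split_pre_post(hh, prepost_config(impl_by_site))
  expect_setequal(
    sp2$pre$hospitalization_id,
    hh[admit_date >= impl_date - 365 & admit_date < impl_date]$hospitalization_id)
  expect_setequal(
    sp2$post$hospitalization_id,
    hh[admit_date >= impl_date & admit_date < impl_date + 365]$hospitalization_id)

  # the anticipatory shift moves the boundary 91 days earlier
  shifted <- prepost_config(impl, date_shift = "minus_3_months")
  spS <- split_pre_post(h, shifted)
  expect_true(2L %in% spS$post$hospitalization_id)
  # completion-date shift uses the supplied dates
  comp <- prepost_config(impl, date_shift = "completion",
                         completion_dates = impl + 100)
  spC <- split_pre_post(h, comp)
  expect_false(1L %in% spC$post$hospitalization_id)
  expect_error(prepost_config(impl, date_shift = "completion"),
               "completion_dates")
  # subgroup filter
  sub <- prepost_config(impl, subgroup = "non_icu_only")
  expect_false(3L %in% split_pre_post(h, sub)$pre$hospitalization_id)
  # missing implementation date names the site
  h2 <- copy(h)[, site := site + 5L]
  expect_error(split_pre_post(h2, cfgpp), "site")
})

make_prefits <- function(seed = 21) {
  cfg <- scaled_study_config(pps = 10)
  co <- generate_cohort(cfg, seed = seed, include_clinical = FALSE,
                        include_truth_cf = FALSE)
  h <- co$hospitalizations
  tr <- co$truth[match(h$hospitalization_id, hospitalization_id)]
  h[, y := tr$true_event]
  sp <- split_pre_post(h, prepost_config(cfg$implementation_dates))
  fits <- fit_pre_models(sp$pre, y = sp$pre$y,
                         covariates = names(cfg$covariate_prevalences),
                         use_site = FALSE, use_year = FALSE)
  list(fits = fits, pre = sp$pre, post = sp$post)
}

test_that("counterfactual probabilities collapse analytically", {
  mp <- make_prefits()
  fits <- mp$fits
  rows <- mp$post[1:50]
  p <- counterfactual_probability(rows, fits)
  expect_true(all(p >= 0 & p <= 1))

  # outcome independent of LOS: the total-probability sum collapses to the
  # plain logistic prediction
  f0 <- fits
  f0$outcome$coef[["los"]] <- 0
  X <- nvhap:::build_design(f0$meta, rows)
  g0 <- f0$outcome$coef[setdiff(names(f0$outcome$coef), "los")]
  expect_equal(counterfactual_probability(rows, f0),
               unname(plogis(drop(X %*% g0))), tolerance = 1e-12)

  # degenerate hurdle (all mass at LOS = 1): result is P(event | LOS = 1)
  f1 <- fits
  f1$los$hurdle$coef[1] <- 30
  expect_equal(counterfactual_probability(rows, f1),
               unname(plogis(drop(X %*% g0) +
                               fits$outcome$coef[["los"]] * 1)),
               tolerance = 1e-9)
  expect_error(counterfactual_probability(rows, fits, l_max = 0), "l_max")
})

test_that("counterfactual probability matches Monte-Carlo integration", {
  mp <- make_prefits()
  fits <- mp$fits
  set.seed(9)
  rows <- mp$post[sample(.N, 5)]
  p_hat <- counterfactual_probability(rows, fits)
  X <- nvhap:::build_design(fits$meta, rows)
  g <- fits$outcome$coef
  g_los <- g[["los"]]
  eta0 <- drop(X %*% g[setdiff(names(g), "los")])
  p1 <- nvhap:::hurdle_p1(fits$los, X)
  mu <- nvhap:::hurdle_mu(fits$los, X)
  B <- 2e5
  for (i in seq_len(5)) {
    one <- rbinom(B, 1, p1[i]) == 1
    los <- ifelse(one, 1, 1 + nvhap:::rztnb(B, mu[i], fits$los$nb$theta))
    # truncation with resampling reproduces the renormalized mass
    while (any(bad <- los > fits$l_max)) {
      nb <- sum(bad)
      one_b <- rbinom(nb, 1, p1[i]) == 1
      los[bad] <- ifelse(one_b, 1,
                         1 + nvhap:::rztnb(nb, mu[i], fits$los$nb$theta))
    }
    vals <- plogis(eta0[i] + g_los * los)
    expect_within_3se(p_hat[i], mean(vals), sd(vals) / sqrt(B))
  }
})

test_that("pooling reproduces the fixed-effect closed forms", {
  rd <- c(0.01, -0.02, 0.005, 0.012)
  # equal variances, diagonal: simple mean and sigma^2/K
  s2 <- 4e-4
  pl <- pool(rd, diag(s2, 4))
  expect_equal(pl$rd, mean(rd), tolerance = 1e-12)
  expect_equal(pl$se^2, s2 / 4, tolerance = 1e-12)
  expect_equal(pl$weights, rep(0.25, 4), tolerance = 1e-12)
  # unequal variances, diagonal: textbook inverse-variance formula
  v <- c(1e-4, 4e-4, 2.5e-4, 9e-4)
  pl2 <- pool(rd, diag(v))
  expect_equal(pl2$rd, sum(rd / v) / sum(1 / v), tolerance = 1e-12)
  expect_equal(pl2$se^2, 1 / sum(1 / v), tolerance = 1e-12)
  # equicorrelation inflates the pooled variance by 1 + (K-1) rho
  rho <- 0.3
  Sig <- s2 * (diag(4) * (1 - rho) + rho)
  pl3 <- pool(rd, Sig)
  expect_equal(pl3$se^2, (s2 / 4) * (1 + 3 * rho), tolerance = 1e-12)
  expect_equal(pl3$ci95, pl3$rd + c(-1, 1) * 1.959964 * pl3$se,
               tolerance = 1e-10)
  expect_error(pool(rd[1], Sig[1, 1, drop = FALSE]), "two sites")
  expect_error(pool(rd, diag(c(1, -1, 1, 1))), "variance")
})

test_that("unadjusted differences equal direct arithmetic", {
  pre <- data.table(site = rep(1:2, c(100, 200)))
  post <- data.table(site = rep(1:2, c(120, 180)))
  y_pre <- c(rep(1, 5), rep(0, 95), rep(1, 8), rep(0, 192))
  y_post <- c(rep(1, 9), rep(0, 111), rep(1, 6), rep(0, 174))
  ud <- unadjusted_differences(pre, post, y_pre, y_post, "binary")
  expect_equal(ud$sites$diff,
               c(9 / 120 - 5 / 100, 6 / 180 - 8 / 200), tolerance = 1e-12)
  p1 <- 5 / 100; p2 <- 9 / 120
  expect_equal(ud$sites$se[1],
               sqrt(p1 * (1 - p1) / 100 + p2 * (1 - p2) / 120),
               tolerance = 1e-12)
  # pooled with diagonal covariance matches pool() directly
  ref <- pool(ud$sites$diff, diag(ud$sites$se^2, 2))
  expect_equal(ud$pooled$rd, ref$rd, tolerance = 1e-12)
  expect_equal(ud$pooled$se, ref$se, tolerance = 1e-12)
})

test_that("site covariance has the stated structure", {
  cfg <- scaled_study_config(pps = 8)
  co <- generate_cohort(cfg, seed = 31, include_clinical = FALSE,
                        include_truth_cf = FALSE)
  eff <- scaled_evaluate(co, cfg)
  K <- nrow(eff$sites)
  expect_equal(dim(eff$Sigma), c(K, K))
  expect_equal(eff$Sigma, t(eff$Sigma), tolerance = 1e-12)
  # off-diagonals nonzero: the shared pre-period fits induce correlation
  off <- eff$Sigma[upper.tri(eff$Sigma)]
  expect_true(all(abs(off) > 0))
  C <- cov2cor(eff$Sigma)
  expect_true(all(C >= -1 - 1e-9 & C <= 1 + 1e-9))
  # diagonal = model component + binomial component (stabilized)
  binom <- eff$sites$counterfactual * (1 - eff$sites$counterfactual) /
    eff$sites$n_post
  expect_equal(eff$sites$se^2, eff$sites$se_model^2 + binom,
               tolerance = 1e-10)
  # risks and weights are valid
  expect_true(all(eff$sites$actual >= 0 & eff$sites$actual <= 1))
  expect_true(all(eff$sites$counterfactual >= 0 &
                    eff$sites$counterfactual <= 1))
  expect_equal(sum(eff$pooled$weights), 1, tolerance = 1e-12)
  expect_true(all(eff$pooled$weights >= 0))
})

test_that("a null cohort yields a null pooled effect on every outcome", {
  cfg <- scaled_study_config(pps = 10)
  co <- generate_cohort(cfg, seed = 55, include_clinical = FALSE,
                        include_truth_cf = FALSE)
  eff <- scaled_evaluate(co, cfg)
  expect_within_3se(eff$pooled$rd, 0, eff$pooled$se)
  # risk differences are probabilities; percentage-point conversion
  expect_true(abs(eff$pooled$rd) < 1)
  expect_equal(nvhap:::as_pct(eff$pooled$rd), 100 * eff$pooled$rd)

  pp <- prepost_config(cfg$implementation_dates)
  mort <- evaluate_effect(co, pp, "death30",
                          covariates = names(cfg$covariate_prevalences),
                          use_site = FALSE, use_year = FALSE,
                          stabilize_binomial = TRUE)
  expect_within_3se(mort$pooled$rd, 0, mort$pooled$se)
  los <- evaluate_effect(co, pp, "los",
                         covariates = names(cfg$covariate_prevalences),
                         use_site = FALSE, use_year = FALSE)
  expect_within_3se(los$pooled$rd, 0, los$pooled$se)
})

test_that("permuting row order leaves the pre-period fits unchanged", {
  mp <- make_prefits()
  set.seed(10)
  shuffled <- mp$pre[sample(.N)]
  f2 <- fit_pre_models(shuffled, y = shuffled$y,
                       covariates = mp$fits$meta$covariates,
                       use_site = FALSE, use_year = FALSE)
  expect_equal(f2$outcome$coef, mp$fits$outcome$coef, tolerance = 1e-6)
  expect_equal(f2$los$nb$coef, mp$fits$los$nb$coef, tolerance = 1e-6)
})
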