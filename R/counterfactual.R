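# Counterfactual pre/post evaluation.
#
# For each site, the year after its implementation date is compared with
# what the year before predicts: models for (1) length of stay (hurdle-NB)
# and (2) the outcome given length of stay (logistic), both fitted on
# pre-implementation data with site, calendar and patient covariates, are
# combined by the law of total probability into a per-patient
# counterfactual event probability, averaged within site, and contrasted
# with the site's actual post-implementation risk.  Site-specific risk
# differences share the two pre-period fits, so their covariance (delta
# method over the stacked parameter vector) has nonzero off-diagonals; the
# pooled estimate uses classic inverse-variance weights with the full
# covariance entering the pooled variance.

#' Pre/post analysis configuration
#'
#' @param implementation_dates per-site roll-out start dates, indexable by
#'   the site codes of the hospitalization table.
#' @param window_days window length on each side of the boundary.
#' @param date_shift `"none"`, `"minus_3_months"` (boundary moved 91 days
#'   earlier, for anticipatory effects) or `"completion"` (boundary at
#'   `completion_dates`, for delayed effects).
#' @param completion_dates per-site roll-out completion dates (required
#'   for `date_shift = "completion"`).
#' @param subgroup `"all"` or `"non_icu_only"` (restrict to admissions
#'   with `icu_ward == 0`).
#' @param lmax_quantile,lmax_cap length-of-stay truncation for the
#'   standardization sum: `L_max` is the `lmax_quantile` quantile of
#'   pre-period LOS, capped at `lmax_cap` days; the truncated hurdle-NB
#'   mass is renormalized over `1..L_max`.
#' @return list of class `nvhap_prepost_config`.
#' @export
prepost_config <- function(implementation_dates,
                           window_days = 365L,
                           date_shift = c("none", "minus_3_months",
                                          "completion"),
                           completion_dates = NULL,
                           subgroup = c("all", "non_icu_only"),
                           lmax_quantile = 0.999,
                           lmax_cap = 120L) {
  date_shift <- match.arg(date_shift)
  subgroup <- match.arg(subgroup)
  if (date_shift == "completion" && is.null(completion_dates))
    stop("completion_dates are required for date_shift = 'completion'")
  cfg <- list(implementation_dates = as.Date(implementation_dates),
              window_days = as.integer(window_days),
              date_shift = date_shift,
              completion_dates = if (is.null(completion_dates)) NULL
              else as.Date(completion_dates),
              subgroup = subgroup,
              lmax_quantile = lmax_quantile,
              lmax_cap = as.integer(lmax_cap))
  class(cfg) <- "nvhap_prepost_config"
  cfg
}

site_boundaries <- function(config, sites) {
  base <- switch(config$date_shift,
                 none = config$implementation_dates,
                 minus_3_months = config$implementation_dates - 91L,
                 completion = config$completion_dates)
  b <- base[sites]
  if (any(is.na(b)))
    stop("missing implementation date for site(s): ",
         paste(unique(sites[is.na(b)]), collapse = ", "))
  b
}

#' Split hospitalizations into pre- and post-implementation windows
#'
#' Windows are half-open: pre is `[boundary - window, boundary)` and post
#' is `[boundary, boundary + window)`, so an admission exactly on the
#' boundary date is post.
#'
#' @param hospitalizations hospitalization table (or `nvhap_cohort`).
#' @param config a [prepost_config()] object.
#' @return list of `data.table`s `pre` and `post`.
#' @export
split_pre_post <- function(hospitalizations, config) {
  if (inherits(hospitalizations, "nvhap_cohort"))
    hospitalizations <- hospitalizations$hospitalizations
  h <- as.data.table(hospitalizations)
  b <- site_boundaries(config, h$site)
  w <- config$window_days
  pre <- h[admit_date >= b - w & admit_date < b]
  post <- h[admit_date >= b & admit_date < b + w]
  if (config$subgroup == "non_icu_only") {
    pre <- pre[icu_ward == 0L]
    post <- post[icu_ward == 0L]
  }
  list(pre = pre, post = post)
}

# ---- design handling ------------------------------------------------------

# Calendar covariates: continuous calendar-year term (extrapolates linearly
# into the post year) and one annual sine/cosine harmonic for week of year.
make_design_meta <- function(data, covariates, use_site = TRUE,
                             use_year = TRUE, use_season = TRUE,
                             ref_date = min(data$admit_date)) {
  sites <- sort(unique(as.character(data$site)))
  list(covariates = covariates,
       use_site = use_site && length(sites) > 1L,
       use_year = use_year, use_season = use_season,
       sites = sites, ref_date = as.Date(ref_date))
}

build_design <- function(meta, data) {
  n <- nrow(data)
  cols <- list("(Intercept)" = rep(1, n))
  if (meta$use_site) {
    for (s in meta$sites[-1L])
      cols[[paste0("site_", s)]] <- as.numeric(as.character(data$site) == s)
  }
  if (meta$use_year)
    cols$year_c <- years_since(data$admit_date, meta$ref_date)
  if (meta$use_season) {
    ang <- 2 * pi * (as.POSIXlt(data$admit_date)$yday / 365.25)
    cols$woy_sin <- sin(ang)
    cols$woy_cos <- cos(ang)
  }
  for (v in meta$covariates) cols[[v]] <- as.numeric(data[[v]])
  do.call(cbind, cols)
}

#' Fit the two pre-period models used for standardization
#'
#' Model (1): hurdle-NB for length of stay given site, calendar year,
#' week-of-year harmonics and patient covariates.  Model (2): logistic for
#' the outcome given length of stay and the same design (omitted when
#' `include_los = FALSE`, as for 30-day mortality where length of stay is
#' not treated as a mediator).
#'
#' @param pre pre-period hospitalization table.
#' @param y 0/1 outcome aligned with `pre` rows (ignored for
#'   `fit_outcome = FALSE`).
#' @param covariates names of binary covariate columns to adjust for.
#' @param include_los should the outcome model condition on length of
#'   stay (standardization over the LOS distribution)?
#' @param fit_outcome fit model (2) at all? (`FALSE` for the LOS secondary
#'   outcome, which only needs model (1).)
#' @param use_site,use_year,use_season design switches.
#' @param config a [prepost_config()] (supplies the L_max rule).
#' @return object of class `nvhap_prefits`.
#' @export
fit_pre_models <- function(pre, y = NULL, covariates = character(),
                           include_los = TRUE, fit_outcome = TRUE,
                           use_site = TRUE, use_year = TRUE,
                           use_season = TRUE,
                           config = NULL) {
  pre <- as.data.table(pre)
  meta <- make_design_meta(pre, covariates, use_site, use_year, use_season)
  X <- build_design(meta, pre)
  qd <- qr(X)
  if (qd$rank < ncol(X))
    stop("rank-deficient pre-period design; collinear columns: ",
         paste(colnames(X)[qd$pivot[-seq_len(qd$rank)]], collapse = ", "))
  los_fit <- fit_hurdle_los(pre$los, X)
  outcome <- NULL
  if (fit_outcome) {
    if (is.null(y)) stop("outcome vector y is required")
    y <- as.integer(y)
    if (length(unique(y)) < 2L)
      stop("pre-period outcome has a single level")
    Xo <- if (include_los) cbind(X, los = as.numeric(pre$los)) else X
    ofit <- glm.fit(Xo, y, family = binomial())
    w <- ofit$weights
    ovc <- chol2inv(chol(crossprod(Xo * sqrt(w))))
    outcome <- list(coef = setNames(ofit$coefficients, colnames(Xo)),
                    vcov = ovc, include_los = include_los)
  }
  lmax <- if (is.null(config)) {
    min(120L, max(2L, as.integer(quantile(pre$los, 0.999))))
  } else {
    min(config$lmax_cap,
        max(2L, as.integer(quantile(pre$los, config$lmax_quantile))))
  }
  out <- list(los = los_fit, outcome = outcome, meta = meta,
              l_max = lmax, n_pre = nrow(pre))
  class(out) <- "nvhap_prefits"
  out
}

#' Counterfactual outcome probability for new patients
#'
#' For each row, `sum_l P(LOS = l | x) * P(event | LOS = l, x)` over
#' `l = 1..l_max` with the truncated hurdle-NB mass renormalized -- the
#' law of total probability applied to the two pre-period fits.  When the
#' outcome model does not condition on LOS the sum collapses to the
#' logistic prediction.
#'
#' @param newdata hospitalization rows conforming to the recorded design.
#' @param fits an `nvhap_prefits` object.
#' @param l_max LOS truncation (defaults to the value recorded at fit
#'   time).
#' @return probabilities in `[0, 1]`.
#' @export
counterfactual_probability <- function(newdata, fits, l_max = fits$l_max) {
  if (l_max < 1) stop("l_max must be >= 1")
  X <- build_design(fits$meta, as.data.table(newdata))
  if (!fits$outcome$include_los)
    return(plogis(drop(X %*% fits$outcome$coef)))
  M <- hurdle_los_mass(fits$los, X, l_max)
  g <- fits$outcome$coef
  g_los <- g[["los"]]
  eta0 <- drop(X %*% g[setdiff(names(g), "los")])
  P <- plogis(outer(eta0, g_los * seq_len(l_max), `+`))
  rowSums(M * P)
}

# ---- delta-method covariance ---------------------------------------------

# Stacked parameter vector layout for a given estimand type:
#   risk_los : (hurdle coef | nb coef, log theta | outcome coef)
#   risk     : (outcome coef)
#   mean_los : (hurdle coef | nb coef, log theta)
stacked_theta <- function(fits, type) {
  switch(type,
    risk_los = c(fits$los$hurdle$coef, fits$los$nb$coef,
                 fits$los$nb$log_theta, fits$outcome$coef),
    risk = fits$outcome$coef,
    mean_los = c(fits$los$hurdle$coef, fits$los$nb$coef,
                 fits$los$nb$log_theta))
}

stacked_vcov <- function(fits, type) {
  switch(type,
    risk_los = Matrix_bdiag(list(fits$los$hurdle$vcov, fits$los$nb$vcov,
                                 fits$outcome$vcov)),
    risk = as.matrix(fits$outcome$vcov),
    mean_los = Matrix_bdiag(list(fits$los$hurdle$vcov, fits$los$nb$vcov)))
}

# Site-level standardized estimates and their gradient with respect to the
# stacked parameters, by forward finite differences (relative step 1e-5).
# Works on the full post table at once: each perturbation yields a
# per-patient value vector whose site means are taken by grouped sums.
# Perturbations recompute only the affected factor: hurdle coefficients
# reweight the cached truncated-NB mass, count parameters rebuild it, and
# outcome coefficients shift the cached linear predictor.
site_standardized <- function(post, site, fits, type) {
  site <- factor(site)
  n_k <- as.numeric(table(site))
  K <- nlevels(site)
  lmax <- fits$l_max
  th_nb <- fits$los$nb$theta
  p_h <- length(fits$los$hurdle$coef)
  p_b <- length(fits$los$nb$coef)
  theta <- stacked_theta(fits, type)
  G <- matrix(0, K, length(theta))
  fd <- function(x) 1e-5 * max(1, abs(x))
  X <- build_design(fits$meta, post)
  smean <- function(v) rowsum(v, site)[, 1L] / n_k

  if (type == "risk") {
    g <- fits$outcome$coef
    eta <- drop(X %*% g)
    m0 <- smean(plogis(eta))
    for (j in seq_along(g)) {
      h <- fd(g[j])
      G[, j] <- (smean(plogis(eta + h * X[, j])) - m0) / h
    }
    return(list(estimate = m0, gradient = G))
  }

  eta_h <- drop(X %*% fits$los$hurdle$coef)
  eta_mu <- drop(X %*% fits$los$nb$coef)
  p1 <- plogis(eta_h)
  mu <- exp(eta_mu)
  ztnb_mass <- function(mu, th) {
    p0 <- (th / (th + mu))^th
    nb_pmf_cols(mu, th, lmax - 1L) / (1 - p0)
  }
  Q <- if (type == "mean_los") NULL else ztnb_mass(mu, th_nb)

  if (type == "mean_los") {
    lmean <- function(p1, mu, th) {
      p0 <- (th / (th + mu))^th
      p1 + (1 - p1) * (1 + mu / (1 - p0))
    }
    m0 <- smean(lmean(p1, mu, th_nb))
    for (j in seq_len(p_h)) {
      h <- fd(theta[j])
      G[, j] <- (smean(lmean(plogis(eta_h + h * X[, j]), mu, th_nb)) -
                   m0) / h
    }
    for (j in seq_len(p_b)) {
      h <- fd(theta[p_h + j])
      G[, p_h + j] <- (smean(lmean(p1, exp(eta_mu + h * X[, j]),
                                   th_nb)) - m0) / h
    }
    h <- fd(theta[p_h + p_b + 1L])
    G[, p_h + p_b + 1L] <-
      (smean(lmean(p1, mu, exp(fits$los$nb$log_theta + h))) - m0) / h
    return(list(estimate = m0, gradient = G))
  }

  # type == "risk_los".  The standardized value for patient i is
  #   [p1 * P(e|l=1) + (1 - p1) * sum_{l>=2} Q_l P(e|l)] /
  #   [p1 + (1 - p1) * sum_{l>=2} Q_l]
  # (the truncated-mass renormalization).  Caching the truncated-NB mass
  # row sums and the outcome-probability contractions makes the hurdle
  # perturbations O(n) and the others one matrix pass each.
  g <- fits$outcome$coef
  g_los <- g[["los"]]
  eta0 <- drop(X %*% g[setdiff(names(g), "los")])
  E <- outer(eta0, g_los * seq_len(lmax), `+`)
  P <- plogis(E)
  P1 <- P[, 1L]
  Ptail <- P[, -1L, drop = FALSE]
  q <- rowSums(Q)
  A <- rowSums(Q * Ptail)
  val <- function(p1, P1, A, q)
    (p1 * P1 + (1 - p1) * A) / (p1 + (1 - p1) * q)
  m0 <- smean(val(p1, P1, A, q))
  off <- 0L
  for (j in seq_len(p_h)) {                      # hurdle coefficients
    h <- fd(theta[off + j])
    p1p <- plogis(eta_h + h * X[, j])
    G[, off + j] <- (smean(val(p1p, P1, A, q)) - m0) / h
  }
  off <- p_h
  for (j in seq_len(p_b)) {                      # NB mean coefficients
    h <- fd(theta[off + j])
    Qp <- ztnb_mass(exp(eta_mu + h * X[, j]), th_nb)
    G[, off + j] <- (smean(val(p1, P1, rowSums(Qp * Ptail),
                               rowSums(Qp))) - m0) / h
  }
  off <- p_h + p_b
  h <- fd(theta[off + 1L])                       # log dispersion
  Qp <- ztnb_mass(mu, exp(fits$los$nb$log_theta + h))
  G[, off + 1L] <- (smean(val(p1, P1, rowSums(Qp * Ptail),
                              rowSums(Qp))) - m0) / h
  off <- p_h + p_b + 1L
  gn <- names(g)
  for (j in seq_along(g)) {                      # outcome coefficients
    h <- fd(theta[off + j])
    Pp <- if (gn[j] == "los")
      plogis(E + rep(h * seq_len(lmax), each = nrow(X)))
    else plogis(E + h * X[, gn[j]])
    G[, off + j] <- (smean(val(p1, Pp[, 1L],
                               rowSums(Q * Pp[, -1L, drop = FALSE]),
                               q)) - m0) / h
  }
  list(estimate = m0, gradient = G)
}

#' Delta-method covariance of site-specific risk differences
#'
#' `Sigma[i, j] = g_i' V g_j` for `i != j` and `Sigma[i, i] = g_i' V g_i +
#' v_i`, where `g_i` is the forward-finite-difference gradient of site
#' `i`'s counterfactual estimate with respect to the stacked pre-period
#' parameters, `V` is block-diagonal over the component fits (the fits
#' are treated as independent), and `v_i` is the sampling variance of the
#' site's actual outcome (binomial for risks, `var/n` for mean LOS).  The
#' matrix is symmetrized; a tiny negative eigenvalue (deficit below
#' 1e-10 relative) is projected away with a warning, anything worse is an
#' error.
#'
#' @param std result of the internal site standardization (estimates and
#'   gradients).
#' @param fits `nvhap_prefits`.
#' @param type estimand type (`"risk_los"`, `"risk"`, `"mean_los"`).
#' @param actual_var per-site sampling variances of the actual outcome.
#' @return list with `Sigma` (full covariance) and `Sigma_model` (the
#'   shared-fit component only, no actual-outcome variance).
#' @keywords internal
delta_sigma <- function(std, fits, type, actual_var) {
  V <- stacked_vcov(fits, type)
  S_model <- std$gradient %*% V %*% t(std$gradient)
  S_model <- (S_model + t(S_model)) / 2
  S <- S_model + diag(actual_var, nrow(S_model))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1e-300)
  if (min(ev) < -1e-10 * scale)
    stop("site covariance matrix is not positive semidefinite")
  if (min(ev) < 0) {
    warning("projecting site covariance to nearest PSD matrix ",
            "(eigenvalue deficit ", format(min(ev)), ")")
    ed <- eigen(S, symmetric = TRUE)
    S <- ed$vectors %*% diag(pmax(ed$values, 0)) %*% t(ed$vectors)
    S <- (S + t(S)) / 2
  }
  list(Sigma = S, Sigma_model = S_model)
}

#' Pool site-specific risk differences with inverse-variance weights
#'
#' Weights are the classic inverse marginal variances,
#' `w_i = (1/Sigma_ii) / sum_j (1/Sigma_jj)`; the pooled variance is
#' `w' Sigma w`, so the correlation of site estimates induced by the
#' shared pre-period fits widens (or narrows) the pooled interval.
#'
#' @param rd site-specific risk differences.
#' @param Sigma their covariance matrix.
#' @return list of class `nvhap_pooled`: `rd`, `se`, `ci95`, `weights`,
#'   `Sigma`.
#' @export
pool <- function(rd, Sigma) {
  rd <- as.numeric(rd)
  Sigma <- as.matrix(Sigma)
  if (length(rd) < 2L) stop("pooling needs at least two sites")
  d <- diag(Sigma)
  if (any(d <= 0)) stop("non-positive site variance in Sigma")
  w <- (1 / d) / sum(1 / d)
  est <- sum(w * rd)
  v <- drop(t(w) %*% Sigma %*% w)
  out <- list(rd = est, se = sqrt(v), ci95 = unname(ci95(est, sqrt(v))),
              weights = w, Sigma = Sigma)
  class(out) <- "nvhap_pooled"
  out
}

#' Crude (unadjusted) pre/post differences by site
#'
#' Post-minus-pre difference of proportions (binary outcomes) or means
#' (length of stay) with standard two-sample errors, pooled with a
#' diagonal covariance.
#'
#' @param pre,post window tables from [split_pre_post()].
#' @param y_pre,y_post outcome values aligned with the window tables.
#' @param type `"binary"` or `"mean"`.
#' @return list with per-site `data.table` and an `nvhap_pooled` estimate.
#' @export
unadjusted_differences <- function(pre, post, y_pre, y_post,
                                   type = c("binary", "mean")) {
  type <- match.arg(type)
  pre <- as.data.table(pre)[, y := as.numeric(y_pre)]
  post <- as.data.table(post)[, y := as.numeric(y_post)]
  agg <- function(d) d[, .(n = .N, m = mean(y), v = var(y)), by = site]
  a <- merge(agg(pre), agg(post), by = "site", suffixes = c("_pre", "_post"))
  empty <- setdiff(union(pre$site, post$site), a$site)
  if (length(empty))
    warning("site(s) with an empty window excluded: ",
            paste(empty, collapse = ", "))
  if (type == "binary") {
    a[, se := sqrt(m_pre * (1 - m_pre) / n_pre +
                     m_post * (1 - m_post) / n_post)]
  } else {
    a[, se := sqrt(v_pre / n_pre + v_post / n_post)]
  }
  a[, diff := m_post - m_pre]
  setorder(a, site)
  pooled <- pool(a$diff, diag(a$se^2, nrow(a)))
  list(sites = a[, .(site, n_pre, n_post, pre = m_pre, post = m_post,
                     diff, se)],
       pooled = pooled)
}

#' Adjusted (counterfactual) pre/post effect for one outcome
#'
#' Runs the full standardization analysis: splits the cohort around each
#' site's boundary date, fits the pre-period models, computes per-site
#' actual and counterfactual estimates for the post period, the
#' delta-method covariance of the site risk differences, and the pooled
#' estimate.  Risk differences follow the convention `actual -
#' counterfactual`, so a protective intervention is negative.
#'
#' @param cohort an `nvhap_cohort` (or a list with a `hospitalizations`
#'   table and, for detector/coding outcomes, the day-level tables).
#' @param config a [prepost_config()].
#' @param outcome one of `"nvhap_electronic"`, `"nvhap_coding"`,
#'   `"nvhap_truth"` (the generator's true event indicator),
#'   `"death30"`, `"los"`.
#' @param covariates covariate columns for the adjustment models; default
#'   uses every generator flag present in the table.
#' @param events optional precomputed [detect_nvhap()] output.
#' @param use_site,use_year,use_season design switches passed to
#'   [fit_pre_models()].
#' @param stabilize_binomial use the model-based (counterfactual) risk in
#'   the binomial variance of each site's actual risk, instead of the
#'   observed proportion.  Recommended when expected events per site are
#'   few (rare outcomes at modest site sizes): the observed-proportion
#'   plug-in makes inverse-variance weights anti-correlated with the site
#'   risk differences and biases the pooled estimate downward.
#' @return list with `sites` (per-site actual, counterfactual, rd, se,
#'   se_model, n_post), `pooled`, `Sigma`, `fits` and the outcome label.
#' @export
evaluate_effect <- function(cohort, config,
                            outcome = c("nvhap_electronic", "nvhap_coding",
                                        "nvhap_truth", "death30", "los"),
                            covariates = NULL, events = NULL,
                            use_site = TRUE, use_year = TRUE,
                            use_season = TRUE, stabilize_binomial = FALSE) {
  outcome <- match.arg(outcome)
  hosp <- as.data.table(cohort$hospitalizations)
  if (is.null(covariates))
    covariates <- intersect(
      c("age_ge75", "male", "copd", "chf", "dementia", "abn_temp",
        "abn_wbc", "hypoxemia", "icu_ward"), names(hosp))
  y_all <- switch(outcome,
    nvhap_electronic = {
      if (is.null(events)) events <- detect_nvhap(cohort)
      event_indicator(hosp, events)
    },
    nvhap_coding = coding_indicator(hosp, classify_coding(cohort)),
    nvhap_truth = {
      tr <- as.data.table(cohort$truth)
      tr[match(hosp$hospitalization_id, hospitalization_id)]$true_event
    },
    death30 = hosp$death30,
    los = hosp$los)
  hosp[, .outcome_y := y_all]
  sp <- split_pre_post(hosp, config)
  pre <- sp$pre; post <- sp$post
  if (nrow(pre) == 0L || nrow(post) == 0L)
    stop("empty pre or post window")
  type <- switch(outcome, death30 = "risk", los = "mean_los", "risk_los")
  fits <- fit_pre_models(pre, y = if (type != "mean_los") pre$.outcome_y,
                         covariates = covariates,
                         include_los = (type == "risk_los"),
                         fit_outcome = (type != "mean_los"),
                         use_site = use_site, use_year = use_year,
                         use_season = use_season, config = config)
  keep_sites <- sort(unique(post$site))
  drop_sites <- setdiff(unique(pre$site), keep_sites)
  if (length(drop_sites))
    warning("site(s) with zero post admissions excluded: ",
            paste(drop_sites, collapse = ", "))
  setorder(post, site)
  site_f <- factor(post$site)
  std <- site_standardized(post, site_f, fits, type)
  agg <- post[, .(n_post = .N, actual = mean(.outcome_y),
                  v = var(.outcome_y)), by = site]
  setorder(agg, site)
  actual <- agg$actual
  n_post <- agg$n_post
  actual_var <- if (type == "mean_los") {
    agg$v / n_post
  } else if (stabilize_binomial) {
    # model-based binomial variance: decouples the inverse-variance
    # weights from each site's own event count, which otherwise biases
    # the pooled estimate when expected events per site are few
    std$estimate * (1 - std$estimate) / n_post
  } else {
    actual * (1 - actual) / n_post
  }
  sig <- delta_sigma(std, fits, type, actual_var)
  rd <- actual - std$estimate
  sites <- data.table(site = as.character(agg$site), n_post = n_post,
                      actual = actual, counterfactual = std$estimate,
                      rd = rd, se = sqrt(diag(sig$Sigma)),
                      se_model = sqrt(pmax(diag(sig$Sigma_model), 0)))
  pooled <- if (length(rd) >= 2L) pool(rd, sig$Sigma) else NULL
  list(outcome = outcome, sites = sites, pooled = pooled,
       Sigma = sig$Sigma, Sigma_model = sig$Sigma_model, fits = fits,
       config = config)
}
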