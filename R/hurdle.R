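# Hurdle model for length of stay.
#
# LOS is a positive integer; the hurdle sits at LOS = 1 (every admission
# spends at least one day).  Component A is a logistic model for
# P(LOS = 1 | x).  Component B models Y = LOS - 1 on stays longer than a
# day as a zero-truncated negative binomial with log-linear mean
# mu(x) = exp(x'beta) and dispersion theta (variance mu + mu^2/theta),
# fitted by maximum likelihood with analytic score.

# log-likelihood and score of the zero-truncated NB; par = (beta, log theta).
# BFGS evaluates the function and gradient at the same point, so the
# shared quantities (mu, theta, zero mass) are memoized on the last par.
ztnb_cache <- function(X) {
  env <- new.env(parent = emptyenv())
  env$par <- NULL
  function(par) {
    if (!identical(par, env$par)) {
      p <- ncol(X)
      # clamp the linear predictors so extreme line-search steps stay finite
      env$mu <- exp(pmin(pmax(drop(X %*% par[1:p]), -30), 30))
      env$th <- exp(pmin(pmax(par[p + 1L], -20), 20))
      env$p0 <- (env$th / (env$th + env$mu))^env$th
      env$par <- c(par)   # copy: the optimizer may reuse its buffer
    }
    env
  }
}

ztnb_negll <- function(par, X, y, cache = NULL) {
  if (is.null(cache)) cache <- ztnb_cache(X)
  e <- cache(par)
  -sum(dnbinom(y, size = e$th, mu = e$mu, log = TRUE) - log1p(-e$p0))
}

ztnb_neggrad <- function(par, X, y, cache = NULL) {
  if (is.null(cache)) cache <- ztnb_cache(X)
  e <- cache(par)
  mu <- e$mu; th <- e$th; p0 <- e$p0
  one_m_p0 <- 1 - p0
  # d ll / d eta (log-link)
  dldeta <- y - mu * (y + th) / (mu + th) -
    th * mu * p0 / ((th + mu) * one_m_p0)
  gb <- drop(crossprod(X, dldeta))
  dldth <- digamma(y + th) - digamma(th) + log(th) + 1 -
    log(th + mu) - (th + y) / (th + mu) +
    p0 * (log(th) - log(th + mu) + 1 - th / (th + mu)) / one_m_p0
  c(gb, th * sum(dldth)) * -1
}

# Fit the zero-truncated NB regression for y >= 1 on design X.
fit_ztnb <- function(y, X) {
  stopifnot(all(y >= 1))
  p <- ncol(X)
  m <- mean(y); v <- var(y)
  th0 <- if (is.na(v) || v <= m) 10 else min(max(m^2 / (v - m), 0.05), 50)
  # Poisson warm start for the mean coefficients
  b0 <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = stats::poisson())$coefficients),
    error = function(e) c(log(m), rep(0, p - 1L)))
  if (any(!is.finite(b0))) b0 <- c(log(m), rep(0, p - 1L))
  start <- c(b0, log(th0))
  cache <- ztnb_cache(X)
  fit <- optim(start, ztnb_negll, ztnb_neggrad, X = X, y = y,
               cache = cache, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  if (fit$convergence != 0) {
    # the iteration cap can trip during a flat terminal zigzag; only a
    # materially nonzero score indicates an actual failure
    gnorm <- max(abs(ztnb_neggrad(fit$par, X, y, cache)))
    if (gnorm > 1e-3 * length(y))
      warning("zero-truncated NB fit did not converge (code ",
              fit$convergence, ", max |score| ", format(gnorm), ")")
  }
  H <- optimHess(fit$par, ztnb_negll, ztnb_neggrad, X = X, y = y,
                 cache = cache)
  vc <- tryCatch(solve(H), error = function(e) {
    warning("singular ZTNB information matrix; using pseudo-inverse")
    ev <- eigen(H, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-12
    ev$vectors[, pos, drop = FALSE] %*%
      diag(1 / ev$values[pos], sum(pos)) %*%
      t(ev$vectors[, pos, drop = FALSE])
  })
  list(coef = fit$par[1:p], log_theta = fit$par[p + 1L],
       theta = exp(fit$par[p + 1L]), vcov = vc,
       logLik = -fit$value, n = length(y))
}

#' Fit a hurdle negative-binomial model for length of stay
#'
#' @param los positive integer length of stay, one per hospitalization.
#' @param design numeric design matrix (including an intercept column)
#'   shared by both components; defaults to intercept only.
#' @return object of class `nvhap_hurdle`: `hurdle` (logistic coefficients
#'   and covariance for P(LOS = 1)), `nb` (count coefficients, log
#'   dispersion and their joint covariance), and the column names of the
#'   design.
#' @export
fit_hurdle_los <- function(los, design = NULL) {
  los <- as.numeric(los)
  if (any(los < 1)) stop("all LOS must be >= 1 day")
  if (length(unique(los)) == 1L)
    stop("degenerate LOS (all values identical)")
  n <- length(los)
  if (is.null(design))
    design <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  design <- as.matrix(design)
  stopifnot(nrow(design) == n)
  qd <- qr(design)
  if (qd$rank < ncol(design))
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(design)[-seq_len(qd$rank)], collapse = ", "))
  z <- as.integer(los == 1)
  hfit <- glm.fit(design, z, family = binomial())
  w <- hfit$weights
  hvc <- chol2inv(chol(crossprod(design * sqrt(w))))
  long <- los > 1
  if (sum(long) < ncol(design) + 2L)
    stop("too few stays longer than one day to fit the count component")
  nb <- fit_ztnb(los[long] - 1, design[long, , drop = FALSE])
  out <- list(hurdle = list(coef = stats::setNames(hfit$coefficients,
                                                   colnames(design)),
                            vcov = hvc),
              nb = nb, columns = colnames(design), n = n)
  class(out) <- "nvhap_hurdle"
  out
}

# P(LOS = 1 | x) and NB mean mu(x) for new design rows
hurdle_p1 <- function(fit, X) plogis(drop(X %*% fit$hurdle$coef))
hurdle_mu <- function(fit, X) exp(drop(X %*% fit$nb$coef))

# NB pmf columns y = 1..ymax via the recurrence
# f(y+1) = f(y) * ((y + theta)/(y + 1)) * (mu/(mu + theta)),
# seeded with f(1) = theta * p0 * mu/(mu + theta); one pass, no dnbinom
# sweep per column.
nb_pmf_cols <- function(mu, theta, ymax) {
  q <- mu / (theta + mu)
  p0 <- (1 - q)^theta
  out <- matrix(0, length(mu), ymax)
  f <- theta * p0 * q
  out[, 1L] <- f
  if (ymax >= 2L) {
    for (y in 2:ymax) {
      f <- f * ((y - 1 + theta) / y) * q
      out[, y] <- f
    }
  }
  out
}

#' Probability mass of length of stay under a fitted hurdle model
#'
#' Returns the n x L matrix of P(LOS = l | x) for l = 1..`l_max`,
#' renormalized over that support (the truncated tail mass is folded back
#' proportionally).
#'
#' @param fit an `nvhap_hurdle` object.
#' @param X design rows.
#' @param l_max truncation point (days).
#' @param p1,mu optionally precomputed hurdle probabilities and count
#'   means (used by the delta-method perturbations).
#' @return matrix of probabilities with rows summing to 1.
#' @export
hurdle_los_mass <- function(fit, X, l_max, p1 = NULL, mu = NULL) {
  if (l_max < 1) stop("l_max must be >= 1")
  if (is.null(p1)) p1 <- hurdle_p1(fit, X)
  if (is.null(mu)) mu <- hurdle_mu(fit, X)
  th <- fit$nb$theta
  n <- length(p1)
  M <- matrix(0, n, l_max)
  M[, 1L] <- p1
  if (l_max >= 2L) {
    p0 <- (th / (th + mu))^th
    M[, -1L] <- (1 - p1) * nb_pmf_cols(mu, th, l_max - 1L) / (1 - p0)
  }
  M / rowSums(M)
}

#' Expected length of stay under a fitted hurdle model
#'
#' `E[LOS | x] = p1 + (1 - p1) * (1 + mu / (1 - p0))` where `p0` is the
#' untruncated NB mass at zero, i.e. the hurdle mixture of a one-day stay
#' and `1 +` the zero-truncated NB mean.
#'
#' @param fit an `nvhap_hurdle` object.
#' @param X design rows.
#' @return numeric vector of conditional means (days).
#' @export
hurdle_mean_los <- function(fit, X) {
  p1 <- hurdle_p1(fit, X)
  mu <- hurdle_mu(fit, X)
  th <- fit$nb$theta
  p0 <- (th / (th + mu))^th
  p1 + (1 - p1) * (1 + mu / (1 - p0))
}
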