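#' @import data.table
#' @importFrom stats glm glm.fit binomial plogis qlogis rbinom rpois runif
#'   rnorm dnbinom pnbinom qnbinom optim optimHess coef vcov qnorm sd var
#'   predict as.formula quantile uniroot setNames aggregate poisson
#' @importFrom utils head tail write.csv
NULL

# Derive a reproducible child seed for a named random stream.  Each table /
# stage draws from its own stream so that adding one table does not perturb
# the draws of another.  Kept below 2^31 - 1 (R integers are 32-bit).
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + h * 7919 + 12345) %% 2147483629)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(child_seed(seed, stream))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 95% normal-theory confidence interval
ci95 <- function(est, se) c(lower = est - 1.959964 * se, est + 1.959964 * se)

as_pct <- function(p) 100 * p

stop_if_not_scalar_date <- function(x, what) {
  if (!inherits(x, "Date") || length(x) != 1L || is.na(x))
    stop(what, " must be a single non-missing Date", call. = FALSE)
  invisible(x)
}
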