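#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx binomial coef dnorm fisher.test glm glm.fit lm
#'   lm.fit logLik median pchisq plogis pnorm qchisq qlogis qnorm quantile
#'   rbinom rexp rnorm runif sd t.test uniroot var vcov
#' @importFrom utils read.table write.table head
NULL

## Parameter validation helper: stops with the offending argument name.
check_that <- function(ok, what, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid `%s`: %s", what, msg), call. = FALSE)
  invisible(TRUE)
}

check_number <- function(x, what, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  check_that(is.numeric(x) && length(x) == 1L && is.finite(x), what,
             "must be a single finite number")
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  check_that(lo_ok && hi_ok, what,
             sprintf("must lie in %s%s, %s%s",
                     if (open_lower) "(" else "[", format(lower),
                     format(upper), if (open_upper) ")" else "]"))
  invisible(x)
}

check_count <- function(x, what, min = 1L) {
  check_that(is.numeric(x) && length(x) == 1L && is.finite(x) &&
               x == round(x) && x >= min, what,
             sprintf("must be an integer >= %d", min))
  as.integer(x)
}

## Seeded evaluation that leaves the global RNG state untouched.
with_seed <- function(seed, expr) {
  seed <- check_count(seed, "seed", min = 0L)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Signed Z from a two-sided P, stable for very small P (log scale).
z_from_p <- function(p, sign = 1) {
  stopifnot(all(p > 0))
  qnorm(log(p) - log(2), lower.tail = FALSE, log.p = TRUE) * sign
}

## Two-sided P from Z, on the log scale to avoid underflow to exactly 0.
p_from_z <- function(z) {
  lp <- pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)
  pmin(exp(lp), 1)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
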