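#' Exact two-sample quantile test
#'
#' Nonparametric exact test of whether a quantile (default the median,
#' `q = 0.5`) differs between two samples. The pooled q-th quantile is the
#' order statistic of rank `ceiling(q * N)` of the combined sample; with
#' `T` the number of pooled values at or below it and `A` the number of
#' first-sample values at or below it, `A` follows a hypergeometric
#' distribution under the null of exchangeability (ties count as at-or-
#' below). `alternative = "greater"` tests whether the second sample `y`
#' tends to exceed `x` (large `A`): its p-value is `P(A >= a_obs)`.
#'
#' @param x,y Numeric samples (e.g. daily activity in the closed and open
#'   seasons, zero-activity days already removed).
#' @param q Quantile in (0, 1).
#' @param alternative `"greater"` (y exceeds x), `"less"`, or
#'   `"two_sided"` (twice the smaller one-sided p, capped at 1).
#' @return A `quantile_test` object with fields `q`, `m`, `n`,
#'   `pooled_quantile`, `a_obs`, `t_obs`, `p_value`, `alternative`,
#'   `median_x`, `median_y`.
#' @export
quantile_test <- function(x, y, q = 0.5,
                          alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) abort("Both samples must be non-empty.")
  if (q <= 0 || q >= 1) abort("`q` must be in (0, 1).")
  m <- length(x); n <- length(y); N <- m + n
  pooled <- sort(c(x, y))
  xi <- pooled[ceiling(q * N)]
  t_obs <- sum(pooled <= xi)
  a_obs <- sum(x <= xi)
  # A ~ Hypergeometric: draw m of N labels; T of the N values are <= xi
  p_greater <- stats::phyper(a_obs - 1, t_obs, N - t_obs, m, lower.tail = FALSE)
  p_less <- stats::phyper(a_obs, t_obs, N - t_obs, m)
  p <- switch(alternative,
    greater = p_greater,
    less = p_less,
    two_sided = min(1, 2 * min(p_greater, p_less))
  )
  structure(
    list(q = q, m = m, n = n, pooled_quantile = xi,
         a_obs = a_obs, t_obs = t_obs, p_value = p,
         alternative = alternative,
         median_x = stats::median(x), median_y = stats::median(y)),
    class = "quantile_test"
  )
}

#' @export
print.quantile_test <- function(x, ...) {
  cat("Exact two-sample quantile test\n")
  cat(sprintf("  q = %g, m = %d, n = %d, pooled quantile = %g\n",
              x$q, x$m, x$n, x$pooled_quantile))
  cat(sprintf("  medians: x = %g, y = %g\n", x$median_x, x$median_y))
  cat(sprintf("  alternative: %s; p-value = %g\n", x$alternative, x$p_value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.quantile_test <- function(x, ...) {
  tibble(
    q = x$q, m = x$m, n = x$n,
    pooled_quantile = x$pooled_quantile,
    median_x = x$median_x, median_y = x$median_y,
    a_obs = x$a_obs, t_obs = x$t_obs,
    alternative = x$alternative,
    p.value = x$p_value
  )
}

#' @exportS3Method generics::glance
glance.quantile_test <- function(x, ...) tidy(x)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
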