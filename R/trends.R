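# Trend and association statistics for surveyed-year series. Series are
# unevenly spaced (rice was surveyed only 6 times in 25 years); calendar
# year is always the regressor and unsurveyed years are simply absent.

trend_result <- function(statistic_kind, estimate, p_value, n, method_note,
                         extra = list()) {
  res <- c(list(statistic_kind = statistic_kind, estimate = estimate,
                p_value = p_value, n = n, method_note = method_note), extra)
  class(res) <- "trend_result"
  res
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("%s: estimate = %.4g, two-sided p = %.4g (n = %d, %s)\n",
              x$statistic_kind, x$estimate, x$p_value, x$n, x$method_note))
  invisible(x)
}

as_series <- function(year, value, caller) {
  if (is.null(value)) {
    if (is.data.frame(year) && ncol(year) >= 2) {
      value <- year[[2]]; year <- year[[1]]
    } else {
      stop_config("%s: supply (year, value) vectors or a two-column data frame", caller)
    }
  }
  if (length(year) != length(value)) stop_config("%s: year/value length mismatch", caller)
  keep <- !is.na(year) & !is.na(value)
  year <- year[keep]; value <- value[keep]
  if (length(year) < 3L) stop_data("%s: need at least 3 points, got %d", caller, length(year))
  o <- order(year)
  list(year = year[o], value = value[o])
}

# Null distribution of the Mann-Kendall S statistic for n tie-free
# observations: S = n(n-1)/2 - 2k where k is the number of inversions, and
# the number of permutations of n with k inversions follows the classic
# convolution recurrence (Mahonian numbers). Counts are exact in doubles up
# to n = 10 (10! = 3628800).
mk_s_null_counts <- function(n) {
  counts <- 1
  for (i in 2:n) {
    new_len <- length(counts) + i - 1L
    acc <- numeric(new_len)
    for (j in 0:(i - 1L)) {
      acc[(1L + j):(length(counts) + j)] <-
        acc[(1L + j):(length(counts) + j)] + counts
    }
    counts <- acc
  }
  d0 <- n * (n - 1) / 2
  list(s = d0 - 2 * (seq_along(counts) - 1L), counts = counts,
       total = sum(counts))
}

#' Mann-Kendall test for monotonic trend
#'
#' Computes `S = sum_{i<j} sign(v_j - v_i)` over the year-ordered series and
#' Kendall's tau-b (tie-corrected denominator). The two-sided p-value is
#' exact — from full enumeration of the S null distribution — for tie-free
#' series with `n <= 10`, and otherwise uses the normal approximation with
#' tie-corrected variance and continuity correction.
#'
#' @param year survey years (distinct), or a two-column (year, value) data
#'   frame with `value` omitted.
#' @param value observed values.
#' @return a `trend_result` with `estimate` = tau, plus `s` and (for the
#'   approximate branch) `var_s`.
#' @export
#' @examples
#' mann_kendall(1990:1994, c(1, 3, 2, 5, 7))
mann_kendall <- function(year, value = NULL) {
  ser <- as_series(year, value, "mann_kendall")
  v <- ser$value
  n <- length(v)
  if (anyDuplicated(ser$year)) stop_data("mann_kendall: years must be distinct")

  d <- outer(v, v, "-")               # d[j, i] = v_j - v_i; lower triangle is j > i
  s <- sum(sign(d[lower.tri(d)]))
  d0 <- n * (n - 1) / 2
  tie_sizes <- as.integer(table(v))
  tie_sizes <- tie_sizes[tie_sizes > 1L]
  ty <- sum(tie_sizes * (tie_sizes - 1) / 2)

  if (length(unique(v)) == 1L) {
    return(trend_result("mann_kendall_tau", 0, 1, n,
                        "degenerate: all values identical",
                        extra = list(s = 0)))
  }
  tau <- s / sqrt(d0 * (d0 - ty))

  if (n <= 10L && length(tie_sizes) == 0L) {
    null <- mk_s_null_counts(n)
    p <- min(1, 2 * sum(null$counts[null$s >= abs(s)]) / null$total)
    return(trend_result("mann_kendall_tau", tau, p, n, "exact enumeration",
                        extra = list(s = s)))
  }

  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(tie_sizes * (tie_sizes - 1) * (2 * tie_sizes + 5))) / 18
  z <- if (s == 0) 0 else (s - sign(s)) / sqrt(var_s)
  p <- 2 * pnorm(-abs(z))
  trend_result("mann_kendall_tau", tau, p, n,
               "normal approximation, tie-corrected, continuity-corrected",
               extra = list(s = s, var_s = var_s))
}

#' Ordinary least-squares trend slope
#'
#' Least-squares slope of value on calendar year with the usual two-sided
#' t-test on `n - 2` degrees of freedom.
#'
#' @inheritParams mann_kendall
#' @return a `trend_result` with `estimate` = slope (units of value per
#'   year).
#' @export
ols_slope <- function(year, value = NULL) {
  ser <- as_series(year, value, "ols_slope")
  x <- ser$year; y <- ser$value
  n <- length(x)
  if (length(unique(x)) < 2L) stop_data("ols_slope: zero variance in year")
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  fitted <- mean(y) + slope * (x - mean(x))
  rss <- sum((y - fitted)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  if (se == 0) {
    p <- if (slope == 0) 1 else 0
    note <- "degenerate: zero residual variance"
  } else {
    p <- 2 * pt(-abs(slope / se), df = n - 2)
    note <- "t-test, n-2 df"
  }
  trend_result("ols_slope", slope, p, n, note, extra = list(std_error = se))
}

#' Pearson correlation with t-transform p-value
#'
#' @param x,y numeric vectors of equal length (`n >= 3`), both nonconstant.
#' @return a `trend_result` with `estimate` = r.
#' @export
pearson_correlation <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) != length(y)) stop_config("pearson_correlation: length mismatch")
  n <- length(x)
  if (n < 3L) stop_data("pearson_correlation: need at least 3 points, got %d", n)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop_data("pearson_correlation: constant vector")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
  trend_result("pearson_r", r, p, n, "t-transform, n-2 df")
}
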