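#' Bland-Altman agreement analysis
#'
#' Classic Bland-Altman comparison of a test method against a reference:
#' bias is the mean of the pairwise differences (test - reference) and the
#' limits of agreement are bias +/- 1.96 times their sample standard
#' deviation (n - 1 denominator).  Spearman's rank correlation between the
#' two series is reported alongside when at least three pairs with rank
#' variance are available.
#'
#' @param test,reference numeric vectors of equal length (n >= 2).
#' @param metric optional metric name carried into the result.
#' @param loa_multiplier multiplier for the limits of agreement; 1.96 for
#'   the classic 95% limits.
#' @return An object of class \code{agreement_result}: list with
#'   \code{metric}, \code{n}, \code{bias}, \code{sd_diff}, \code{loa_low},
#'   \code{loa_high}, \code{rho}.
#' @examples
#' bland_altman(c(10, 12, 9), c(10, 11, 10))
#' @export
bland_altman <- function(test, reference, metric = NA_character_,
                         loa_multiplier = 1.96) {
  if (length(test) != length(reference))
    stop_lq("alignment_error", "test and reference must have equal length")
  n <- length(test)
  if (n < 2L)
    stop_lq("insufficient_data_error", "Bland-Altman needs at least two pairs")
  d <- test - reference
  bias <- mean(d)
  sd_diff <- sd(d)
  rho <- if (n >= 3L && length(unique(test)) > 1L &&
             length(unique(reference)) > 1L)
    spearman_rho(test, reference) else NA_real_
  structure(list(metric = metric, n = n, bias = bias, sd_diff = sd_diff,
                 loa_low = bias - loa_multiplier * sd_diff,
                 loa_high = bias + loa_multiplier * sd_diff,
                 rho = rho),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("agreement (%s): n=%d bias=%.4g LOA (%.4g, %.4g) rho=%.3f\n",
              ifelse(is.na(x$metric), "unnamed", x$metric),
              x$n, x$bias, x$loa_low, x$loa_high, x$rho))
  invisible(x)
}

#' @export
as.data.frame.agreement_result <- function(x, ...) {
  data.frame(metric = x$metric, n = x$n, bias = x$bias, sd_diff = x$sd_diff,
             loa_low = x$loa_low, loa_high = x$loa_high, rho = x$rho)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked data; ties receive average ranks.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return Spearman's rho in [-1, 1].
#' @examples
#' spearman_rho(1:4, c(1, 3, 2, 4))  # 0.8
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop_lq("alignment_error", "x and y must have equal length")
  if (length(x) < 3L)
    stop_lq("insufficient_data_error", "Spearman correlation needs n >= 3")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0)
    stop_lq("undefined_correlation_error",
            "rank variance is zero; correlation undefined")
  cor(rx, ry)
}

#' Median and interquartile range
#'
#' Linear-interpolation (type-7) quantiles, the convention used for the
#' median (IQR) summaries throughout the package.
#'
#' @param values numeric vector, n >= 1.
#' @param type quantile type passed to [stats::quantile()].
#' @return Named numeric vector \code{c(median, q1, q3)}.
#' @examples
#' median_iqr(c(1, 2, 3))  # 2, 1.5, 2.5
#' @export
median_iqr <- function(values, type = 7) {
  if (length(values) < 1L)
    stop_lq("insufficient_data_error", "need at least one value")
  q <- quantile(values, probs = c(0.5, 0.25, 0.75), type = type, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}
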