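# Method-comparison statistics: Pearson / Spearman correlation and
# Bland-Altman agreement, the analysis surface used to validate the direct
# flow measurements against aortic flow and planimetry.

#' Correlation between two measurement series
#'
#' Pearson product-moment or Spearman rank correlation (average ranks for
#' ties) with a two-sided p-value from the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `coefficient`, `p_value`, `n`, `method`.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in input; correlation undefined")
  }
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(coefficient = r, p_value = p, n = n, method = method)
}

#' Bland-Altman agreement between two measurement methods
#'
#' Differences `d = x - y`; reports their mean (bias), SD (n-1 denominator),
#' 95% limits of agreement `mean +/- 1.96 * SD` (no small-sample t
#' correction, following the original method), and the paired-t p-value for
#' zero mean difference.
#'
#' @param x,y paired measurements (same units), n >= 2.
#' @return An `agreement_result` list: `n`, `mean_difference`,
#'   `sd_difference`, `loa_lower`, `loa_upper`, `p_value`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  p <- if (s == 0) {
    if (abs(m) < .Machine$double.eps^0.5) 1 else 0
  } else {
    stats::t.test(d)$p.value
  }
  structure(list(n = n, mean_difference = m, sd_difference = s,
                 loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
                 p_value = p),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> n = %d\n", x$n))
  cat(sprintf("  mean difference %.3f +/- %.3f (p = %.3g)\n",
              x$mean_difference, x$sd_difference, x$p_value))
  cat(sprintf("  95%% limits of agreement [%.3f; %.3f]\n",
              x$loa_lower, x$loa_upper))
  invisible(x)
}
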