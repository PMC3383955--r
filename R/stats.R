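#' @include AllClasses.R
NULL

#' Simple ordinary least squares
#'
#' Closed-form simple linear regression of \code{y} on \code{x}:
#' \code{slope = Sxy / Sxx}, \code{intercept = mean(y) - slope * mean(x)},
#' with \code{F = (r2 / (1 - r2)) * dfDen} on \code{(1, n - 2)} degrees of
#' freedom and the upper-tail F probability as p-value.
#'
#' @param x predictor values, at least 3, not all equal.
#' @param y response values, same length as \code{x}.
#' @param predictor name of the predictor (for printing).
#' @return A [RegressionResult-class].
#' @examples
#' olsFit(1:5, 2 * (1:5) + 1)  # slope 2, intercept 1, r2 = 1
#' @export
olsFit <- function(x, y, predictor = "x") {
  if (length(x) != length(y)) stop("olsFit: x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("olsFit: need at least 3 points")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) stop("olsFit: constant predictor")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  ssTot <- sum((y - mean(y))^2)
  ssRes <- sum((y - intercept - slope * x)^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else 1
  r2 <- min(max(r2, 0), 1)
  dfDen <- n - 2
  fStat <- if (r2 < 1) (r2 / (1 - r2)) * dfDen else Inf
  p <- if (is.finite(fStat))
    stats::pf(fStat, 1, dfDen, lower.tail = FALSE) else 0
  p <- max(p, .Machine$double.xmin)   # keep p in (0, 1]
  se <- if (dfDen > 0) sqrt((ssRes / dfDen) / sxx) else NA_real_
  new("RegressionResult", slope = slope, intercept = intercept, r2 = r2,
      fStat = fStat, dfNum = 1, dfDen = dfDen, p = p, n = as.integer(n),
      predictor = predictor, slopeSe = se)
}

#' Two-sided confidence interval for the slope of an OLS fit
#'
#' @param fit a [RegressionResult-class].
#' @param level confidence level (default 0.95).
#' @return Numeric length-2 vector (lower, upper).
#' @export
slopeCI <- function(fit, level = 0.95) {
  stopifnot(is(fit, "RegressionResult"))
  tq <- stats::qt(1 - (1 - level) / 2, fit@dfDen)
  fit@slope + c(-1, 1) * tq * fit@slopeSe
}

#' Paired two-tailed t-test
#'
#' Computes the paired t statistic \code{t = mean(d) / (sd(d) / sqrt(n))}
#' with \code{df = n - 1} for paired arrays (e.g. per-subject mean reaction
#' times for the left and the right hand). A non-zero constant difference
#' (zero within-pair variance) is flagged as degenerate with an infinite t.
#'
#' @param left,right paired numeric vectors, length >= 2.
#' @return List with \code{t}, \code{df}, \code{p}, \code{meanDiff} and
#'   \code{degenerate}.
#' @export
handTTest <- function(left, right) {
  if (length(left) != length(right))
    stop("handTTest: paired arrays must have equal length")
  keep <- is.finite(left) & is.finite(right)
  d <- left[keep] - right[keep]
  n <- length(d)
  if (n < 2L) stop("handTTest: need at least 2 pairs")
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = n - 1, p = 1, meanDiff = 0, degenerate = FALSE))
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                meanDiff = mean(d), degenerate = TRUE))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE),
       meanDiff = mean(d), degenerate = FALSE)
}
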