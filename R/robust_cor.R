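#' Biweight midcorrelation
#'
#' Outlier-resistant correlation. Deviations from the median are scaled
#' by `c * MAD` (tuning constant `c = 9` by convention, MAD unscaled) and
#' down-weighted by Tukey's biweight `(1 - u^2)^2`, with zero weight
#' beyond `|u| >= 1`; the correlation is then computed on the weighted
#' deviations.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param c Tuning constant (default 9).
#' @return List of class `"robust_cor"`: `estimate`, `method`, `tuning`,
#'   `n`.
#' @export
biweight_midcorrelation <- function(x, y, c = 9) {
  check_pair(x, y)
  bw <- function(v) {
    med <- stats::median(v)
    mad0 <- stats::median(abs(v - med))
    if (mad0 == 0)
      stop2("zero median absolute deviation; biweight undefined ",
            "(consider percentage_bend_correlation)")
    u <- (v - med) / (c * mad0)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (v - med) * w
  }
  a <- bw(x)
  b <- bw(y)
  est <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  structure(list(estimate = unname(est), method = "biweight_midcorrelation",
                 tuning = c, n = length(x)), class = "robust_cor")
}

#' Percentage bend correlation
#'
#' Robust correlation that bends (clips) the most extreme `beta` fraction
#' of observations in each margin. Deviations from an M-estimate of
#' location are scaled by the `floor((1 - beta) * n)`-th largest absolute
#' deviation and passed through the clipping psi function
#' `psi(u) = max(-1, min(1, u))`. With `beta = 0` the estimator reduces
#' to the Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param beta Bend fraction in \[0, 0.5) (default 0.2).
#' @return List of class `"robust_cor"`: `estimate`, `method`, `tuning`,
#'   `n`.
#' @export
percentage_bend_correlation <- function(x, y, beta = 0.2) {
  check_pair(x, y)
  if (!is.numeric(beta) || length(beta) != 1 || beta < 0 || beta >= 0.5)
    stop2("beta must be a single value in [0, 0.5)")
  n <- length(x)
  pb <- function(v) {
    w <- sort(abs(v - stats::median(v)))
    m <- floor((1 - beta) * n)
    omega <- w[m]
    if (omega == 0)
      stop2("zero bend scale (too many ties); increase beta or use ",
            "another estimator")
    z <- (v - stats::median(v)) / omega
    i1 <- sum(z < -1)
    i2 <- sum(z > 1)
    # M-estimate of location with the clipped tails pulled to the scale
    loc <- (omega * (i2 - i1) + sum(v[z >= -1 & z <= 1])) / (n - i1 - i2)
    pmin(1, pmax(-1, (v - loc) / omega))
  }
  a <- pb(x)
  b <- pb(y)
  est <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  structure(list(estimate = unname(est), method = "percentage_bend",
                 tuning = beta, n = n), class = "robust_cor")
}

check_pair <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop2("x and y must be numeric")
  if (length(x) != length(y))
    stop2("x and y lengths differ (", length(x), " vs ", length(y), ")")
  if (length(x) < 4) stop2("need at least 4 observations")
  if (anyNA(x) || anyNA(y)) stop2("missing values not supported")
  invisible(NULL)
}

#' @export
print.robust_cor <- function(x, ...) {
  cat(x$method, " (tuning ", x$tuning, ", n = ", x$n, "): r = ",
      format(x$estimate, digits = 4), "\n", sep = "")
  invisible(x)
}
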