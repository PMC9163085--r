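#' Z-score regional activity time-series
#'
#' Standardizes each node's series to zero mean and unit *population*
#' standard deviation (divisor `T`, not `T - 1`). Under this convention the
#' time-average of the edge time-series exactly recovers the Pearson
#' correlation matrix (see [edge_time_series()]).
#'
#' @param activity Numeric node x time matrix (nodes as rows).
#' @return Matrix of the same shape, each row with mean 0 and population
#'   sd 1.
#' @examples
#' z <- zscore_activity(rbind(a = c(1, 2, 3), b = c(5, 1, 0)))
#' rowMeans(z)  # ~ 0
#' @seealso [edge_time_series()], [static_fc()]
#' @export
zscore_activity <- function(activity) {
  check_activity(activity)
  mu <- rowMeans(activity)
  sigma <- sqrt(rowMeans((activity - mu)^2))
  bad <- which(sigma == 0)
  if (length(bad))
    stop2("constant activity series for node(s): ",
          paste(if (is.null(rownames(activity))) bad else
                  rownames(activity)[bad], collapse = ", "))
  (activity - mu) / sigma
}

is_zscored <- function(activity, tol = 1e-6) {
  mu <- rowMeans(activity)
  sigma <- sqrt(rowMeans((activity - mu)^2))
  all(abs(mu) < tol) && all(abs(sigma - 1) < tol)
}

#' Edge time-series (co-fluctuation tensor)
#'
#' Temporal unwrapping of functional connectivity: the co-fluctuation of
#' nodes i and j at frame t is the element-wise product of their z-scored
#' activity, `z[i,t] * z[j,t]`. Node pairs deflecting to the same side of
#' their baseline at frame t get a positive value, pairs deflecting in
#' opposite directions a negative value. Averaging the tensor over time
#' recovers the Pearson correlation (static functional connectivity).
#'
#' The diagonal slice holds each node's squared z-score; downstream
#' operations use off-diagonal entries only.
#'
#' @param z Z-scored node x time activity matrix (see [zscore_activity()];
#'   checked to tolerance 1e-6).
#' @return Numeric node x node x time array, symmetric in its first two
#'   indices at every frame.
#' @export
edge_time_series <- function(z) {
  check_activity(z, "z-scored activity")
  if (!is_zscored(z))
    stop2("input does not look z-scored; call zscore_activity() first")
  n <- nrow(z)
  tt <- ncol(z)
  ets <- array(NA_real_, dim = c(n, n, tt),
               dimnames = list(rownames(z), rownames(z), NULL))
  for (t in seq_len(tt))
    ets[, , t] <- tcrossprod(z[, t])
  ets
}

#' Static functional connectivity
#'
#' Pearson correlation matrix of the regional activity; identical (to
#' numerical precision) to the time-average of [edge_time_series()].
#'
#' @param activity Numeric node x time matrix (raw or z-scored).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
static_fc <- function(activity) {
  check_activity(activity)
  sigma <- apply(activity, 1, stats::sd)
  bad <- which(sigma == 0)
  if (length(bad))
    stop2("constant activity series for node(s): ",
          paste(bad, collapse = ", "))
  fc <- stats::cor(t(activity))
  dimnames(fc) <- list(rownames(activity), rownames(activity))
  fc
}

#' Global co-fluctuation amplitude per frame
#'
#' Root-sum-square of the upper-triangle (off-diagonal) co-fluctuation
#' values at each frame; frames of globally high amplitude correspond to
#' network-wide "events".
#'
#' @param ets Co-fluctuation array from [edge_time_series()].
#' @return Nonnegative numeric vector of length `dim(ets)[3]`.
#' @export
cofluctuation_amplitude <- function(ets) {
  if (!is.array(ets) || length(dim(ets)) != 3 || dim(ets)[1] != dim(ets)[2])
    stop2("ets must be a node x node x time array")
  ut <- upper.tri(matrix(0, dim(ets)[1], dim(ets)[2]))
  apply(ets, 3, function(frame) sqrt(sum(frame[ut]^2)))
}
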