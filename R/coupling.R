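#' Per-node design matrix of structural predictors
#'
#' Rows are all other nodes j != i (ascending), columns are node i's
#' Euclidean distance, shortest path length and communicability to each j,
#' in that fixed order. The intercept is added at fit time.
#'
#' @param predictors A `predictor_set` from [build_predictors()].
#' @param i Node index (1-based).
#' @return `(N-1) x 3` matrix with columns `dist`, `spl`, `cmc`.
#' @export
node_design <- function(predictors, i) {
  n <- nrow(predictors$dist)
  if (!is.numeric(i) || length(i) != 1 || i < 1 || i > n || i != round(i))
    stop2("node index i must be a single integer in 1..", n)
  cbind(dist = predictors$dist[i, -i],
        spl  = predictors$spl[i, -i],
        cmc  = predictors$cmc[i, -i])
}

#' Ordinary least squares fit with adjusted R-squared
#'
#' Fits `response ~ 1 + design` and reports the coefficient of
#' determination and its adjusted version
#' `adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1)`.
#'
#' @param design Numeric matrix of predictors (no intercept column).
#' @param response Numeric vector, `nrow(design)` long.
#' @return List of class `"sfc_fit"`: `beta` (intercept first), `r2`,
#'   `adj_r2`, `n_obs`, `n_pred`.
#' @export
fit_ols <- function(design, response) {
  design <- as.matrix(design)
  if (!is.numeric(design) || !is.numeric(response))
    stop2("design and response must be numeric")
  if (length(response) != nrow(design))
    stop2("response length ", length(response), " != ", nrow(design), " rows")
  if (anyNA(design) || anyNA(response) || any(!is.finite(design)) ||
      any(!is.finite(response)))
    stop2("non-finite values in design or response")
  n <- nrow(design)
  p <- ncol(design)
  if (n <= p + 1)
    stop2("too few observations (", n, ") for ", p, " predictors")
  x <- cbind(`(Intercept)` = 1, design)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped <- setdiff(seq_len(ncol(x)), keep)
    stop2("rank-deficient design; collinear column(s): ",
          paste(colnames(x)[dropped], collapse = ", "))
  }
  tss <- sum((response - mean(response))^2)
  if (tss < 1e-12)
    stop2("response has (near) zero variance; R2 undefined")
  beta <- qr.coef(qx, response)
  rss <- sum(qr.resid(qx, response)^2)
  r2 <- max(0, min(1, 1 - rss / tss))
  structure(list(beta = beta, r2 = r2,
                 adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1),
                 n_obs = n, n_pred = p),
            class = "sfc_fit")
}

#' @export
print.sfc_fit <- function(x, ...) {
  cat("OLS fit:", x$n_obs, "obs,", x$n_pred, "predictors\n")
  print(round(x$beta, 4))
  cat("R2 =", format(x$r2, digits = 4),
      " adjusted R2 =", format(x$adj_r2, digits = 4), "\n")
  invisible(x)
}

# Adjusted R2 of one node's model against many responses at once.
# Shares the QR decomposition across frames; returns NA for frames whose
# response profile is (near) constant, with the count attached.
adj_r2_profile <- function(design, responses) {
  n <- nrow(design)
  p <- ncol(design)
  qx <- qr(cbind(1, design))
  if (qx$rank < p + 1)
    stop2("rank-deficient design in per-frame fit")
  rss <- colSums(qr.resid(qx, responses)^2)
  tss <- colSums(sweep(responses, 2, colMeans(responses))^2)
  degenerate <- tss < 1e-12
  r2 <- pmin(1, pmax(0, 1 - rss / tss))
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  adj[degenerate] <- NA_real_
  attr(adj, "n_degenerate") <- sum(degenerate)
  adj
}

#' Dynamic (time-resolved) structure-function coupling
#'
#' For every node i and frame t, regresses node i's co-fluctuation profile
#' to all other nodes on its structural predictor profile and records the
#' adjusted R-squared. The model is fitted separately for each frame; the
#' result is the node x time coupling matrix at the center of the
#' analysis.
#'
#' Frames whose co-fluctuation profile is (near) constant across j have an
#' undefined R-squared; they are returned as `NA` and counted in the
#' `"n_degenerate"` attribute rather than silently set to 0, which would
#' bias temporal statistics such as cv(R2).
#'
#' @param predictors A `predictor_set` from [build_predictors()].
#' @param ets Co-fluctuation array from [edge_time_series()].
#' @return Node x time matrix of adjusted R-squared values, with attribute
#'   `n_degenerate` (count of skipped frames over all nodes).
#' @export
dynamic_coupling <- function(predictors, ets) {
  n <- nrow(predictors$dist)
  if (!is.array(ets) || length(dim(ets)) != 3)
    stop2("ets must be a node x node x time array")
  if (dim(ets)[1] != n || dim(ets)[2] != n)
    stop2("predictor set (", n, " nodes) and ets (", dim(ets)[1],
          ") disagree")
  tt <- dim(ets)[3]
  out <- matrix(NA_real_, n, tt)
  n_degen <- 0L
  for (i in seq_len(n)) {
    resp <- matrix(ets[i, -i, ], nrow = n - 1L, ncol = tt)
    adj <- adj_r2_profile(node_design(predictors, i), resp)
    n_degen <- n_degen + attr(adj, "n_degenerate")
    out[i, ] <- adj
  }
  attr(out, "n_degenerate") <- n_degen
  out
}

#' Static structure-function coupling
#'
#' The same multilinear model applied without temporal expansion: node i's
#' static functional connectivity profile regressed on its structural
#' predictors, one adjusted R-squared per node.
#'
#' @param predictors A `predictor_set`.
#' @param fc Static functional connectivity matrix ([static_fc()]).
#' @return Numeric vector of length N.
#' @export
static_coupling <- function(predictors, fc) {
  n <- nrow(predictors$dist)
  check_square_symmetric(fc, "fc", tol = 1e-8)
  if (nrow(fc) != n) stop2("fc dimension mismatch")
  vapply(seq_len(n), function(i)
    fit_ols(node_design(predictors, i), fc[i, -i])$adj_r2, numeric(1))
}

#' Spearman rank structure-function coupling
#'
#' The classical alternative coupling estimate: for each node, the
#' Spearman rank correlation between its structural and functional
#' connectivity profiles, restricted to node pairs that share a structural
#' connection (rank correlation is meaningful only where an anatomical
#' weight exists). Ties receive midranks.
#'
#' @param sc Weighted structural connectome.
#' @param fc Static functional connectivity matrix.
#' @return Numeric vector of length N; `NA` (with a warning) for nodes
#'   with fewer than 3 structural connections.
#' @export
spearman_rank_coupling <- function(sc, fc) {
  check_connectome(sc)
  if (!all(dim(sc) == dim(fc))) stop2("sc and fc dimensions disagree")
  n <- nrow(sc)
  out <- rep(NA_real_, n)
  low <- integer(0)
  for (i in seq_len(n)) {
    j <- which(sc[i, ] > 0)
    j <- setdiff(j, i)
    if (length(j) < 3) { low <- c(low, i); next }
    out[i] <- stats::cor(sc[i, j], fc[i, j], method = "spearman")
  }
  if (length(low))
    warning("node(s) with < 3 structural connections left NA: ",
            paste(low, collapse = ", "), call. = FALSE)
  out
}

# R2 (unadjusted) of response on the given predictor columns, intercept
# included; R2 of the empty model is 0 by convention.
subset_r2 <- function(design, response, cols) {
  if (!length(cols)) return(0)
  qx <- qr(cbind(1, design[, cols, drop = FALSE]))
  rss <- sum(qr.resid(qx, response)^2)
  tss <- sum((response - mean(response))^2)
  1 - rss / tss
}

#' Dominance analysis of predictor importance
#'
#' Decomposes the full-model R-squared into per-predictor contributions by
#' refitting the regression on every non-empty predictor subset. The total
#' dominance of predictor p is the average, over subset sizes, of the mean
#' incremental R-squared when p joins each subset that does not contain
#' it. Total dominances sum exactly to the full-model (unadjusted)
#' R-squared.
#'
#' @param design Numeric predictor matrix (no intercept column).
#' @param response Numeric response vector.
#' @return Named numeric vector of total dominance, one per predictor
#'   column, with attribute `full_r2`.
#' @export
dominance_analysis <- function(design, response) {
  design <- as.matrix(design)
  fit_ols(design, response)  # validates dimensions, rank, variance
  p <- ncol(design)
  idx <- seq_len(p)
  # cache R2 of all 2^p subsets, keyed by bitmask
  r2 <- numeric(2^p)
  for (mask in seq_len(2^p - 1))
    r2[mask + 1] <- subset_r2(design, response,
                              idx[bitwAnd(mask, bitwShiftL(1, idx - 1)) > 0])
  total <- numeric(p)
  for (pp in idx) {
    bit <- bitwShiftL(1, pp - 1)
    inc_by_size <- vapply(0:(p - 1), function(k) {
      masks <- Filter(function(m)
        bitwAnd(m, bit) == 0 && sum(bitwAnd(m, bitwShiftL(1, idx - 1)) > 0) == k,
        0:(2^p - 1))
      mean(vapply(masks, function(m)
        r2[bitwOr(m, bit) + 1] - r2[m + 1], numeric(1)))
    }, numeric(1))
    total[pp] <- mean(inc_by_size)
  }
  names(total) <- colnames(design)
  attr(total, "full_r2") <- r2[2^p]
  total
}
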