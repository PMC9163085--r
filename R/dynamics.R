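#' Coefficient of variation of coupling across time
#'
#' `cv_i = sd_t(R2[i, ]) / mean_t(R2[i, ])`, a standardized dispersion
#' measure that lets coupling time-series with different means be
#' compared. The standard deviation uses divisor `n - 1` (sample sd);
#' missing frames (degenerate fits) are excluded.
#'
#' @param coupling Node x time coupling matrix ([dynamic_coupling()]).
#' @return Numeric vector of per-node cv values; `NA` (with a warning)
#'   where the temporal mean is within 1e-8 of zero or fewer than 3
#'   non-missing frames remain.
#' @export
coefficient_of_variation <- function(coupling) {
  if (!is.matrix(coupling)) stop2("coupling must be a node x time matrix")
  out <- apply(coupling, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 3) return(NA_real_)
    m <- mean(x)
    if (abs(m) < 1e-8) return(NA_real_)
    stats::sd(x) / m
  })
  if (anyNA(out))
    warning(sum(is.na(out)),
            " node(s) with near-zero mean or too few frames set to NA",
            call. = FALSE)
  out
}

#' Dynamic-versus-static coupling statistics
#'
#' Frames the comparison of a distribution (dynamic coupling values) with
#' a single observation (static coupling) through three per-node
#' statistics: the probability that a dynamic value exceeds the static
#' one (strict inequality), the bias (median of dynamic minus static),
#' and the variance (spread between the 84th and 16th percentiles of the
#' dynamic values — +/- 1 sd under normality — robust to outliers and
#' skew). Percentiles use linear interpolation between order statistics.
#'
#' @param coupling Node x time dynamic coupling matrix.
#' @param static Per-node static coupling vector.
#' @return Data frame with columns `node`, `prob_greater`, `bias`,
#'   `variance`.
#' @export
dynamic_vs_static <- function(coupling, static) {
  if (!is.matrix(coupling)) stop2("coupling must be a node x time matrix")
  if (length(static) != nrow(coupling))
    stop2("static vector length ", length(static), " != ",
          nrow(coupling), " nodes")
  stats_one <- function(i) {
    x <- coupling[i, ]
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA_real_, NA_real_, NA_real_))
    q <- stats::quantile(x, c(0.16, 0.84), names = FALSE, type = 7)
    c(mean(x > static[i]), stats::median(x) - static[i], q[2] - q[1])
  }
  res <- t(vapply(seq_len(nrow(coupling)), stats_one, numeric(3)))
  data.frame(node = seq_len(nrow(coupling)), prob_greater = res[, 1],
             bias = res[, 2], variance = res[, 3])
}

#' Inter-node coupling similarity
#'
#' Pearson correlation between the coupling time-series of every pair of
#' nodes, averaged across subjects. Node pairs with similar coupling
#' dynamics score high regardless of their mean coupling level.
#'
#' @param coupling_list List of node x time coupling matrices, one per
#'   subject, with identical node sets.
#' @return Symmetric node x node similarity matrix with unit diagonal;
#'   entries involving a constant coupling series are `NA` with a warning.
#' @export
coupling_similarity <- function(coupling_list) {
  if (is.matrix(coupling_list)) coupling_list <- list(coupling_list)
  if (!length(coupling_list)) stop2("need at least one subject")
  n <- nrow(coupling_list[[1]])
  if (!all(vapply(coupling_list, nrow, integer(1)) == n))
    stop2("subjects have inconsistent node counts")
  sims <- lapply(coupling_list, function(cm) {
    const <- apply(cm, 1, function(x) stats::sd(x, na.rm = TRUE) == 0)
    if (any(const))
      warning("constant coupling series for node(s): ",
              paste(which(const), collapse = ", "), call. = FALSE)
    suppressWarnings(s <- stats::cor(t(cm), use = "pairwise.complete.obs"))
    s[const, ] <- NA_real_
    s[, const] <- NA_real_
    diag(s) <- 1
    s
  })
  Reduce(`+`, sims) / length(sims)
}

#' Mean connectivity distance per node
#'
#' Average Euclidean distance from a node to its structurally connected
#' neighbors — a summary of the connection-length distribution a region
#' participates in. The default is an unweighted mean over existing
#' connections; `weighted = TRUE` weights each neighbor's distance by the
#' connection weight.
#'
#' @param sc Weighted structural connectome.
#' @param dist Euclidean distance matrix ([euclidean_distance()]).
#' @param weighted Logical; weight distances by connection strength.
#' @return Numeric vector of length N; `NA` for isolated nodes.
#' @export
connectivity_distance <- function(sc, dist, weighted = FALSE) {
  check_connectome(sc)
  if (!all(dim(sc) == dim(dist))) stop2("sc and dist dimensions disagree")
  vapply(seq_len(nrow(sc)), function(i) {
    j <- which(sc[i, ] > 0)
    if (!length(j)) return(NA_real_)
    if (weighted) sum(sc[i, j] * dist[i, j]) / sum(sc[i, j])
    else mean(dist[i, j])
  }, numeric(1))
}

#' Summarize a node map by annotation groups
#'
#' Group means of a per-node statistic over one of three annotation
#' schemes: intrinsic functional `network` labels, cytoarchitectonic
#' `class` labels, or `gradient_bins` — nodes ranked by their continuous
#' gradient value and split into `n_bins` equal-count bins (any remainder
#' goes to the lowest bins; ties broken by node index, stable).
#'
#' @param node_map Numeric per-node vector.
#' @param annotation Annotation data frame ([gen_annotations()]) with
#'   columns `network`, `class`, `gradient`.
#' @param scheme One of `"network"`, `"class"`, `"gradient_bins"`.
#' @param n_bins Number of gradient bins (default 10).
#' @return Data frame with columns `scheme`, `group`, `n`, `mean`, `sd`.
#' @export
annotate_summary <- function(node_map, annotation,
                             scheme = c("network", "class", "gradient_bins"),
                             n_bins = 10) {
  scheme <- match.arg(scheme)
  if (length(node_map) != nrow(annotation))
    stop2("node_map length and annotation rows disagree")
  groups <- switch(scheme,
    network = as.character(annotation$network),
    class = as.character(annotation$class),
    gradient_bins = {
      if (anyNA(annotation$gradient)) stop2("gradient values incomplete")
      rk <- order(annotation$gradient, seq_along(node_map))
      n <- length(node_map)
      base <- n %/% n_bins
      rem <- n %% n_bins
      sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
      g <- character(n)
      g[rk] <- rep(sprintf("bin%02d", seq_len(n_bins)), times = sizes)
      g
    })
  if (anyNA(groups) || any(groups == ""))
    stop2("incomplete labels for scheme '", scheme, "'")
  agg <- tapply(node_map, groups, function(x)
    c(n = length(x), mean = mean(x), sd = stats::sd(x)))
  out <- do.call(rbind, agg)
  data.frame(scheme = scheme, group = rownames(out),
             n = as.integer(out[, "n"]), mean = out[, "mean"],
             sd = out[, "sd"], row.names = NULL)
}

#' Two-sample contrast of similarity values between pair groups
#'
#' Splits the upper-triangle entries of a node x node similarity matrix
#' into two groups — structurally connected versus unconnected pairs, or
#' same-network versus different-network pairs — and compares them with a
#' pooled-variance two-sample t-test (df = n1 + n2 - 2).
#'
#' @param similarity Symmetric node x node matrix.
#' @param grouping Either a weighted connectome (pairs with weight > 0
#'   form group 1) or a per-node label vector (same-label pairs form
#'   group 1).
#' @return List: `t`, `df`, `p`, `mean1`, `mean2`, `n1`, `n2`. A
#'   degenerate contrast (zero pooled variance) returns `t = Inf`
#'   (sign of the mean difference) with `p = 0` and a warning.
#' @export
group_similarity_contrast <- function(similarity, grouping) {
  check_square_symmetric(similarity, "similarity", tol = 1e-8)
  n <- nrow(similarity)
  ut <- upper.tri(similarity)
  if (is.matrix(grouping)) {
    if (!all(dim(grouping) == dim(similarity)))
      stop2("grouping matrix dimensions disagree")
    in1 <- grouping[ut] > 0
  } else {
    if (length(grouping) != n) stop2("grouping labels length disagrees")
    same <- outer(grouping, grouping, `==`)
    in1 <- same[ut]
  }
  v <- similarity[ut]
  ok <- !is.na(v)
  g1 <- v[in1 & ok]
  g2 <- v[!in1 & ok]
  if (!length(g1) || !length(g2)) stop2("one contrast group is empty")
  if (length(g1) < 2 || length(g2) < 2)
    stop2("need >= 2 pairs per group")
  n1 <- length(g1); n2 <- length(g2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(g1) + (n2 - 1) * stats::var(g2)) / df
  delta <- mean(g1) - mean(g2)
  if (sp2 == 0) {
    warning("zero within-group variance; t undefined", call. = FALSE)
    tval <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    tval <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(t = tval, df = df, p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
       mean1 = mean(g1), mean2 = mean(g2), n1 = n1, n2 = n2)
}
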