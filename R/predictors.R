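#' Euclidean distance between node centroids
#'
#' @param geometry Node geometry as returned by [gen_geometry()], or any
#'   data frame with numeric columns `x`, `y`, `z` (one row per node).
#' @return Symmetric node x node distance matrix, zero diagonal.
#' @export
euclidean_distance <- function(geometry) {
  xyz <- as.matrix(geometry[, c("x", "y", "z")])
  if (anyNA(xyz)) stop2("geometry centroids contain missing values")
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- NULL
  off <- d[upper.tri(d)]
  if (any(off == 0))
    stop2("duplicate centroids: some node pairs have zero distance")
  d
}

#' Minmax-normalize a weighted structural connectome
#'
#' Maps every entry by `(w - min) / (max - min)` over the whole matrix.
#' For a sparse connectome (minimum entry 0) this is division by the
#' largest weight: absent edges stay 0 and the strongest edge becomes 1.
#'
#' @param sc Symmetric nonnegative weight matrix, zero diagonal.
#' @return Matrix with entries in \[0, 1\].
#' @export
minmax_normalize <- function(sc) {
  check_connectome(sc, "sc")
  lo <- min(sc)
  hi <- max(sc)
  if (hi == lo) stop2("cannot minmax-normalize: all weights identical")
  (sc - lo) / (hi - lo)
}

#' Convert normalized weights to edge lengths
#'
#' Applies the negative log transform `-log(w)` so strong connections are
#' short. Absent edges (weight 0) are non-traversable and returned as `NA`;
#' a unit weight maps to length 0.
#'
#' @param sc_norm Minmax-normalized connectome (entries in \[0, 1\]).
#' @return Length matrix: nonnegative where an edge exists, `NA` where
#'   absent, zero diagonal.
#' @export
weight_to_length <- function(sc_norm) {
  check_connectome(sc_norm, "sc_norm")
  if (any(sc_norm > 1))
    stop2("weights exceed 1; minmax_normalize() the connectome first")
  len <- ifelse(sc_norm > 0, -log(sc_norm), NA_real_)
  diag(len) <- 0
  len
}

#' All-pairs shortest path length
#'
#' Minimal total edge length over contiguous edge sequences, computed with
#' Dijkstra's algorithm (igraph). Zero-length edges (unit normalized
#' weight) are legal; `NA` entries mark missing edges.
#'
#' @param lengths Symmetric matrix of nonnegative edge lengths with `NA`
#'   for absent edges, as returned by [weight_to_length()].
#' @return Symmetric matrix of finite shortest path lengths, zero diagonal.
#' @export
shortest_path_length <- function(lengths) {
  if (!is.matrix(lengths) || nrow(lengths) != ncol(lengths))
    stop2("lengths must be a square matrix")
  adj <- !is.na(lengths) & row(lengths) != col(lengths)
  if (any(lengths[adj] < 0)) stop2("negative edge lengths")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  spl <- igraph::distances(g, weights = lengths[el],
                           algorithm = "dijkstra")
  if (any(is.infinite(spl))) {
    comp <- igraph::components(g)$membership
    stop2("graph is disconnected; components: ",
          paste(tapply(seq_along(comp), comp, function(i)
            paste0("{", paste(i, collapse = ","), "}")), collapse = " "))
  }
  dimnames(spl) <- NULL
  spl
}

#' Weighted communicability
#'
#' Communicability between nodes i and j is the weighted sum of all walks
#' between them, with longer walks factorially down-weighted:
#' `C = expm(D^{-1/2} A D^{-1/2})` where `D = diag(rowSums(A))` is the
#' generalized degree matrix. The degree normalization prevents high-
#' strength hubs from dominating the walk count.
#'
#' The matrix exponential is computed by eigendecomposition of the
#' symmetric normalized adjacency.
#'
#' @param sc_norm Symmetric nonnegative weight matrix (normalized
#'   connectome), zero diagonal.
#' @return Symmetric matrix, diagonal >= 1, entrywise positive for
#'   connected graphs.
#' @export
weighted_communicability <- function(sc_norm) {
  check_connectome(sc_norm, "sc_norm")
  deg <- rowSums(sc_norm)
  if (any(deg <= 0))
    stop2("isolated node(s) with zero degree: ",
          paste(which(deg <= 0), collapse = ", "))
  dinv <- 1 / sqrt(deg)
  a_norm <- sc_norm * tcrossprod(dinv)
  e <- eigen(a_norm, symmetric = TRUE)
  cmc <- e$vectors %*% (exp(e$values) * t(e$vectors))
  # enforce exact symmetry lost to floating point
  (cmc + t(cmc)) / 2
}

#' Build the structural predictor set for the coupling model
#'
#' Composes the three pairwise structural relationship matrices used as
#' regressors: Euclidean distance between centroids, shortest path length
#' on negative-log-transformed minmax-normalized weights, and weighted
#' communicability of the same normalized matrix.
#'
#' @param geometry Node geometry (data frame with `x`, `y`, `z`).
#' @param sc Weighted symmetric structural connectome (raw weights; the
#'   minmax normalization is applied internally).
#' @return Object of class `"predictor_set"`: list with elements `dist`,
#'   `spl`, `cmc` (node x node matrices) and `norm_max` (the weight that
#'   mapped to 1).
#' @export
build_predictors <- function(geometry, sc) {
  if (nrow(geometry) != nrow(sc))
    stop2("geometry (", nrow(geometry), " nodes) and connectome (",
          nrow(sc), ") disagree")
  if (!is_connected_graph(sc))
    stop2("structural connectome is not connected")
  sc_norm <- minmax_normalize(sc)
  out <- list(
    dist = euclidean_distance(geometry),
    spl = shortest_path_length(weight_to_length(sc_norm)),
    cmc = weighted_communicability(sc_norm),
    norm_max = max(sc)
  )
  class(out) <- "predictor_set"
  out
}

#' @export
print.predictor_set <- function(x, ...) {
  cat("Structural predictor set:", nrow(x$dist), "nodes\n")
  cat("  dist range:", format(range(x$dist[upper.tri(x$dist)]),
                              digits = 4), "\n")
  cat("  spl  range:", format(range(x$spl[upper.tri(x$spl)]),
                              digits = 4), "\n")
  cat("  cmc  range:", format(range(x$cmc[upper.tri(x$cmc)]),
                              digits = 4), "\n")
  invisible(x)
}
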