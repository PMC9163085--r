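#' Generate bilateral node geometry
#'
#' Draws `n_nodes / 2` parcel positions uniformly on the left half of the
#' unit sphere and mirrors them (lateral-axis sign flip, x) to the right
#' hemisphere, emulating the bilateral symmetry of cortical parcellations
#' that spin permutation tests rely on. Centroids are the sphere
#' coordinates scaled to a cortical-shell radius of 70 (arbitrary length
#' units, mm-like).
#'
#' @param n_nodes Even integer >= 8.
#' @param seed Integer seed; output is deterministic.
#' @return Data frame with columns `node_id`, `hemisphere`, centroid
#'   `x`, `y`, `z`, and unit-sphere coordinates `sx`, `sy`, `sz`.
#' @export
gen_geometry <- function(n_nodes, seed) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1 || n_nodes != round(n_nodes))
    stop2("n_nodes must be a single integer")
  if (n_nodes < 8 || n_nodes %% 2 != 0)
    stop2("n_nodes must be even and >= 8, got ", n_nodes)
  half <- n_nodes / 2
  sph_l <- with_seed(seed, {
    g <- matrix(stats::rnorm(3 * half), half, 3)
    g <- g / sqrt(rowSums(g^2))
    g[, 1] <- -abs(g[, 1])   # confine to the left (x < 0) hemisphere
    g
  })
  sph <- rbind(sph_l, sph_l %*% diag(c(-1, 1, 1)))
  radius <- 70
  data.frame(
    node_id = seq_len(n_nodes),
    hemisphere = rep(c("left", "right"), each = half),
    x = sph[, 1] * radius, y = sph[, 2] * radius, z = sph[, 3] * radius,
    sx = sph[, 1], sy = sph[, 2], sz = sph[, 3]
  )
}

#' Generate a sparse distance-dependent weighted connectome
#'
#' Samples the requested number of edges without replacement with
#' selection probability proportional to `exp(-d / length_scale)` —
#' shorter connections are exponentially more likely, as in empirical
#' structural connectomes. Edge weights combine the same exponential
#' distance decay with lognormal variability. If the sampled graph is
#' disconnected, a minimal set of shortest bridging edges is added.
#'
#' @param geometry Node geometry from [gen_geometry()].
#' @param density Target edge density in (0, 1); achieved within 10%
#'   relative.
#' @param length_scale Decay length of connection probability, same units
#'   as the centroids.
#' @param seed Integer seed.
#' @return Symmetric nonnegative weight matrix with zero diagonal,
#'   connected as a graph.
#' @export
gen_connectome <- function(geometry, density, length_scale, seed) {
  n <- nrow(geometry)
  if (!is.numeric(density) || density <= 0 || density >= 1)
    stop2("density must be in (0, 1)")
  if (!is.numeric(length_scale) || length_scale <= 0)
    stop2("length_scale must be positive")
  d <- euclidean_distance(geometry)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  n_pairs <- nrow(pairs)
  m <- round(density * n_pairs)
  if (m < n - 1)
    stop2("density ", density, " yields ", m, " edges; at least ",
          n - 1, " needed to ensure connectivity")
  w <- with_seed(seed, {
    prob <- exp(-d[pairs] / length_scale)
    chosen <- sample.int(n_pairs, m, prob = prob)
    wt <- exp(stats::rnorm(m, 0, 0.5)) * exp(-d[pairs][chosen] / length_scale)
    sc <- matrix(0, n, n)
    sc[pairs[chosen, , drop = FALSE]] <- wt
    sc <- sc + t(sc)
    # bridge disconnected components through their closest node pair
    repeat {
      g <- igraph::graph_from_adjacency_matrix(sc > 0, mode = "undirected")
      comp <- igraph::components(g)
      if (comp$no == 1) break
      in1 <- comp$membership == 1
      dd <- d
      dd[in1, in1] <- Inf
      dd[!in1, !in1] <- Inf
      at <- which(dd == min(dd), arr.ind = TRUE)[1, ]
      bw <- exp(-d[at[1], at[2]] / length_scale)
      sc[at[1], at[2]] <- sc[at[2], at[1]] <- bw
    }
    sc
  })
  w
}

#' Generate activity with known coupling dynamics
#'
#' Simulates regional activity whose instantaneous covariance tracks a
#' structure-derived target with node-specific, time-varying fidelity:
#' at frame t node i's sample is
#' `sqrt(w_i(t)) * s_i(t) + sqrt(1 - w_i(t)) * e_i(t)`, where `s(t)` is a
#' zero-mean Gaussian draw with correlation equal to the connectome's
#' normalized communicability (rescaled to a valid correlation matrix),
#' `e` is independent unit noise, and the fidelity trajectory is
#' `w_i(t) = baseline + alpha_i * m(t)` with `m(t)` a shared unit
#' sinusoid of period `timescale` frames and seed-drawn phase. Nodes with
#' large `alpha` therefore swing between structure-dominated and
#' noise-dominated regimes, producing large coupling fluctuations;
#' `alpha = 0` nodes keep constant fidelity.
#'
#' @param connectome Weighted symmetric connectome ([gen_connectome()]).
#' @param geometry Matching node geometry.
#' @param n_time Number of frames (>= 50).
#' @param alpha Per-node modulation amplitude in \[0, 1\] (scalar
#'   recycled); `baseline + alpha` must stay in \[0, 1\].
#' @param baseline Mean structural fidelity in \[0, 1\].
#' @param timescale Modulator period in frames.
#' @param seed Integer seed.
#' @param walk_temp Walk temperature of the structured correlation
#'   target: the normalized adjacency is scaled by this factor before
#'   the matrix exponential. The default 4 yields off-diagonal
#'   correlations of realistic BOLD magnitude (median about 0.2) on
#'   sparse connectomes; 1 reproduces plain communicability, whose
#'   correlations are too weak to carry recoverable structure.
#' @return List: `activity` (node x time matrix), `ground_truth` (list
#'   with `alpha`, `w` node x time fidelity matrix, `phase`, `target`
#'   correlation matrix).
#' @export
gen_activity <- function(connectome, geometry, n_time, alpha, baseline,
                         timescale, seed, walk_temp = 4) {
  n <- nrow(connectome)
  if (nrow(geometry) != n) stop2("geometry and connectome disagree")
  if (n_time < 50) stop2("n_time must be >= 50")
  if (length(alpha) == 1) alpha <- rep(alpha, n)
  if (length(alpha) != n) stop2("alpha must be scalar or length ", n)
  if (any(alpha < 0 | alpha > 1)) stop2("alpha must lie in [0, 1]")
  if (baseline < 0 || baseline > 1) stop2("baseline must lie in [0, 1]")
  if (any(baseline + alpha > 1) || any(baseline - alpha < 0))
    stop2("baseline +/- alpha must stay in [0, 1]")
  if (timescale <= 0) stop2("timescale must be positive")
  target <- communicability_correlation(connectome, walk_temp)
  ch <- tryCatch(chol(target), error = function(e)
    stop2("structured covariance is not positive definite after scaling: ",
          conditionMessage(e)))
  out <- with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    m <- sin(2 * pi * seq_len(n_time) / timescale + phase)
    w <- baseline + outer(alpha, m)          # n x T fidelity
    s <- t(ch) %*% matrix(stats::rnorm(n * n_time), n, n_time)
    eps <- matrix(stats::rnorm(n * n_time), n, n_time)
    list(activity = sqrt(w) * s + sqrt(1 - w) * eps,
         ground_truth = list(alpha = alpha, w = w, phase = phase,
                             target = target))
  })
  out
}

# Correlation-matrix target: unit-diagonal rescaling of the normalized
# communicability, shrunk toward the identity until the smallest
# eigenvalue is >= 1e-6 (the matrix exponential is already positive
# definite, so shrinkage only guards against numerical degeneracy).
# walk_temp scales the normalized adjacency before exponentiation:
# exp(tau * D^{-1/2} A D^{-1/2}) re-weights longer walks upward. At
# tau = 1 (plain communicability) off-diagonal correlations of sparse
# connectomes are near zero and the activity would carry no recoverable
# structure; tau = 4 puts the median off-diagonal around 0.2, the
# magnitude typical of empirical BOLD functional connectivity.
communicability_correlation <- function(connectome, walk_temp = 4) {
  a <- minmax_normalize(connectome)
  deg <- rowSums(a)
  if (any(deg <= 0)) stop2("isolated node in connectome")
  dinv <- 1 / sqrt(deg)
  e <- eigen(a * tcrossprod(dinv), symmetric = TRUE)
  cmc <- e$vectors %*% (exp(walk_temp * e$values) * t(e$vectors))
  cmc <- (cmc + t(cmc)) / 2
  r <- stats::cov2cor(cmc)
  ev <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-6) {
    lambda <- (1e-6 - ev) / (1 - ev)
    r <- (1 - lambda) * r + lambda * diag(nrow(r))
  }
  r
}

#' Generate synthetic parcel annotations
#'
#' Assigns each node a spatially contiguous intrinsic-network label
#' (nearest of `n_networks` farthest-point-sampled seed nodes), a
#' cytoarchitectonic-class-like categorical label (same construction
#' with its own seeds), and a continuous gradient value — the
#' anterior-posterior (y) centroid coordinate plus mild noise, emulating
#' the smooth unimodal-transmodal gradient.
#'
#' @param geometry Node geometry from [gen_geometry()].
#' @param n_networks Number of network labels (>= 2, <= number of nodes).
#' @param seed Integer seed.
#' @return Data frame with columns `node_id`, `network`, `class`,
#'   `gradient`.
#' @export
gen_annotations <- function(geometry, n_networks, seed) {
  n <- nrow(geometry)
  if (n_networks < 2) stop2("n_networks must be >= 2")
  if (n_networks > n) stop2("n_networks exceeds the number of nodes")
  d <- euclidean_distance(geometry)
  n_classes <- max(2, min(5, n %/% 2))
  with_seed(seed, {
    net <- contiguous_labels(d, n_networks, prefix = "net")
    cls <- contiguous_labels(d, n_classes, prefix = "class")
    grad <- geometry$y + stats::rnorm(n, 0, 0.05 * max(abs(geometry$y)))
    data.frame(node_id = geometry$node_id, network = net, class = cls,
               gradient = grad)
  })
}

# Farthest-point seeding + nearest-seed assignment: spatially contiguous
# clusters without requiring equal sizes.
contiguous_labels <- function(d, k, prefix) {
  n <- nrow(d)
  seeds <- sample.int(n, 1)
  while (length(seeds) < k) {
    dmin <- apply(d[, seeds, drop = FALSE], 1, min)
    seeds <- c(seeds, which.max(dmin))
  }
  assign_to <- apply(d[, seeds, drop = FALSE], 1, which.min)
  paste0(prefix, assign_to)
}
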