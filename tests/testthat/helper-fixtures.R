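# Shared fixtures: small synthetic worlds built in code.

small_world <- function(n_nodes = 20, n_time = 120, density = 0.4,
                        alpha = 0, baseline = 0.6, timescale = 40,
                        seed = 42) {
  geometry <- gen_geometry(n_nodes, seed = seed)
  sc <- gen_connectome(geometry, density = density, length_scale = 60,
                       seed = seed)
  act <- gen_activity(sc, geometry, n_time = n_time, alpha = alpha,
                      baseline = baseline, timescale = timescale,
                      seed = seed)
  list(geometry = geometry, sc = sc, activity = act$activity,
       ground_truth = act$ground_truth)
}

# Independent all-pairs shortest-path oracle (Floyd-Warshall), used to
# validate the Dijkstra-based implementation.
floyd_warshall <- function(lengths) {
  n <- nrow(lengths)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  edge <- !is.na(lengths) & row(lengths) != col(lengths)
  d[edge] <- lengths[edge]
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Random connected weighted graph with zero diagonal.
random_connected_sc <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    edges <- stats::runif(sum(ut)) < p
    w[ut][edges] <- stats::runif(sum(edges), 0.1, 2)
    w <- w + t(w)
    g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
    if (igraph::is_connected(g)) return(w)
  }
}
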