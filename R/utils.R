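# Internal validation helpers shared across modules.

stop2 <- function(...) stop(..., call. = FALSE)

check_square_symmetric <- function(m, name = "matrix", tol = 0) {
  if (!is.matrix(m) || !is.numeric(m))
    stop2(name, " must be a numeric matrix")
  if (nrow(m) != ncol(m))
    stop2(name, " must be square, got ", nrow(m), "x", ncol(m))
  if (anyNA(m))
    stop2(name, " contains missing values")
  d <- max(abs(m - t(m)))
  if (d > tol)
    stop2(name, " is not symmetric (max asymmetry ", format(d), ")")
  invisible(m)
}

check_connectome <- function(w, name = "connectome") {
  check_square_symmetric(w, name)
  if (any(w < 0))
    stop2(name, " has negative weights")
  if (any(diag(w) != 0))
    stop2(name, " must have a zero diagonal")
  invisible(w)
}

# Connectivity check via igraph on the binarized graph.
is_connected_graph <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected",
                                           diag = FALSE)
  igraph::is_connected(g)
}

check_activity <- function(x, name = "activity") {
  if (!is.matrix(x) || !is.numeric(x))
    stop2(name, " must be a numeric node x time matrix")
  if (anyNA(x))
    stop2(name, " contains missing values")
  if (ncol(x) < 3)
    stop2(name, " needs at least 3 time points, got ", ncol(x))
  invisible(x)
}

# Population-sd variant used by the z-scoring convention (divisor T).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

upper_tri_values <- function(m) m[upper.tri(m)]

# Evaluate expr under a fixed seed without disturbing the caller's RNG
# stream (generators must be deterministic yet side-effect free).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop2("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
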