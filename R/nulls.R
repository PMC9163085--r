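#' Generate spatial-autocorrelation-preserving spin permutations
#'
#' Builds a null family for parcellated brain maps by randomly rotating
#' parcel positions on the sphere and reassigning values by proximity.
#' For each permutation a uniform (Haar) random 3-D rotation is drawn,
#' applied to the left-hemisphere sphere coordinates, and mirrored
#' (lateral-axis sign flip) for the right hemisphere, so bilateral
#' symmetry of the map's spatial structure is preserved. Each parcel then
#' receives the value of the nearest rotated parcel within its own
#' hemisphere; because assignment is by nearest neighbor, a source parcel
#' may be used more than once (rows are surjections-with-repeats rather
#' than strict permutations).
#'
#' @param geometry Node geometry with columns `hemisphere` and unit-norm
#'   sphere coordinates `sx`, `sy`, `sz` ([gen_geometry()]).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return Object of class `"spin_perms"`: list with `perm_index`
#'   (`n_perm x n_nodes` integer matrix; entry `[k, i]` is the source
#'   parcel whose value parcel i receives in permutation k), `n_perm`,
#'   `seed`.
#' @export
generate_spins <- function(geometry, n_perm, seed) {
  if (n_perm < 1) stop2("n_perm must be >= 1")
  sph <- as.matrix(geometry[, c("sx", "sy", "sz")])
  if (any(abs(sqrt(rowSums(sph^2)) - 1) > 1e-9))
    stop2("sphere coordinates are not unit-norm")
  hemi <- as.character(geometry$hemisphere)
  if (!all(hemi %in% c("left", "right")))
    stop2("hemisphere labels must be 'left' or 'right'")
  idx_l <- which(hemi == "left")
  idx_r <- which(hemi == "right")
  if (!length(idx_l) || !length(idx_r))
    stop2("both hemispheres must be populated")
  mirror <- diag(c(-1, 1, 1))  # lateral axis = x
  perm <- matrix(NA_integer_, n_perm, nrow(sph))
  with_seed(seed, {
    for (k in seq_len(n_perm))
      perm[k, ] <- spin_assignment(sph, idx_l, idx_r, random_rotation(), mirror)
  })
  structure(list(perm_index = perm, n_perm = n_perm, seed = seed),
            class = "spin_perms")
}

# Haar-uniform rotation: QR of a Gaussian matrix, sign-corrected so R has
# a positive diagonal, then determinant flipped to +1 if needed.
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qrd)
  q <- q %*% diag(sign(diag(qr.R(qrd))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# One spin: rotate left-hemisphere coordinates by rot, right-hemisphere
# ones by the mirrored rotation, and give every target parcel the value
# index of the nearest rotated source parcel within its hemisphere.
spin_assignment <- function(sph, idx_l, idx_r, rot, mirror = diag(c(-1, 1, 1))) {
  rot_r <- mirror %*% rot %*% mirror
  out <- integer(nrow(sph))
  out[idx_l] <- idx_l[nearest_rows(sph[idx_l, , drop = FALSE] %*% t(rot),
                                   sph[idx_l, , drop = FALSE])]
  out[idx_r] <- idx_r[nearest_rows(sph[idx_r, , drop = FALSE] %*% t(rot_r),
                                   sph[idx_r, , drop = FALSE])]
  out
}

# For each row of rotated source coordinates, the index of the nearest
# target row; equivalently (on the unit sphere) the maximal dot product.
# Returns, for each TARGET parcel, which rotated SOURCE parcel is nearest.
nearest_rows <- function(rotated, targets) {
  dots <- targets %*% t(rotated)   # n_target x n_source
  max.col(dots, ties.method = "first")
}

#' @export
print.spin_perms <- function(x, ...) {
  cat("Spin permutations:", x$n_perm, "rotations x",
      ncol(x$perm_index), "parcels (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Spin-test permutation p-value
#'
#' Recomputes a map-level statistic under every spin permutation of the
#' first map and reports the permutation p-value
#' `p = (1 + #extreme nulls) / (n_perm + 1)`, bounded below by
#' `1 / (n_perm + 1)` so it is never exactly zero. The default test is
#' two-tailed on the absolute statistic.
#'
#' @param node_map_a Per-node vector; its values are reassigned by each
#'   permutation row.
#' @param node_map_b Per-node vector (for `stat = "correlation"`) or a
#'   group label/logical vector (for `stat = "group_mean_diff"`).
#' @param spins `spin_perms` object from [generate_spins()].
#' @param stat `"correlation"` (Pearson r between maps) or
#'   `"group_mean_diff"` (mean of map a in group vs out of group).
#' @param tails `"two"` (default, by absolute value) or `"one"` (upper).
#' @return List: `observed`, `p`, `nulls` (length `n_perm`), `tails`.
#' @export
spin_pvalue <- function(node_map_a, node_map_b, spins,
                        stat = c("correlation", "group_mean_diff"),
                        tails = c("two", "one")) {
  stat <- match.arg(stat)
  tails <- match.arg(tails)
  if (!inherits(spins, "spin_perms")) stop2("spins must be a spin_perms object")
  if (spins$n_perm < 1) stop2("no permutations available")
  n <- ncol(spins$perm_index)
  if (length(node_map_a) != n)
    stop2("node_map_a length ", length(node_map_a), " != ", n, " parcels")
  if (anyNA(node_map_a) || anyNA(node_map_b)) stop2("maps must be complete")
  stat_fn <- switch(stat,
    correlation = function(a) stats::cor(a, node_map_b),
    group_mean_diff = {
      grp <- as.logical(node_map_b)
      if (length(grp) != n) stop2("group vector length disagrees")
      function(a) mean(a[grp]) - mean(a[!grp])
    })
  observed <- stat_fn(node_map_a)
  nulls <- apply(spins$perm_index, 1, function(src) stat_fn(node_map_a[src]))
  extreme <- if (tails == "two") abs(nulls) >= abs(observed)
             else nulls >= observed
  list(observed = observed,
       p = (1 + sum(extreme, na.rm = TRUE)) / (spins$n_perm + 1),
       nulls = nulls, tails = tails)
}
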