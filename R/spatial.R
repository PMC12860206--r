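# Spatial utilities: great-circle distances, spatial weights, Moran's I
# with a permutation test, Moran eigenvector map (MEM) spatial predictors,
# distance-based thinning, and spatially coherent cross-validation folds.

EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance matrix
#'
#' Haversine distances between all pairs of plots, in km, on a sphere of
#' radius 6371.0088 km.
#'
#' @param coords data.frame with `lon` and `lat` in decimal degrees (an
#'   optional `plot_id` column labels the matrix).
#' @return n x n symmetric matrix of distances (km), zero diagonal.
#' @export
haversine_matrix <- function(coords) {
  check_coords(coords)
  p <- as.matrix(coords[, c("lon", "lat")])
  D <- geosphere::distm(p, fun = function(a, b) {
    geosphere::distHaversine(a, b, r = EARTH_RADIUS_KM)
  })
  ids <- if ("plot_id" %in% names(coords)) coords$plot_id else
    as.character(seq_len(nrow(p)))
  dimnames(D) <- list(ids, ids)
  D
}

#' Spatial weights from a distance matrix
#'
#' Inverse-distance weights truncated at a radius (default: the 25th
#' percentile of the off-diagonal distances), or k-nearest-neighbour
#' weights; optionally row-standardised.
#'
#' @param D distance matrix (km), as from [haversine_matrix()].
#' @param scheme "idw" (default) or "knn".
#' @param truncation_km truncation radius for "idw"; default the 25th
#'   percentile of pairwise distances.
#' @param k number of neighbours for "knn" (default 8).
#' @param row_standardize logical; if TRUE (default) non-empty rows sum to 1.
#' @return weights matrix with zero diagonal and attributes `scheme`,
#'   `row_standardized`.
#' @export
spatial_weights <- function(D, scheme = c("idw", "knn"),
                            truncation_km = NULL, k = 8,
                            row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  n <- nrow(D)
  W <- matrix(0, n, n, dimnames = dimnames(D))
  if (scheme == "idw") {
    if (is.null(truncation_km)) {
      truncation_km <- stats::quantile(D[upper.tri(D)], 0.25)
    }
    check_scalar(truncation_km, "truncation_km", positive = TRUE)
    sel <- D <= truncation_km & D > 0
    W[sel] <- 1 / D[sel]
  } else {
    k <- min(k, n - 1)
    for (i in seq_len(n)) {
      nb <- order(D[i, ])[2:(k + 1)]
      W[i, nb] <- 1
    }
  }
  diag(W) <- 0
  if (row_standardize) {
    rs <- rowSums(W)
    nz <- rs > 0
    W[nz, ] <- W[nz, , drop = FALSE] / rs[nz]
  }
  attr(W, "scheme") <- scheme
  attr(W, "row_standardized") <- row_standardize
  W
}

#' Moran's I with a permutation test
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with centred values z
#' and `S0 = sum(W)`. The expectation under the null is `-1/(n-1)`; the
#' two-sided p-value comes from seeded random permutations of the values.
#'
#' @param values numeric vector (not all equal).
#' @param W spatial weights matrix (zero diagonal).
#' @param n_perm number of permutations (default 999); 0 skips the test.
#' @param seed integer seed for the permutations.
#' @return list with `I`, `expected`, `p_value` (NA if `n_perm = 0`),
#'   `n_perm`.
#' @export
morans_i <- function(values, W, n_perm = 999, seed = 1) {
  n <- length(values)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (nrow(W) != n || ncol(W) != n) {
    stop("W must be n x n", call. = FALSE)
  }
  if (anyNA(values)) stop("values contain NA", call. = FALSE)
  z <- values - mean(values)
  ss <- sum(z^2)
  if (ss == 0) stop("zero variance: values are constant", call. = FALSE)
  s0 <- sum(W)
  stat <- function(z) (n / s0) * sum(z * (W %*% z)) / sum(z^2)
  I <- stat(z)
  expected <- -1 / (n - 1)
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(derive_seed(seed, "morans_i"))
    perm <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      perm[b] <- stat(z[sample.int(n)])
    }
    p <- (1 + sum(abs(perm - expected) >= abs(I - expected))) / (n_perm + 1)
  }
  list(I = I, expected = expected, p_value = p, n_perm = n_perm,
       permuted = if (n_perm > 0) perm else numeric(0))
}

#' Moran eigenvector map (MEM) spatial predictors
#'
#' Builds the principal-coordinates-of-neighbour-matrices connectivity:
#' distances above the truncation radius are replaced by four times the
#' truncation, similarities are `1 - (d* / max(d*))^2`, the similarity
#' matrix is double-centred and eigendecomposed. Eigenvectors with positive
#' eigenvalues, sorted by eigenvalue, are returned together with their
#' Moran's I (computed with the default inverse-distance weights truncated
#' at the same radius).
#'
#' @param D distance matrix (km).
#' @param truncation_km truncation radius (> 0); see [pcnm_truncation()] for
#'   the conventional default.
#' @return list of class `mem_predictors`: `vectors` (n x k, unit-norm,
#'   columns `mem_1` ...), `values` (eigenvalues), `moran` (Moran's I per
#'   column), `truncation_km`.
#' @export
mem_predictors <- function(D, truncation_km) {
  check_scalar(truncation_km, "truncation_km", positive = TRUE)
  n <- nrow(D)
  adj <- D <= truncation_km
  diag(adj) <- TRUE
  # connectivity check: BFS over the truncation graph
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    nb <- which(adj[i, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!all(seen)) {
    stop("disconnected graph: some plots are beyond the truncation ",
         "distance from all others; increase truncation_km", call. = FALSE)
  }
  dstar <- D
  dstar[D > truncation_km] <- 4 * truncation_km
  C <- 1 - (dstar / max(dstar))^2
  # double-centre (Gower)
  C <- sweep(C, 1, rowMeans(C))
  C <- sweep(C, 2, colMeans(C))
  C <- (C + t(C)) / 2
  eg <- eigen(C, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-8
  if (!any(keep)) stop("no positive MEM eigenvalues", call. = FALSE)
  V <- eg$vectors[, keep, drop = FALSE]
  colnames(V) <- sprintf("mem_%d", seq_len(ncol(V)))
  rownames(V) <- rownames(D)
  W <- spatial_weights(D, truncation_km = truncation_km)
  mi <- apply(V, 2, function(v) morans_i(v, W, n_perm = 0)$I)
  structure(list(vectors = V, values = eg$values[keep], moran = mi,
                 truncation_km = truncation_km),
            class = "mem_predictors")
}

#' Conventional MEM truncation distance
#'
#' The longest edge of the minimum spanning tree of the distance matrix --
#' the smallest truncation that keeps the connectivity graph connected.
#'
#' @param D distance matrix (km).
#' @return truncation distance (km).
#' @export
pcnm_truncation <- function(D) {
  max(vegan::spantree(stats::as.dist(D))$dist)
}

#' Spatial thinning to a minimum inter-plot distance
#'
#' Randomised greedy elimination: while any pair is closer than
#' `min_dist_km`, drop a random plot among those with the most neighbours
#' inside the exclusion radius. The procedure is repeated `n_tries` times
#' with different sub-seeds and the largest retained set is returned. The
#' output always satisfies the distance constraint.
#'
#' @param coords data.frame with `lon`, `lat` and optionally `plot_id`.
#' @param min_dist_km minimum allowed pairwise distance (km).
#' @param n_tries number of randomised restarts (default 10).
#' @param seed integer seed.
#' @return character vector of retained plot ids (row indices as character
#'   if no `plot_id` column).
#' @export
thin_points <- function(coords, min_dist_km, n_tries = 10, seed = 1) {
  check_scalar(min_dist_km, "min_dist_km", positive = TRUE)
  if (n_tries < 1) stop("n_tries must be >= 1", call. = FALSE)
  D <- haversine_matrix(coords)
  n <- nrow(D)
  ids <- rownames(D)
  if (n == 1) return(ids)
  conflict <- D < min_dist_km
  diag(conflict) <- FALSE
  best <- character(0)
  for (t in seq_len(n_tries)) {
    set.seed(derive_seed(seed, paste0("thin_", t)))
    alive <- rep(TRUE, n)
    deg <- rowSums(conflict)
    while (any(deg[alive] > 0)) {
      cand <- which(alive & deg == max(deg[alive]))
      drop_i <- if (length(cand) == 1) cand else
        cand[sample.int(length(cand), 1L)]
      alive[drop_i] <- FALSE
      nb <- which(conflict[drop_i, ] & alive)
      deg[nb] <- deg[nb] - 1L
      deg[drop_i] <- 0L
    }
    kept <- ids[alive]
    if (length(kept) > length(best)) best <- kept
  }
  stopifnot(all(D[best, best][upper.tri(D[best, best])] >= min_dist_km))
  best
}

#' Spatially coherent cross-validation folds
#'
#' Plots are clustered into `k` folds by k-means on their unit-sphere
#' (chord) coordinates, which orders pairs identically to great-circle
#' distance. Every fold is non-empty and labels are deterministic given the
#' seed.
#'
#' @param coords data.frame with `lon`, `lat`.
#' @param k number of folds (2 <= k <= n; default 30).
#' @param seed integer seed.
#' @return integer vector of fold labels in `1..k`.
#' @export
spatial_folds <- function(coords, k = 30, seed = 1) {
  check_coords(coords)
  n <- nrow(coords)
  if (k > n) stop("k must not exceed the number of plots", call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k == n) return(seq_len(n))
  lam <- coords$lon * pi / 180
  phi <- coords$lat * pi / 180
  xyz <- cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
  set.seed(derive_seed(seed, "spatial_folds"))
  km <- stats::kmeans(xyz, centers = k, nstart = 10, iter.max = 100)
  as.integer(km$cluster)
}
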