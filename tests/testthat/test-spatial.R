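test_that("haversine distances match closed-form great-circle cases", {
  co <- data.frame(lon = c(0, 0, 0, 1), lat = c(0, 180 - 180, 1, 0))
  same <- haversine_matrix(data.frame(lon = c(10, 10), lat = c(5, 5)))
  expect_equal(same[1, 2], 0)

  anti <- haversine_matrix(data.frame(lon = c(0, 180), lat = c(0, 0)))
  expect_equal(anti[1, 2], pi * 6371.0088, tolerance = 1e-6)

  one_deg <- haversine_matrix(data.frame(lon = c(0, 0), lat = c(0, 1)))
  expect_equal(one_deg[1, 2], 6371.0088 * pi / 180, tolerance = 1e-6)

  # symmetry, zero diagonal, triangle inequality on random triples
  set.seed(1)
  co <- data.frame(lon = runif(12, -180, 180), lat = runif(12, -60, 60))
  D <- haversine_matrix(co)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 12))
  for (i in 1:20) {
    tri <- sample(12, 3)
    expect_lte(D[tri[1], tri[2]],
               D[tri[1], tri[3]] + D[tri[3], tri[2]] + 1e-9)
  }
  expect_error(haversine_matrix(data.frame(lon = c(0, NA), lat = c(0, 1))),
               "missing")
})

test_that("Moran's I matches its formula, null and lattice behaviour", {
  expect_equal(morans_i(rnorm(10), matrix(1, 10, 10) - diag(10),
                        n_perm = 0)$expected, -1 / 9)
  expect_error(morans_i(rep(1, 10), matrix(1, 10, 10), n_perm = 0),
               "zero variance")

  # checkerboard on a 6x6 rook lattice: strong negative autocorrelation
  W <- rook_weights(6, 6)
  chk <- outer(1:6, 1:6, function(i, j) (-1)^(i + j))
  mi <- morans_i(as.numeric(chk), W, n_perm = 499, seed = 1)
  expect_lt(mi$I, mi$expected)
  expect_lt(mi$p_value, 0.05)

  # permutation null centres on -1/(n-1)
  set.seed(2)
  vals <- rnorm(36)
  mi2 <- morans_i(vals, W, n_perm = 999, seed = 3)
  se <- sd(mi2$permuted) / sqrt(length(mi2$permuted))
  expect_lt(abs(mean(mi2$permuted) - mi2$expected), 3 * se)

  # long-range field: positive and significant
  cfg <- small_config()
  co <- generate_coordinates(cfg)
  env <- generate_environment(co, cfg)
  D <- haversine_matrix(co)
  Wd <- spatial_weights(D)
  mi3 <- morans_i(env$X$bio01, Wd, n_perm = 499, seed = 4)
  expect_gt(mi3$I, 0)
  expect_lt(mi3$p_value, 0.05)
})

test_that("Moran's I agrees with the ape implementation", {
  set.seed(7)
  co <- data.frame(lon = runif(25, 0, 10), lat = runif(25, 0, 10))
  D <- haversine_matrix(co)
  W <- spatial_weights(D, truncation_km = 400)
  x <- rnorm(25)
  ours <- morans_i(x, W, n_perm = 0)$I
  theirs <- ape::Moran.I(x, W)$observed
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("spatial weights have zero diagonal and standardized rows", {
  set.seed(8)
  co <- data.frame(lon = runif(15), lat = runif(15))
  D <- haversine_matrix(co)
  for (W in list(spatial_weights(D), spatial_weights(D, "knn", k = 4))) {
    expect_equal(unname(diag(W)), rep(0, 15))
    rs <- rowSums(W)
    expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
  }
})

test_that("MEM predictors are orthogonal spatial filters", {
  set.seed(9)
  co <- grid_coords(5, 5)
  D <- haversine_matrix(co)
  mem <- mem_predictors(D, truncation_km = pcnm_truncation(D))
  V <- mem$vectors
  # unit norm and mutual orthogonality after centering
  G <- crossprod(scale(V, center = TRUE, scale = FALSE))
  expect_true(all(abs(G[upper.tri(G)]) <= 1e-8))
  expect_equal(unname(sqrt(colSums(V^2))), rep(1, ncol(V)))
  # first eigenvector carries the largest Moran's I of the returned set
  expect_equal(which.max(mem$moran), 1L, ignore_attr = TRUE)
  expect_true(all(diff(mem$values) <= 1e-9))

  # all points mutually beyond truncation: disconnected
  far <- data.frame(lon = c(0, 50, 100), lat = c(0, 0, 0))
  expect_error(mem_predictors(haversine_matrix(far), truncation_km = 10),
               "disconnected")
})

test_that("MEM columns absorb residual spatial autocorrelation", {
  cfg <- small_config(seed = 21)
  co <- generate_coordinates(cfg)
  env <- generate_environment(co, cfg)
  # response = spatial field + noise; model has no informative covariate
  y <- env$X$bio01 + rnorm(nrow(co), 0, 0.3)
  D <- haversine_matrix(co)
  W <- spatial_weights(D, truncation_km = pcnm_truncation(D))
  mem <- mem_predictors(D, pcnm_truncation(D))
  res0 <- residuals(lm(y ~ 1))
  k <- order(mem$moran, decreasing = TRUE)[1:5]
  res1 <- residuals(lm(y ~ mem$vectors[, k]))
  I0 <- abs(morans_i(res0, W, n_perm = 0)$I)
  I1 <- abs(morans_i(res1, W, n_perm = 0)$I)
  expect_lt(I1, I0)
})

test_that("thinning always honours the distance constraint", {
  # already sparse: identity
  co <- data.frame(plot_id = c("a", "b"), lon = c(0, 10), lat = c(0, 0))
  expect_setequal(thin_points(co, 100), c("a", "b"))
  # two close points: exactly one kept
  co2 <- data.frame(plot_id = c("a", "b"), lon = c(0, 0.09), lat = c(0, 0))
  expect_length(thin_points(co2, 50), 1)
  # collinear 0 / 40 / 80 km: optimal keeps the endpoints
  co3 <- data.frame(plot_id = c("p0", "p40", "p80"),
                    lon = c(0, 40, 80) / 111.19492664, lat = c(0, 0, 0))
  kept <- thin_points(co3, 50, n_tries = 10, seed = 1)
  expect_setequal(kept, c("p0", "p80"))
  # property: constraint satisfied on random configurations
  set.seed(3)
  for (i in 1:5) {
    co4 <- data.frame(lon = runif(30, 0, 5), lat = runif(30, 0, 5))
    ids <- thin_points(co4, 150, n_tries = 5, seed = i)
    D <- haversine_matrix(co4)[ids, ids, drop = FALSE]
    if (length(ids) > 1) expect_gte(min(D[upper.tri(D)]), 150)
  }
})

# exhaustive maximum independent set for small fixtures
max_retained <- function(D, min_dist) {
  n <- nrow(D)
  best <- 0
  for (code in 0:(2^n - 1)) {
    sel <- which(bitwAnd(code, 2^(0:(n - 1))) > 0)
    if (length(sel) <= best) next
    sub <- D[sel, sel, drop = FALSE]
    if (all(sub[upper.tri(sub)] >= min_dist)) best <- length(sel)
  }
  best
}

test_that("thinning attains the exhaustive optimum on small fixtures", {
  hits <- 0; total <- 0
  for (i in 1:4) {
    set.seed(400 + i)
    n <- sample(8:12, 1)
    co <- data.frame(lon = runif(n, 0, 3), lat = runif(n, 0, 3))
    D <- haversine_matrix(co)
    opt <- max_retained(D, 120)
    for (s in 1:5) {
      total <- total + 1
      hits <- hits + (length(thin_points(co, 120, n_tries = 10,
                                         seed = s)) == opt)
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("spatial folds partition the plots coherently", {
  set.seed(5)
  co <- data.frame(lon = runif(20, 0, 5), lat = runif(20, 0, 5))
  expect_equal(spatial_folds(co, k = 20), 1:20)
  expect_error(spatial_folds(co, k = 21), "exceed")
  expect_error(spatial_folds(co, k = 1), ">= 2")

  f <- spatial_folds(co, k = 4, seed = 2)
  expect_length(f, 20)
  expect_equal(sort(unique(f)), 1:4)          # all folds non-empty
  expect_identical(f, spatial_folds(co, k = 4, seed = 2))

  # two well-separated clouds -> folds coincide with the clouds
  clouds <- rbind(
    data.frame(lon = runif(10, 0, 1), lat = runif(10, 0, 1)),
    data.frame(lon = runif(10, 40, 41), lat = runif(10, 0, 1)))
  fc <- spatial_folds(clouds, k = 2, seed = 3)
  expect_equal(length(unique(fc[1:10])), 1)
  expect_equal(length(unique(fc[11:20])), 1)
  expect_false(fc[1] == fc[11])
})
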