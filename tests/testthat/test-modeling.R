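sim_X <- function(n, p, seed = 1) {
  set.seed(seed)
  as.data.frame(matrix(rnorm(n * p), n, p,
                       dimnames = list(NULL, paste0("X", seq_len(p)))))
}

test_that("VIF screening drops exactly the collinear columns", {
  set.seed(1)
  X <- sim_X(200, 4)
  rep1 <- vif_screen(X)
  expect_length(rep1$dropped$variable, 0)
  expect_setequal(rep1$kept, names(X))

  Xd <- X; Xd$X5 <- Xd$X1
  rep2 <- vif_screen(Xd)
  expect_equal(nrow(rep2$dropped), 1)
  expect_true(rep2$dropped$variable %in% c("X1", "X5"))

  Xs <- X; Xs$X3 <- Xs$X1 + Xs$X2 + rnorm(200, 0, 1e-4)
  rep3 <- vif_screen(Xs, threshold = 10)
  expect_equal(nrow(rep3$dropped), 1)
  expect_true(rep3$dropped$variable %in% c("X1", "X2", "X3"))
  expect_setequal(c(rep3$kept, rep3$dropped$variable), names(Xs))

  Xc <- X; Xc$flat <- 1
  rep4 <- vif_screen(Xc)
  expect_true("flat" %in% rep4$dropped$variable)
  expect_equal(rep4$dropped$reason[rep4$dropped$variable == "flat"],
               "zero variance")
})

test_that("shadow-feature screen separates signal from noise", {
  n <- 400
  X <- sim_X(n, 10, seed = 2)
  y <- X$X1 + rnorm(n, 0, 0.3)
  rep1 <- boruta_screen(X, y, n_iter = 40, seed = 1)
  expect_true("X1" %in% rep1$kept)
  expect_gte(sum(paste0("X", 2:10) %in% rep1$dropped$variable), 7)
  expect_setequal(c(rep1$kept, rep1$tentative, rep1$dropped$variable),
                  names(X))

  # pure noise: nothing confirmed
  for (s in 1:3) {
    set.seed(100 + s)
    y0 <- rnorm(n)
    rep0 <- boruta_screen(X, y0, n_iter = 30, alpha = 0.01, seed = s)
    expect_length(rep0$kept, 0)
  }
  expect_error(boruta_screen(X, rep(1, n), n_iter = 30), "constant")
  expect_error(boruta_screen(X, y, n_iter = 5), "n_iter")
})

test_that("interaction features are the pair's first principal component", {
  n <- 500
  X <- sim_X(n, 4, seed = 3)
  res <- suggest_interactions(X, rnorm(n), list(c("X1", "X2")),
                              seed = 1)
  expect_equal(res$report$name, "X1..pca..X2")
  # PC1 of a standardised pair is (z_a + sign(r) z_b) / sqrt(2)
  r <- cor(X$X1, X$X2)
  pc <- (scale(X$X1) + sign(r) * scale(X$X2)) / sqrt(2)
  got <- richdrivers:::pair_pc1(X$X1, X$X2, "X1", "X2")[[1]]
  expect_gt(abs(cor(got, pc)), 1 - 1e-10)

  # strong product signal: the interaction of the true pair is kept
  y <- X$X1 * X$X2 + rnorm(n, 0, 0.2)
  res2 <- suggest_interactions(X, y, list(c("X1", "X2"), c("X3", "X4")),
                               seed = 1)
  expect_true("X1..pca..X2" %in% res2$report$name[res2$report$kept])

  # pure noise: interactions almost never kept at the default margin
  n_kept <- 0
  for (s in 1:5) {
    set.seed(500 + s)
    res3 <- suggest_interactions(X, rnorm(n), list(c("X1", "X2"),
                                                   c("X3", "X4")),
                                 seed = s)
    n_kept <- n_kept + sum(res3$report$kept)
  }
  expect_lte(n_kept, 1)

  # perfectly collinear pair is skipped with a warning
  Xc <- X; Xc$X9 <- 2 * Xc$X1
  expect_warning(suggest_interactions(Xc, y, list(c("X1", "X9")), seed = 1),
                 "collinear")
})

test_that("random forest recovers strong signal and rejects pure noise", {
  n <- 500
  X <- sim_X(n, 8, seed = 4)
  y_step <- ifelse(X$X1 > 0, 10, 0) + ifelse(X$X1 > 1, 5, 0)
  fit <- fit_rf(X, y_step, seed = 1)
  expect_gte(fit$oob_r2, 0.9)
  expect_equal(names(which.max(fit$importance)), "X1")
  expect_true(all(fit$importance >= 0))
  # unused columns have ~zero importance
  expect_lt(max(fit$importance[-1]), 0.05 * max(fit$importance))

  for (s in 1:3) {
    set.seed(200 + s)
    fit0 <- fit_rf(sim_X(400, 24, seed = 300 + s), rnorm(400), seed = s,
                   compute_importance = FALSE)
    expect_lte(fit0$oob_r2, 0.1)
  }
  Xn <- X; Xn$X2[5] <- NA
  expect_error(fit_rf(Xn, y_step), "X2")
  expect_error(fit_rf(X[1:10, ], y_step[1:10]), "30 observations")
})

test_that("spatial forest absorbs spatial structure only when present", {
  # dense single-region network: strong local autocorrelation
  cfg <- generator_config(n_plots_per_region = c(Americas = 150),
                          region_boxes = list(Americas = c(-80, -45, -20, 10)),
                          spatial_range_km = 1000, seed = 31)
  co <- generate_coordinates(cfg)
  env <- generate_environment(co, cfg)
  n <- nrow(co)

  # response dominated by a long-range spatial field, no X signal
  y_sp <- 10 + 3 * env$X$bio01
  Xn <- sim_X(n, 6, seed = 5)     # uninformative covariates
  fs <- fit_spatial_rf(Xn, y_sp, co, seed = 1, n_perm = 199)
  expect_gte(ncol(fs$mem), 1)
  expect_lt(abs(fs$residual_moran$I), abs(fs$residual_moran_nonspatial$I))
  # importance covers every X column and every selected MEM column
  expect_setequal(names(fs$importance),
                  c(names(Xn), colnames(fs$mem)))

  # response independent of space: no eigenvector selected
  set.seed(6)
  y_ns <- 5 + 2 * Xn$X1 + rnorm(n, 0, 0.5)
  fs2 <- fit_spatial_rf(Xn, y_ns, co, seed = 1, n_perm = 199)
  expect_equal(ncol(fs2$mem), 0)

  # selection never costs more than the tolerance in OOB R^2
  base <- fit_rf(Xn, y_sp, seed = 1, compute_importance = FALSE)
  expect_gte(fs$oob_r2, base$oob_r2 - 0.005)
})

test_that("negative-binomial GLM recovers coefficients and nests Poisson", {
  n <- 2000
  set.seed(10)
  X <- data.frame(X1 = rnorm(n))
  mu <- exp(1 + 0.5 * X$X1)
  y <- rnbinom(n, size = 2, mu = mu)
  region <- factor(rep(c("A", "B"), length.out = n))
  fit <- fit_nb_glm(X, y, region)
  co <- fit$coefficients[fit$coefficients$term == "X1", ]
  expect_true(co$estimate - 1.96 * co$se <= 0.5 &&
              co$estimate + 1.96 * co$se >= 0.5)
  expect_equal(fit$theta, 2, tolerance = 0.3)

  # Poisson data: huge dispersion estimate, coefficients match glm(poisson)
  yp <- rpois(n, mu)
  nb <- fit_nb_glm(X, yp, region)
  po <- glm(yp ~ X1 + region, data = cbind(X, region = region),
            family = poisson())
  expect_gt(nb$theta, 100)
  expect_equal(unname(nb$coefficients$estimate[1:2]),
               unname(coef(po)[1:2]), tolerance = 1e-3)

  expect_error(fit_nb_glm(X, y + 0.5, region), "integers")
  expect_error(fit_nb_glm(X, y, factor(rep("A", n))), "2 levels")
})

test_that("regional richness offsets surface as region effects in the GLM", {
  # Americas plots get a +0.3 log-richness shift over the Africa baseline
  cfg <- generator_config(seed = 41)
  co <- generate_coordinates(cfg)
  env <- generate_environment(co, cfg)
  set.seed(11)
  mu <- exp(4 + 0.3 * (co$region == "Americas"))
  y <- rnbinom(nrow(co), size = 10, mu = mu)
  region <- factor(as.character(co$region), levels = c("Africa", "Americas",
                                                       "Asia"))
  fit <- fit_nb_glm(env$X["tpi"], y, region)   # tpi: no regional offsets
  am <- fit$coefficients[fit$coefficients$term == "regionAmericas", ]
  expect_gt(am$estimate, 0)
  expect_lt(am$p, 0.05)
})

test_that("environmental PCA is an exact orthogonal decomposition", {
  set.seed(12)
  X <- sim_X(50, 5)
  pca <- pca_env(X)
  expect_equal(sum(pca$variance_fraction), 1, tolerance = 1e-9)
  # reconstruction of the standardised data from scores and loadings
  Z <- scale(as.matrix(X))
  rec <- pca$scores %*% t(pca$loadings)
  expect_lt(max(abs(rec - Z)), 1e-8)
  # sign convention: dominant loading entry positive
  for (j in seq_len(ncol(pca$loadings))) {
    v <- pca$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }

  X2 <- data.frame(a = X$X1, b = 2 * X$X1 + 3)
  expect_equal(pca_env(X2)$variance_fraction[1], 1, tolerance = 1e-12)
  Xc <- X; Xc$flat <- 7
  expect_error(pca_env(Xc), "flat")
})

test_that("partial dependence reflects the fitted response surface", {
  n <- 600
  X <- sim_X(n, 3, seed = 13)
  # constant response -> flat curve
  fit0 <- fit_rf(X, rep(5, n) + rnorm(n, 0, 1e-12), seed = 1,
                 compute_importance = FALSE)
  pd0 <- partial_dependence(fit0, "X1")
  expect_lt(diff(range(pd0$yhat)), 1e-6)

  # linear truth: slope ~ 2 over the interquartile range
  y <- 2 * X$X1 + rnorm(n, 0, 0.1)
  fit <- fit_rf(X, y, seed = 1, compute_importance = FALSE)
  qs <- quantile(X$X1, c(0.25, 0.75))
  pd <- partial_dependence(fit, "X1", grid = seq(qs[1], qs[2],
                                                 length.out = 11))
  slope <- coef(lm(yhat ~ value, pd))[2]
  expect_equal(unname(slope), 2, tolerance = 0.25)

  # subgroup curves average (weighted) to the pooled curve
  g <- rep(c(TRUE, FALSE), c(200, 400))
  pd_a <- partial_dependence(fit, "X1", grid = 0:2, rows = which(g))
  pd_b <- partial_dependence(fit, "X1", grid = 0:2, rows = which(!g))
  pd_all <- partial_dependence(fit, "X1", grid = 0:2)
  expect_equal((200 * pd_a$yhat + 400 * pd_b$yhat) / 600, pd_all$yhat,
               tolerance = 1e-8)

  # out-of-range grid points are flagged
  pd_x <- partial_dependence(fit, "X1", grid = c(0, 100))
  expect_identical(pd_x$extrapolated, c(FALSE, TRUE))
  expect_error(partial_dependence(fit, "nope"), "training variable")
})
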