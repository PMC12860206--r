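# Variable screening, random-forest regression with out-of-bag evaluation,
# spatial augmentation with Moran eigenvectors, negative-binomial count
# regression with region interactions, environmental PCA, and partial
# dependence. The forest base learner is ranger; everything around it
# (screening, spatial selection, sensitivity bookkeeping) is this package's.

#' Random-forest hyperparameters
#'
#' @param num_trees number of trees (default 500).
#' @param mtry variables tried per split; default `ceiling(p / 3)`.
#' @param min_node_size minimal terminal node size (default 5).
#' @return list of class `rf_params`.
#' @export
rf_params <- function(num_trees = 500, mtry = NULL, min_node_size = 5) {
  structure(list(num_trees = num_trees, mtry = mtry,
                 min_node_size = min_node_size),
            class = "rf_params")
}

check_model_matrix <- function(X, y = NULL) {
  if (!is.data.frame(X)) X <- as.data.frame(X)
  bad <- names(X)[vapply(X, function(col) any(!is.finite(col)), logical(1))]
  if (length(bad)) {
    stop("non-finite values in columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(y)) {
    if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
    if (any(!is.finite(y))) stop("non-finite values in y", call. = FALSE)
  }
  X
}

#' Iterative variance-inflation-factor screen
#'
#' Repeatedly drops the predictor with the highest VIF (`1 / (1 - R^2)` of
#' regressing it on the remaining predictors) until all VIFs are at or
#' below the threshold. Constant columns are dropped first with reason
#' "zero variance". Ties are broken by dropping the later column.
#'
#' @param X data.frame of predictors.
#' @param threshold VIF threshold (> 1; default 10).
#' @return list of class `screen_report`: `kept`, `dropped` (data.frame
#'   `variable`, `reason`), `threshold`.
#' @export
vif_screen <- function(X, threshold = 10) {
  X <- check_model_matrix(X)
  if (threshold <= 1) stop("threshold must be > 1", call. = FALSE)
  dropped <- data.frame(variable = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  const <- names(X)[vapply(X, function(col) stats::var(col) == 0, logical(1))]
  for (v in const) {
    dropped <- rbind(dropped, data.frame(variable = v,
                                         reason = "zero variance"))
  }
  X <- X[setdiff(names(X), const)]
  vif_of <- function(j) {
    r2 <- suppressWarnings(
      summary(stats::lm(X[[j]] ~ ., data = X[-j]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  while (ncol(X) > 1) {
    vifs <- vapply(seq_along(X), vif_of, numeric(1))
    if (max(vifs) <= threshold) break
    j <- max(which(vifs == max(vifs)))          # tie-break: later column
    dropped <- rbind(dropped, data.frame(
      variable = names(X)[j],
      reason = sprintf("VIF=%.3g", vifs[j])))
    X <- X[-j]
  }
  structure(list(kept = names(X), dropped = dropped, threshold = threshold),
            class = "screen_report")
}

#' Shadow-feature (Boruta-style) relevance screen
#'
#' Each iteration appends a permuted copy of every predictor, fits a
#' random forest, and records whether each real predictor's permutation
#' importance exceeds the maximum shadow importance. Predictors are
#' confirmed or rejected by two-sided binomial tests at level `alpha` with
#' Bonferroni correction across predictors; the rest are tentative.
#'
#' @param X data.frame of predictors.
#' @param y numeric response.
#' @param n_iter number of shadow iterations (>= 20; default 50).
#' @param alpha test level before Bonferroni correction (default 0.01).
#' @param seed integer seed.
#' @param params forest hyperparameters for the internal fits.
#' @return list of class `screen_report` with `kept` (confirmed),
#'   `tentative`, `dropped` (rejected, with reasons), `hits`, `n_iter`.
#' @export
boruta_screen <- function(X, y, n_iter = 50, alpha = 0.01, seed = 1,
                          params = rf_params(num_trees = 300)) {
  X <- check_model_matrix(X, y)
  if (n_iter < 20) stop("n_iter must be >= 20", call. = FALSE)
  if (stats::var(y) == 0) stop("y is constant", call. = FALSE)
  p <- ncol(X)
  hits <- stats::setNames(integer(p), names(X))
  for (it in seq_len(n_iter)) {
    set.seed(derive_seed(seed, paste0("boruta_", it)))
    shadow <- as.data.frame(lapply(X, sample))
    names(shadow) <- paste0("shadow_", names(X))
    fit <- ranger::ranger(
      x = cbind(X, shadow), y = y,
      num.trees = params$num_trees,
      mtry = if (is.null(params$mtry)) ceiling(2 * p / 3) else params$mtry,
      min.node.size = params$min_node_size,
      importance = "permutation",
      seed = derive_seed(seed, paste0("boruta_rf_", it)),
      num.threads = 1)
    imp <- fit$variable.importance
    shadow_max <- max(imp[names(shadow)])
    hits <- hits + as.integer(imp[names(X)] > shadow_max)
  }
  pvals <- vapply(hits, function(h) {
    stats::binom.test(h, n_iter, p = 0.5)$p.value
  }, numeric(1))
  padj <- pmin(pvals * p, 1)                    # Bonferroni
  confirmed <- names(X)[padj < alpha & hits > n_iter / 2]
  rejected <- names(X)[padj < alpha & hits < n_iter / 2]
  tentative <- setdiff(names(X), c(confirmed, rejected))
  dropped <- data.frame(
    variable = rejected,
    reason = sprintf("shadow hits %d/%d", hits[rejected], n_iter),
    stringsAsFactors = FALSE)
  structure(list(kept = confirmed, tentative = tentative, dropped = dropped,
                 hits = hits, n_iter = n_iter, alpha = alpha),
            class = "screen_report")
}

# First principal component of a standardised pair, sign-fixed so the
# larger-magnitude loading is positive; named "a..pca..b".
pair_pc1 <- function(a, b, name_a, name_b) {
  if (abs(stats::cor(a, b)) >= 1 - 1e-12) return(NULL)
  z <- cbind(scale(a), scale(b))
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  v <- pc$rotation[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  stats::setNames(list(drop(z %*% v)), paste0(name_a, "..pca..", name_b))
}

#' Screen candidate pairwise interaction features
#'
#' Each candidate interaction column is the first principal component of
#' the standardised pair, named `"a..pca..b"`. A candidate is kept iff
#' adding it to the forest improves out-of-bag R-squared by at least
#' `margin`. Because a single pair of forests measures that improvement
#' with Monte Carlo noise comparable to the margin, the comparison is
#' repeated over `n_reps` bootstrap replicates (paired in-bag samples) and
#' the mean improvement is used.
#'
#' @param X data.frame of predictors.
#' @param y numeric response.
#' @param candidate_pairs list of length-2 character vectors naming columns
#'   of `X`.
#' @param margin required OOB R-squared improvement (default 0.025, above the
#'   chance-improvement scale of OOB comparisons on a few hundred plots).
#' @param n_reps paired replicates per candidate (default 5).
#' @param params forest hyperparameters.
#' @param seed integer seed.
#' @return list with `columns` (data.frame of kept interaction columns,
#'   possibly zero-column), `report` (data.frame per candidate: name,
#'   delta_r2, kept), `base_r2`.
#' @export
suggest_interactions <- function(X, y, candidate_pairs, margin = 0.025,
                                 n_reps = 5, params = rf_params(),
                                 seed = 1) {
  X <- check_model_matrix(X, y)
  # pair the bootstrap within each replicate so the OOB R-squared
  # comparison is not dominated by resampling noise
  rep_seeds <- vapply(seq_len(n_reps), function(r)
    derive_seed(seed, paste0("ia_rep_", r)), integer(1))
  inbags <- lapply(rep_seeds, function(s)
    draw_inbag(nrow(X), params$num_trees, s))
  base_r2 <- vapply(seq_len(n_reps), function(r) {
    fit_rf(X, y, params = params, seed = rep_seeds[r],
           compute_importance = FALSE, inbag = inbags[[r]])$oob_r2
  }, numeric(1))
  cols <- list()
  rep_rows <- list()
  for (pair in candidate_pairs) {
    if (!all(pair %in% names(X))) {
      stop("candidate pair not in X: ", paste(pair, collapse = ", "),
           call. = FALSE)
    }
    pc <- pair_pc1(X[[pair[1]]], X[[pair[2]]], pair[1], pair[2])
    if (is.null(pc)) {
      warning("skipping perfectly collinear pair ",
              paste(pair, collapse = ", "))
      next
    }
    trial_r2 <- vapply(seq_len(n_reps), function(r) {
      fit_rf(cbind(X, as.data.frame(pc)), y, params = params,
             seed = rep_seeds[r], compute_importance = FALSE,
             inbag = inbags[[r]])$oob_r2
    }, numeric(1))
    delta <- mean(trial_r2 - base_r2)
    kept <- delta >= margin
    if (kept) cols <- c(cols, pc)
    rep_rows[[length(rep_rows) + 1]] <- data.frame(
      name = names(pc), delta_r2 = delta, kept = kept,
      stringsAsFactors = FALSE)
  }
  list(columns = if (length(cols)) as.data.frame(cols, optional = TRUE)
       else data.frame(row.names = seq_len(nrow(X))),
       report = if (length(rep_rows)) do.call(rbind, rep_rows) else
         data.frame(name = character(0), delta_r2 = numeric(0),
                    kept = logical(0)),
       base_r2 = mean(base_r2))
}

#' Draw a fixed set of bootstrap (in-bag) samples
#'
#' @param n number of observations.
#' @param num_trees number of trees.
#' @param seed integer seed.
#' @return list of per-tree in-bag count vectors, as accepted by ranger.
#' @export
draw_inbag <- function(n, num_trees, seed = 1) {
  set.seed(derive_seed(seed, "inbag"))
  lapply(seq_len(num_trees), function(t) {
    tabulate(sample.int(n, n, replace = TRUE), nbins = n)
  })
}

#' Random-forest regression with out-of-bag evaluation
#'
#' Bootstrap ensemble of regression trees. Out-of-bag predictions for each
#' plot come only from trees that did not sample it; `oob_r2 = 1 -
#' sum((y - yhat_oob)^2) / sum((y - mean(y))^2)`. Permutation importance
#' (mean increase in out-of-bag error when a predictor is permuted) is
#' floored at zero.
#'
#' @param X data.frame of predictors (no missing values).
#' @param y numeric response (richness scale; non-negative).
#' @param params forest hyperparameters, see [rf_params()].
#' @param seed integer seed.
#' @param compute_importance logical; skip importance for speed in
#'   intermediate fits.
#' @param inbag optional list of per-tree in-bag count vectors (as accepted
#'   by ranger); fixing it across fits pairs their bootstrap samples so
#'   that out-of-bag metrics can be compared with far less Monte Carlo
#'   noise.
#' @return list of class `rf_fit`: `model` (ranger object), `variables`,
#'   `oob_predictions`, `fitted_predictions`, `oob_r2`, `importance`
#'   (named, >= 0), `seed`, `params`, `X` (training frame, kept for
#'   partial dependence).
#' @export
fit_rf <- function(X, y, params = rf_params(), seed = 1,
                   compute_importance = TRUE, inbag = NULL) {
  X <- check_model_matrix(X, y)
  if (nrow(X) < 30) stop("need at least 30 observations", call. = FALSE)
  p <- ncol(X)
  mtry <- if (is.null(params$mtry)) ceiling(p / 3) else min(params$mtry, p)
  args <- list(
    x = X, y = y,
    num.trees = params$num_trees,
    mtry = mtry,
    min.node.size = params$min_node_size,
    importance = if (compute_importance) "permutation" else "none",
    seed = derive_seed(seed, "ranger"),
    num.threads = 1,
    oob.error = TRUE)
  if (!is.null(inbag)) args$inbag <- inbag
  fit <- do.call(ranger::ranger, args)
  oob <- fit$predictions
  if (anyNA(oob)) {
    # rows never out of bag (vanishingly rare at >= 100 trees)
    oob[is.na(oob)] <- mean(y)
  }
  fitted <- stats::predict(fit, X, num.threads = 1)$predictions
  oob_r2 <- 1 - sum((y - oob)^2) / sum((y - mean(y))^2)
  importance <- if (compute_importance) {
    pmax(fit$variable.importance, 0)
  } else NULL
  structure(list(model = fit, variables = names(X),
                 oob_predictions = oob, fitted_predictions = fitted,
                 oob_r2 = oob_r2, importance = importance,
                 seed = seed, params = params, X = X),
            class = "rf_fit")
}

#' Spatial random forest: forest augmented with Moran eigenvectors
#'
#' Computes MEM candidates from the plot distance matrix, ranks them by
#' Moran's I, and forward-selects eigenvectors into the predictor set while
#' the residual |Moran's I| (of out-of-bag residuals) decreases and the
#' out-of-bag R-squared does not drop more than `r2_tolerance` below the
#' non-spatial fit. If the non-spatial residuals already show no
#' significant autocorrelation, no eigenvector is added.
#'
#' @param X data.frame of environmental predictors.
#' @param y numeric response.
#' @param coords data.frame with `lon`, `lat` aligned with rows of `X`.
#' @param params forest hyperparameters.
#' @param truncation_km MEM truncation; default [pcnm_truncation()] of the
#'   distance matrix.
#' @param max_spatial_predictors cap on selected eigenvectors (default 10).
#' @param r2_tolerance allowed OOB R-squared drop (default 0.005).
#' @param n_perm permutations for the final residual Moran test (default
#'   499).
#' @param seed integer seed.
#' @return an `rf_fit` with extra fields: `mem` (selected eigenvector
#'   matrix, possibly zero-column), `mem_candidates`, `residual_moran`
#'   (list `I`, `p_value`), `residual_moran_nonspatial`,
#'   `residual_autocorrelation_ns` (TRUE if final p >= 0.05),
#'   `truncation_km`.
#' @export
fit_spatial_rf <- function(X, y, coords, params = rf_params(),
                           truncation_km = NULL,
                           max_spatial_predictors = 10,
                           r2_tolerance = 0.005, n_perm = 499, seed = 1) {
  X <- check_model_matrix(X, y)
  if (nrow(coords) != nrow(X)) {
    stop("coords must align with rows of X", call. = FALSE)
  }
  D <- haversine_matrix(coords)
  if (is.null(truncation_km)) truncation_km <- pcnm_truncation(D)
  mem <- mem_predictors(D, truncation_km)
  # residual autocorrelation is judged with the package's default local
  # weights (25th-percentile truncation), not the MEM connectivity radius,
  # which on multi-region networks spans the inter-continental bridges
  W <- spatial_weights(D)

  inbag <- draw_inbag(nrow(X), params$num_trees, seed)
  base <- fit_rf(X, y, params = params, seed = seed,
                 compute_importance = FALSE, inbag = inbag)
  res <- y - base$oob_predictions
  mi0 <- morans_i(res, W, n_perm = n_perm, seed = seed)

  selected <- character(0)
  cur_absI <- abs(mi0$I)
  if (mi0$p_value < 0.05) {
    ord <- order(mem$moran, decreasing = TRUE)
    candidates <- colnames(mem$vectors)[ord]
    candidates <- candidates[mem$moran[ord] > 0]
    for (cand in candidates) {
      if (length(selected) >= max_spatial_predictors) break
      trial_X <- cbind(X, as.data.frame(
        mem$vectors[, c(selected, cand), drop = FALSE]))
      trial <- fit_rf(trial_X, y, params = params, seed = seed,
                      compute_importance = FALSE, inbag = inbag)
      tres <- y - trial$oob_predictions
      tI <- abs(morans_i(tres, W, n_perm = 0)$I)
      if (tI < cur_absI && trial$oob_r2 >= base$oob_r2 - r2_tolerance) {
        selected <- c(selected, cand)
        cur_absI <- tI
      }
    }
  }

  final_X <- if (length(selected)) {
    cbind(X, as.data.frame(mem$vectors[, selected, drop = FALSE]))
  } else X
  final <- fit_rf(final_X, y, params = params, seed = seed,
                  compute_importance = TRUE, inbag = inbag)
  fres <- y - final$oob_predictions
  mi <- morans_i(fres, W, n_perm = n_perm, seed = seed)
  final$mem <- mem$vectors[, selected, drop = FALSE]
  final$mem_candidates <- mem
  final$env_variables <- names(X)
  final$residual_moran <- list(I = mi$I, p_value = mi$p_value)
  final$residual_moran_nonspatial <- list(I = mi0$I, p_value = mi0$p_value)
  final$residual_autocorrelation_ns <- mi$p_value >= 0.05
  final$truncation_km <- truncation_km
  final
}

#' Negative-binomial GLM for richness counts with region effects
#'
#' NB2 regression with log link; the dispersion is estimated by maximum
#' likelihood, alternating with the mean model (MASS::glm.nb). Region main
#' effects are always included; interactions between the listed variables
#' and region can be added. A spatial-cross-validation R-squared is
#' computed on the same folds as the forest models so the two approaches
#' are comparable.
#'
#' @param X data.frame of predictors.
#' @param y_counts integer response (non-negative counts; real-valued
#'   richness must be rounded upstream with an explicit flag).
#' @param region factor with >= 2 levels.
#' @param interaction_terms character vector of variables to interact with
#'   region (default none).
#' @param coords optional coordinates; enables spatial-CV R-squared.
#' @param folds optional precomputed fold labels (overrides `coords`).
#' @param k number of spatial folds if `coords` given (default 30).
#' @param seed integer seed (fold construction).
#' @return list of class `nb_fit`: `model`, `coefficients` (data.frame
#'   term/estimate/se/z/p), `theta`, `cv_r2`, `cv_predictions`, `folds`.
#' @export
fit_nb_glm <- function(X, y_counts, region, interaction_terms = NULL,
                       coords = NULL, folds = NULL, k = 30, seed = 1) {
  X <- check_model_matrix(X, y_counts)
  if (any(y_counts < 0) || any(y_counts != round(y_counts))) {
    stop("y_counts must be non-negative integers; round richness upstream ",
         "with an explicit flag", call. = FALSE)
  }
  region <- as.factor(region)
  if (nlevels(region) < 2) stop("region needs >= 2 levels", call. = FALSE)
  # explicit dummy and interaction columns (rather than factor terms) so
  # spatial-CV folds that drop a whole region still yield defined
  # predictions: the aliased coefficient is NA and contributes zero
  dat <- cbind(X, data.frame(.y = as.integer(y_counts)))
  dummies <- character(0)
  for (lvl in levels(region)[-1]) {
    nm <- paste0("region", make.names(lvl))
    dat[[nm]] <- as.numeric(region == lvl)
    dummies <- c(dummies, nm)
    for (v in interaction_terms) {
      inm <- paste0(v, ".x.", nm)
      dat[[inm]] <- X[[v]] * dat[[nm]]
      dummies <- c(dummies, inm)
    }
  }
  rhs <- c(names(X), dummies)
  form <- stats::reformulate(rhs, response = ".y")
  # in the Poisson limit the ML dispersion diverges and glm.nb can fail
  # outright; fall back to the nested Poisson fit with theta = Inf
  poisson_limit <- FALSE
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(form, data = dat, maxit = 100)),
    error = function(e) {
      poisson_limit <<- TRUE
      suppressWarnings(stats::glm(form, data = dat,
                                  family = stats::poisson()))
    })
  if (poisson_limit) fit$theta <- Inf
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      z = sm[, 3], p = sm[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)

  cv_r2 <- NA_real_
  cv_pred <- NULL
  if (is.null(folds) && !is.null(coords)) {
    folds <- spatial_folds(coords, k = min(k, nrow(X)), seed = seed)
  }
  if (!is.null(folds)) {
    cv_pred <- rep(NA_real_, nrow(dat))
    for (fo in unique(folds)) {
      test <- folds == fo
      ffit <- tryCatch(
        suppressWarnings(MASS::glm.nb(form, data = dat[!test, , drop = FALSE],
                                      maxit = 100)),
        error = function(e)
          suppressWarnings(stats::glm(form, data = dat[!test, , drop = FALSE],
                                      family = stats::poisson())))
      cv_pred[test] <- suppressWarnings(
        stats::predict(ffit, newdata = dat[test, , drop = FALSE],
                       type = "response"))
    }
    y <- dat$.y
    cv_r2 <- 1 - sum((y - cv_pred)^2) / sum((y - mean(y))^2)
  }
  structure(list(model = fit, coefficients = coefs, theta = fit$theta,
                 dispersion_diverged = poisson_limit,
                 cv_r2 = cv_r2, cv_predictions = cv_pred, folds = folds),
            class = "nb_fit")
}

#' PCA of the environmental matrix
#'
#' Columns are standardised and decomposed by SVD. The sign convention
#' makes the largest-magnitude entry of each loading vector positive.
#'
#' @param X data.frame (>= 2 variables, >= 3 plots, no constant column).
#' @return list of class `env_pca`: `scores`, `loadings`,
#'   `variance_fraction` (sums to 1), `sdev`.
#' @export
pca_env <- function(X) {
  X <- check_model_matrix(X)
  if (ncol(X) < 2 || nrow(X) < 3) {
    stop("need >= 2 variables and >= 3 plots", call. = FALSE)
  }
  const <- names(X)[vapply(X, function(c) stats::var(c) == 0, logical(1))]
  if (length(const)) {
    stop("constant column(s): ", paste(const, collapse = ", "),
         call. = FALSE)
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(pr$rotation))) {
    v <- pr$rotation[, j]
    if (v[which.max(abs(v))] < 0) {
      pr$rotation[, j] <- -v
      pr$x[, j] <- -pr$x[, j]
    }
  }
  structure(list(scores = pr$x, loadings = pr$rotation,
                 variance_fraction = pr$sdev^2 / sum(pr$sdev^2),
                 sdev = pr$sdev),
            class = "env_pca")
}

#' Partial-dependence curve of a fitted forest
#'
#' Mean prediction over the training rows with one predictor clamped to
#' each grid value. A subset of rows (e.g. one region) gives a conditional
#' curve.
#'
#' @param fit an `rf_fit`.
#' @param variable predictor name (must be in the training set).
#' @param grid numeric grid; default 25 points across the observed range.
#' @param rows optional integer/logical subset of training rows.
#' @return data.frame `value`, `yhat`, `extrapolated`.
#' @export
partial_dependence <- function(fit, variable, grid = NULL, rows = NULL) {
  stopifnot(inherits(fit, "rf_fit"))
  if (!variable %in% fit$variables) {
    stop("'", variable, "' is not a training variable", call. = FALSE)
  }
  X <- fit$X
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  obs_rng <- range(fit$X[[variable]])
  if (is.null(grid)) grid <- seq(obs_rng[1], obs_rng[2], length.out = 25)
  yhat <- vapply(grid, function(g) {
    Xg <- X
    Xg[[variable]] <- g
    mean(stats::predict(fit$model, Xg, num.threads = 1)$predictions)
  }, numeric(1))
  data.frame(value = grid, yhat = yhat,
             extrapolated = grid < obs_rng[1] | grid > obs_rng[2])
}
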