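# Leave-one-category-out driver attribution. Environmental variables are
# grouped into six categories (E1 temperature, E2 precipitation, E3 growing
# season, E4 solar radiation, E5 soil, E6 topography). The model is refit
# without each category in turn; the relative change in the per-plot
# prediction measures that category's influence. A plot is attributed to
# the category with the largest relative sensitivity provided it reaches
# the 1/7 threshold; otherwise it is labelled E7, co-limitation, meaning no
# single type of environmental factor dominates there.

CATEGORY_LEVELS <- c("E1", "E2", "E3", "E4", "E5", "E6")
LABEL_LEVELS <- c(CATEGORY_LEVELS, "E7")

# Columns of X charged to category k: the category's own variables plus any
# "a..pca..b" interaction column with a parent in the category. MEM columns
# belong to no category and are never removed.
category_columns <- function(vars, category_map, k) {
  out <- character(0)
  for (v in vars) {
    if (grepl("..pca..", v, fixed = TRUE)) {
      parents <- strsplit(v, "..pca..", fixed = TRUE)[[1]]
      cats <- category_map[parents]
      if (any(!is.na(cats) & cats == k)) out <- c(out, v)
    } else if (!is.na(category_map[v]) && category_map[v] == k) {
      out <- c(out, v)
    }
  }
  out
}

#' Full-model per-plot predictions
#'
#' Fits the forest on all predictors and returns the per-plot out-of-bag
#' predictions (out-of-bag rather than in-bag, because in-bag forest fits
#' are near-interpolating and would shrink all sensitivities towards zero).
#'
#' @param X data.frame of predictors.
#' @param y numeric response.
#' @param params forest hyperparameters.
#' @param seed integer seed (shared by all refits).
#' @return list with `predictions` (Y_all) and `fit`.
#' @export
predict_full <- function(X, y, params = rf_params(), seed = 1) {
  fit <- fit_rf(X, y, params = params, seed = seed,
                compute_importance = FALSE)
  list(predictions = fit$oob_predictions, fit = fit)
}

#' Predictions with one driver category withheld
#'
#' Refits the model from scratch (same hyperparameters and seed policy) on
#' all predictors except those charged to category `k`, and returns the
#' out-of-bag predictions. Removing a category with no variables is a
#' no-op and returns the full-model predictions.
#'
#' @param X data.frame of predictors.
#' @param y numeric response.
#' @param category_map named character vector variable -> "E1".."E6".
#' @param k category to withhold.
#' @param params,seed as in [predict_full()].
#' @param y_all optional precomputed full-model predictions (used for the
#'   no-op case).
#' @return list with `predictions` (Y_-Ek), `removed` (columns withheld).
#' @export
predict_without <- function(X, y, category_map, k, params = rf_params(),
                            seed = 1, y_all = NULL) {
  if (!k %in% CATEGORY_LEVELS) {
    stop("unknown category: ", k, call. = FALSE)
  }
  removed <- category_columns(names(X), category_map, k)
  if (length(removed) == 0) {
    preds <- if (!is.null(y_all)) y_all else predict_full(X, y, params,
                                                          seed)$predictions
    return(list(predictions = preds, removed = character(0)))
  }
  keep <- setdiff(names(X), removed)
  if (length(keep) == 0) {
    stop("removing category ", k, " leaves no predictors", call. = FALSE)
  }
  fit <- fit_rf(X[keep], y, params = params, seed = seed,
                compute_importance = FALSE)
  list(predictions = fit$oob_predictions, removed = removed)
}

#' Relative sensitivity of predictions to a withheld category
#'
#' `R(Ek) = |Y_all - Y_-Ek| / Y_all`, elementwise per plot.
#'
#' @param y_all full-model predictions (must be > 0 everywhere).
#' @param y_minus predictions with the category withheld (vector, or a
#'   matrix/data.frame with one column per category).
#' @return same shape as `y_minus`: relative sensitivities (>= 0).
#' @export
relative_sensitivity <- function(y_all, y_minus) {
  bad <- which(y_all <= 0)
  if (length(bad)) {
    nm <- if (!is.null(names(y_all))) names(y_all)[bad] else as.character(bad)
    stop("non-positive full-model prediction for plot(s): ",
         paste(utils::head(nm, 5), collapse = ", "), call. = FALSE)
  }
  if (is.matrix(y_minus) || is.data.frame(y_minus)) {
    as.matrix(abs(y_minus - y_all) / y_all)
  } else {
    abs(y_all - y_minus) / y_all
  }
}

#' Classify the dominant driver category of each plot
#'
#' The category with the highest relative sensitivity, provided it meets
#' the threshold (default 1/7), best explains that plot's richness; ties
#' are broken by the fixed order E1 to E6. If all six sensitivities fall
#' below the threshold the plot is labelled E7 (co-limitation).
#'
#' @param R matrix/data.frame of relative sensitivities with columns
#'   "E1".."E6" (plots in rows).
#' @param threshold dominance threshold (default 1/7).
#' @return factor of labels with levels E1..E7.
#' @export
classify_dominant <- function(R, threshold = 1 / 7) {
  R <- as.matrix(R)
  if (!all(CATEGORY_LEVELS %in% colnames(R))) {
    stop("R must have columns E1..E6", call. = FALSE)
  }
  R <- R[, CATEGORY_LEVELS, drop = FALSE]
  if (anyNA(R)) stop("NaN/NA in relative sensitivities", call. = FALSE)
  lab <- apply(R, 1, function(r) {
    if (max(r) < threshold) "E7" else CATEGORY_LEVELS[which.max(r)]
  })
  factor(lab, levels = LABEL_LEVELS)
}

#' Percentage of plots attributed to each category
#'
#' @param labels factor (or character) of labels in E1..E7.
#' @return named numeric vector of percentages over E1..E7, summing to 100.
#' @export
category_shares <- function(labels) {
  if (length(labels) == 0) stop("no labels", call. = FALSE)
  labels <- factor(labels, levels = LABEL_LEVELS)
  if (anyNA(labels)) stop("labels outside E1..E7", call. = FALSE)
  100 * table(labels) / length(labels)
}

#' Category shares along latitudinal and longitudinal bands
#'
#' Plots are binned into half-open bands `[lo, lo + band_deg)` anchored at
#' integer multiples of `band_deg` (a plot exactly on a boundary belongs to
#' the upper band). Empty bands are omitted; each band's shares sum to 100.
#'
#' @param labels factor of labels in E1..E7.
#' @param coords data.frame with `lon`, `lat`.
#' @param band_deg band width in degrees (default 2).
#' @return data.frame `axis` ("lat"/"lon"), `band_lo`, `category`, `pct`,
#'   `n` (plots in the band).
#' @export
band_profiles <- function(labels, coords, band_deg = 2) {
  check_scalar(band_deg, "band_deg", positive = TRUE)
  check_coords(coords)
  labels <- factor(labels, levels = LABEL_LEVELS)
  one_axis <- function(vals, axis) {
    lo <- floor(vals / band_deg) * band_deg
    out <- lapply(sort(unique(lo)), function(b) {
      sel <- lo == b
      sh <- category_shares(labels[sel])
      data.frame(axis = axis, band_lo = b,
                 category = names(sh), pct = as.numeric(sh),
                 n = sum(sel), stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  rbind(one_axis(coords$lat, "lat"), one_axis(coords$lon, "lon"))
}

#' Run the full leave-one-category-out sensitivity analysis
#'
#' Fits the full model, refits it six times with each category withheld,
#' computes per-plot relative sensitivities and dominant labels, and
#' aggregates shares and (if coordinates are given) latitudinal and
#' longitudinal band profiles.
#'
#' @param X data.frame of predictors (environmental variables, optional
#'   interaction and MEM columns).
#' @param y numeric response (estimated richness).
#' @param category_map named character vector variable -> "E1".."E6";
#'   interaction columns inherit both parents' categories, MEM columns are
#'   never removed.
#' @param coords optional data.frame with `lon`, `lat` for the profiles.
#' @param threshold dominance threshold (default 1/7).
#' @param params forest hyperparameters.
#' @param seed integer seed shared by all refits.
#' @param band_deg band width for the profiles (default 2).
#' @return list of class `sensitivity_result`: `table` (per-plot
#'   data.frame: Y_all, Y_minus_E1..E6, R_E1..E6, dominant, threshold),
#'   `R` (matrix), `labels`, `shares`, `profiles`, `threshold`, `fit`.
#' @export
run_sensitivity <- function(X, y, category_map, coords = NULL,
                            threshold = 1 / 7, params = rf_params(),
                            seed = 1, band_deg = 2) {
  X <- check_model_matrix(X, y)
  full <- predict_full(X, y, params = params, seed = seed)
  y_all <- full$predictions
  y_minus <- matrix(NA_real_, nrow(X), length(CATEGORY_LEVELS),
                    dimnames = list(rownames(X), CATEGORY_LEVELS))
  removed <- list()
  for (k in CATEGORY_LEVELS) {
    pw <- predict_without(X, y, category_map, k, params = params,
                          seed = seed, y_all = y_all)
    y_minus[, k] <- pw$predictions
    removed[[k]] <- pw$removed
  }
  R <- relative_sensitivity(y_all, y_minus)
  colnames(R) <- CATEGORY_LEVELS
  labels <- classify_dominant(R, threshold)
  shares <- category_shares(labels)
  profiles <- if (!is.null(coords)) band_profiles(labels, coords, band_deg)
  else NULL
  tab <- data.frame(plot_id = if (!is.null(rownames(X))) rownames(X) else
    as.character(seq_len(nrow(X))),
    Y_all = y_all, stringsAsFactors = FALSE)
  for (k in CATEGORY_LEVELS) tab[[paste0("Y_minus_", k)]] <- y_minus[, k]
  for (k in CATEGORY_LEVELS) tab[[paste0("R_", k)]] <- R[, k]
  tab$dominant <- as.character(labels)
  tab$threshold <- threshold
  structure(list(table = tab, R = R, labels = labels, shares = shares,
                 profiles = profiles, threshold = threshold,
                 removed = removed, fit = full$fit),
            class = "sensitivity_result")
}

#' Export labelled plots as a GeoJSON FeatureCollection
#'
#' Writes one point Feature per plot with the dominant label and the six
#' relative sensitivities as properties.
#'
#' @param result a `sensitivity_result`.
#' @param coords data.frame with `lon`, `lat` aligned with the result.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_sensitivity_geojson <- function(result, coords, path) {
  stopifnot(inherits(result, "sensitivity_result"))
  check_coords(coords)
  tab <- result$table
  features <- lapply(seq_len(nrow(tab)), function(i) {
    props <- list(plot_id = tab$plot_id[i],
                  dominant = tab$dominant[i],
                  Y_all = tab$Y_all[i])
    for (k in CATEGORY_LEVELS) props[[paste0("R_", k)]] <- tab[[paste0("R_", k)]][i]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(coords$lon[i], coords$lat[i])),
         properties = props)
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
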