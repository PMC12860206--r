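# End-to-end orchestration: generate (or read) a plot network, estimate
# diversity, screen variables, fit the non-spatial and spatial forests and
# the negative-binomial GLM for all three richness measures (including
# thinning re-analyses), run the driver attribution, and write tables, a
# machine-readable metrics manifest and a log.

#' Pipeline run configuration
#'
#' @param mode "synthetic" (generate data from `generator`) or "csv" (read
#'   from `paths`).
#' @param generator a [generator_config()] (synthetic mode).
#' @param paths named list with `plots`, `abundance`, `environment`,
#'   `categories` CSV paths (csv mode).
#' @param target_coverage common coverage for rarefied richness; `NULL`
#'   uses the minimum plot coverage.
#' @param vif_threshold VIF screening threshold (default 10).
#' @param boruta_iter shadow-screen iterations (default 30).
#' @param rf forest hyperparameters, see [rf_params()].
#' @param truncation_km MEM truncation; `NULL` for the spanning-tree
#'   default.
#' @param folds_k number of spatial cross-validation folds (default 30).
#' @param thinning_km increasing positive thinning distances (default
#'   c(50, 100, 200)).
#' @param sensitivity_threshold dominance threshold (default 1/7).
#' @param seed master seed.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "csv"),
                       generator = generator_config(),
                       paths = NULL,
                       target_coverage = NULL,
                       vif_threshold = 10,
                       boruta_iter = 30,
                       rf = rf_params(),
                       truncation_km = NULL,
                       folds_k = 30,
                       thinning_km = c(50, 100, 200),
                       sensitivity_threshold = 1 / 7,
                       seed = 1,
                       out_dir = tempfile("richdrivers_run_")) {
  mode <- match.arg(mode)
  if (mode == "csv" && is.null(paths)) {
    stop("csv mode requires 'paths'", call. = FALSE)
  }
  if (folds_k < 2) stop("folds_k must be >= 2", call. = FALSE)
  if (length(thinning_km) &&
      (any(thinning_km <= 0) || is.unsorted(thinning_km, strictly = TRUE))) {
    stop("thinning_km must be positive and strictly increasing",
         call. = FALSE)
  }
  structure(list(mode = mode, generator = generator, paths = paths,
                 target_coverage = target_coverage,
                 vif_threshold = vif_threshold, boruta_iter = boruta_iter,
                 rf = rf, truncation_km = truncation_km, folds_k = folds_k,
                 thinning_km = thinning_km,
                 sensitivity_threshold = sensitivity_threshold,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# Stable hash of the configuration for the sidecar manifest.
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a plot-network dataset from CSV files
#'
#' Expects `plots.csv` (plot_id, lon, lat, region), `abundance.csv`
#' (plot_id, species_id, count), `environment.csv` (plot_id + one column
#' per variable) and `categories.csv` (variable, category). Extra columns
#' are accepted and ignored with a warning; referential problems are hard
#' errors naming the offending ids.
#'
#' @param paths named list/vector with entries `plots`, `abundance`,
#'   `environment`, `categories`.
#' @return list with `plots`, `abundance`, `env` (an `env_matrix`).
#' @export
read_plot_data <- function(paths) {
  need <- c("plots", "abundance", "environment", "categories")
  if (!all(need %in% names(paths))) {
    stop("paths must name: ", paste(need, collapse = ", "), call. = FALSE)
  }
  for (p in unlist(paths[need])) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  read1 <- function(path, req, label) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing_c <- setdiff(req, names(df))
    if (length(missing_c)) {
      stop(label, " is missing column(s): ",
           paste(missing_c, collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(names(df), req)
    if (length(extra) && label != "environment") {
      warning(label, ": ignoring extra column(s) ",
              paste(extra, collapse = ", "))
      df <- df[req]
    }
    df
  }
  plots <- read1(paths$plots, c("plot_id", "lon", "lat", "region"), "plots")
  abundance <- read1(paths$abundance, c("plot_id", "species_id", "count"),
                     "abundance")
  env_df <- read1(paths$environment, "plot_id", "environment")
  cats <- read1(paths$categories, c("variable", "category"), "categories")

  if (anyDuplicated(plots$plot_id)) {
    stop("duplicate plot ids in plots table", call. = FALSE)
  }
  dup <- duplicated(abundance[c("plot_id", "species_id")])
  if (any(dup)) {
    stop("duplicate (plot, species) rows: ",
         paste(utils::head(abundance$plot_id[dup], 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(abundance$count < 1 | abundance$count != round(abundance$count))) {
    stop("abundance counts must be positive integers", call. = FALSE)
  }
  orphan <- setdiff(abundance$plot_id, plots$plot_id)
  if (length(orphan)) {
    stop("abundance rows reference unknown plot(s): ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  no_env <- setdiff(plots$plot_id, env_df$plot_id)
  if (length(no_env)) {
    stop("plots missing environment: ",
         paste(utils::head(no_env, 5), collapse = ", "), call. = FALSE)
  }
  env_df <- env_df[match(plots$plot_id, env_df$plot_id), , drop = FALSE]
  vars <- setdiff(names(env_df), "plot_id")
  cmap_missing <- setdiff(vars, cats$variable)
  if (length(cmap_missing)) {
    stop("variables without a category: ",
         paste(cmap_missing, collapse = ", "), call. = FALSE)
  }
  X <- env_df[vars]
  rownames(X) <- env_df$plot_id
  env <- structure(list(
    X = X,
    category_map = stats::setNames(cats$category, cats$variable)[vars],
    plot_id = plots$plot_id,
    region = factor(plots$region)), class = "env_matrix")
  list(plots = plots, abundance = abundance, env = env)
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
  writeLines(msg, con)
  invisible(msg)
}

#' Run the full analysis pipeline
#'
#' Generates or reads the plot network, then computes: the per-plot
#' diversity table; an environmental PCA; VIF and shadow-feature screening
#' reports; non-spatial and spatial forest fits for the three richness
#' measures (observed, Fisher's alpha, coverage-standardised), on the full
#' network and on each thinned subset; linear regressions of predicted
#' versus estimated richness; negative-binomial GLMs with region
#' interactions and spatial-CV R-squared; and the leave-one-category-out
#' driver attribution. All tables, a metrics manifest
#' (`model_metrics.json`) and a log are written to the output directory.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the main in-memory results and
#'   `out_dir`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logc <- file(file.path(out, "run.log"), "w")
  on.exit(close(logc), add = TRUE)
  log_line(logc, "run_all start; seed=", config$seed,
           "; config_hash=", config_hash(config))
  stage <- function(name, expr) {
    log_line(logc, "stage: ", name)
    tryCatch(expr, error = function(e) {
      log_line(logc, "FAILED at stage ", name, ": ", conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  dat <- stage("data", {
    if (config$mode == "synthetic") {
      ds <- generate_dataset(config$generator)
      list(plots = ds$plots, abundance = ds$abundance, env = ds$env,
           truth = ds$truth)
    } else {
      read_plot_data(config$paths)
    }
  })
  plots <- dat$plots
  X <- dat$env$X
  cmap <- dat$env$category_map
  region <- dat$env$region
  coords <- plots[, c("lon", "lat")]
  seed <- config$seed

  div <- stage("diversity", diversity_table(dat$abundance,
                                            config$target_coverage))
  div <- div[match(plots$plot_id, div$plot_id), ]
  utils::write.csv(div, file.path(out, "diversity.csv"), row.names = FALSE)

  pca <- stage("pca", pca_env(X))
  utils::write.csv(
    data.frame(component = seq_along(pca$variance_fraction),
               variance_fraction = pca$variance_fraction),
    file.path(out, "pca_variance.csv"), row.names = FALSE)

  screen_vif <- stage("vif_screen", vif_screen(X, config$vif_threshold))
  # shadow screen against the primary response (coverage-standardised richness)
  screen_bor <- stage("boruta_screen",
                      boruta_screen(X, div$S_at_coverage,
                                    n_iter = config$boruta_iter,
                                    seed = seed))
  screen_df <- rbind(
    data.frame(screen = "vif", variable = screen_vif$kept, verdict = "kept",
               stringsAsFactors = FALSE),
    if (nrow(screen_vif$dropped))
      data.frame(screen = "vif", variable = screen_vif$dropped$variable,
                 verdict = screen_vif$dropped$reason),
    data.frame(screen = "boruta", variable = names(screen_bor$hits),
               verdict = ifelse(names(screen_bor$hits) %in% screen_bor$kept,
                                "confirmed",
                         ifelse(names(screen_bor$hits) %in%
                                  screen_bor$tentative,
                                "tentative", "rejected"))))
  utils::write.csv(screen_df, file.path(out, "screen_report.csv"),
                   row.names = FALSE)

  measures <- list(observed = div$S_obs,
                   fisher_alpha = div$fisher_alpha,
                   rarefied = div$S_at_coverage)
  folds <- spatial_folds(coords, k = min(config$folds_k, nrow(plots)),
                         seed = seed)

  thin_sets <- stage("thinning", {
    sets <- list(full = plots$plot_id)
    for (d in config$thinning_km) {
      sets[[paste0("thin_", d, "km")]] <-
        thin_points(plots, d, seed = derive_seed(seed, paste0("thin", d)))
    }
    sets
  })

  metrics <- list(seed = seed, config_hash = config_hash(config),
                  n_plots = nrow(plots),
                  pca_variance_fraction = as.numeric(pca$variance_fraction),
                  rf = list(), glm_nb = list(),
                  predicted_vs_estimated_r2 = list())

  fits <- list()
  stage("models", {
    for (mname in names(measures)) {
      y_full <- measures[[mname]]
      ok <- is.finite(y_full)
      for (sname in names(thin_sets)) {
        keep_ids <- thin_sets[[sname]]
        sel <- plots$plot_id %in% keep_ids & ok
        y <- y_full[sel]
        Xs <- X[sel, , drop = FALSE]
        cs <- coords[sel, , drop = FALSE]
        fr <- fit_rf(Xs, y, params = config$rf,
                     seed = derive_seed(seed, paste0("rf_", mname, sname)))
        fs <- fit_spatial_rf(Xs, y, cs, params = config$rf,
                             truncation_km = config$truncation_km,
                             seed = derive_seed(seed,
                                                paste0("srf_", mname, sname)))
        metrics$rf[[mname]][[sname]] <- list(
          n = sum(sel),
          oob_r2_nonspatial = fr$oob_r2,
          oob_r2_spatial = fs$oob_r2,
          n_spatial_predictors = ncol(fs$mem),
          residual_moran_I = fs$residual_moran$I,
          residual_moran_p = fs$residual_moran$p_value)
        utils::write.csv(
          data.frame(variable = names(fr$importance),
                     importance = as.numeric(fr$importance)),
          file.path(out, sprintf("importance_nonspatial_%s_%s.csv",
                                 mname, sname)), row.names = FALSE)
        utils::write.csv(
          data.frame(variable = names(fs$importance),
                     importance = as.numeric(fs$importance)),
          file.path(out, sprintf("importance_spatial_%s_%s.csv",
                                 mname, sname)), row.names = FALSE)
        if (sname == "full") {
          fits[[mname]] <- list(nonspatial = fr, spatial = fs)
          metrics$predicted_vs_estimated_r2[[mname]] <- list(
            nonspatial = summary(stats::lm(y ~ fr$oob_predictions))$r.squared,
            spatial = summary(stats::lm(y ~ fs$oob_predictions))$r.squared)
        }
      }
    }
  })

  stage("glm_nb", {
    for (mname in names(measures)) {
      y <- measures[[mname]]
      ok <- is.finite(y)
      rounded <- any(y[ok] != round(y[ok]))
      nb <- fit_nb_glm(X[ok, , drop = FALSE], round(y[ok]), region[ok],
                       interaction_terms = names(X),
                       folds = folds[ok], seed = seed)
      metrics$glm_nb[[mname]] <- list(cv_r2 = nb$cv_r2, theta = nb$theta,
                                       response_rounded = rounded)
      utils::write.csv(nb$coefficients,
                       file.path(out, sprintf("glm_nb_%s.csv", mname)),
                       row.names = FALSE)
    }
  })

  sens <- stage("sensitivity", {
    y <- measures$rarefied
    run_sensitivity(X, y, cmap, coords = coords,
                    threshold = config$sensitivity_threshold,
                    params = config$rf,
                    seed = derive_seed(seed, "sensitivity"))
  })
  utils::write.csv(sens$table, file.path(out, "sensitivity.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(category = names(sens$shares),
                              pct = as.numeric(sens$shares)),
                   file.path(out, "shares.csv"), row.names = FALSE)
  utils::write.csv(sens$profiles, file.path(out, "band_profiles.csv"),
                   row.names = FALSE)
  write_sensitivity_geojson(sens, coords,
                            file.path(out, "sensitivity.geojson"))
  metrics$sensitivity <- list(
    threshold = config$sensitivity_threshold,
    shares_pct = as.list(stats::setNames(as.numeric(sens$shares),
                                         names(sens$shares))))

  jsonlite::write_json(metrics, file.path(out, "model_metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(logc, "run_all done")
  invisible(list(out_dir = out, metrics = metrics, diversity = div,
                 pca = pca, screen = list(vif = screen_vif,
                                          boruta = screen_bor),
                 fits = fits, sensitivity = sens, data = dat))
}
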