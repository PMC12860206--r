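# Synthetic plot-network generator: coordinates in three tropical regions,
# spatially autocorrelated environmental fields grouped into six driver
# categories, and per-plot tree communities sampled from a Hoppe urn whose
# diversity parameter is a known function of the environment. Everything
# downstream (diversity estimation, spatial RF, driver attribution) can be
# scored against this ground truth.

#' Default environmental variable set
#'
#' Twenty-four variables in six driver categories, loosely named after the
#' bioclimatic, soil and topographic layers commonly used in tropical
#' vegetation modelling. Regional mean offsets (in marginal-sd units) put
#' most of the between-region separation on the moisture-related variables
#' and soil pH, so that an ordination of the generated fields separates the
#' regions along a moisture axis while overlapping elsewhere.
#'
#' Categories: E1 temperature, E2 precipitation, E3 growing season,
#' E4 solar radiation, E5 soil, E6 topography.
#'
#' @return data.frame with columns `name`, `category`, `sd`, and one offset
#'   column per default region (`Americas`, `Africa`, `Asia`).
#' @export
default_variables <- function() {
  v <- function(name, category, am, af, as_) {
    data.frame(name = name, category = category, sd = 1,
               Americas = am, Africa = af, Asia = as_,
               stringsAsFactors = FALSE)
  }
  rbind(
    v("bio01",            "E1",  0.0,  0.2, -0.2),
    v("bio03",            "E1",  0.3, -0.1, -0.2),
    v("bio05",            "E1",  0.0,  0.1,  0.0),
    v("bio06",            "E1",  0.1,  0.0, -0.1),
    v("bio12",            "E2",  0.5, -0.6,  0.4),
    v("bio14",            "E2",  0.6, -0.8,  0.9),
    v("bio15",            "E2", -0.5,  0.6, -0.6),
    v("hurs_range",       "E2", -0.4,  0.5, -0.5),
    v("cmi_mean",         "E2",  0.4, -0.5,  0.3),
    v("npp",              "E3",  0.3, -0.3,  0.2),
    v("gsl",              "E3",  0.2, -0.2,  0.1),
    v("gsp",              "E3",  0.2, -0.3,  0.2),
    v("rsds_mean",        "E4", -0.2,  0.3,  0.0),
    v("rsds_range",       "E4", -0.1,  0.2, -0.1),
    v("pet_penman_mean",  "E4", -0.3,  0.4, -0.2),
    v("phh2o",            "E5", -0.6,  0.5,  0.2),
    v("silt",             "E5",  0.1,  0.0,  0.3),
    v("clay",             "E5",  0.0,  0.1,  0.1),
    v("soc",              "E5",  0.1, -0.1,  0.0),
    v("nitrogen",         "E5",  0.1,  0.0,  0.0),
    v("elevation",        "E6",  0.0,  0.0,  0.2),
    v("tpi",              "E6",  0.0,  0.0,  0.0),
    v("ruggedness",       "E6",  0.1, -0.1,  0.2),
    v("tcurv",            "E6",  0.0,  0.0,  0.0)
  )
}

#' Ground-truth presets for the richness--environment law
#'
#' Three ready-made specifications of how the true log diversity parameter
#' depends on the environment:
#' \describe{
#'   \item{"single-category"}{one strong precipitation (E2) driver; the
#'     attribution stage should recover E2 as the dominant category.}
#'   \item{"two-category"}{a strong precipitation driver plus an opposing
#'     soil-pH effect -- the default study-like condition where moisture
#'     dominates but soil matters.}
#'   \item{"balanced-all"}{equal small weights on one variable from each of
#'     the six categories, so that no single category dominates and the
#'     expected attribution is co-limitation.}
#' }
#'
#' @param preset one of "single-category", "two-category", "balanced-all".
#' @param intercept intercept on the log scale (default `log(50)`).
#' @return list with elements `intercept` and `terms` (named numeric vector;
#'   a name of the form "a:b" denotes a product term).
#' @export
truth_preset <- function(preset = c("two-category", "single-category",
                                    "balanced-all"),
                         intercept = log(50)) {
  preset <- match.arg(preset)
  terms <- switch(preset,
    "single-category" = c(bio14 = 0.6),
    "two-category"    = c(bio14 = 0.30, phh2o = -0.22),
    "balanced-all"    = c(bio06 = 0.08, bio14 = 0.08, npp = 0.08,
                          rsds_mean = 0.08, phh2o = -0.08, tpi = 0.08)
  )
  list(intercept = intercept, terms = terms, preset = preset)
}

#' Configuration for the synthetic plot-network generator
#'
#' Defaults emulate a pantropical inventory network: 429 one-hectare plots
#' split 197/150/82 between the Americas, Africa and Asia, 24 spatially
#' autocorrelated environmental variables in six categories, and plots of a
#' few hundred stems each with a log-series-like abundance structure.
#'
#' @param n_plots_per_region named positive integers; names are region labels.
#' @param region_boxes named list of `c(lon_min, lon_max, lat_min, lat_max)`
#'   rectangles in WGS84 degrees, within the tropical belt.
#' @param variables data.frame as returned by [default_variables()].
#' @param spatial_range_km correlation length of the exponential covariance
#'   of the environmental fields (km).
#' @param truth_spec list as returned by [truth_preset()].
#' @param stems_mean,stems_sd mean and sd of per-plot stem counts; counts
#'   are rounded normals truncated at 50.
#' @param noise_sd residual sd on the log of the true diversity parameter.
#' @param seed master integer seed.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_plots_per_region = c(Americas = 197,
                                                    Africa = 150,
                                                    Asia = 82),
                             region_boxes = list(
                               Americas = c(-80, -45, -20, 10),
                               Africa   = c(8, 30, -10, 8),
                               Asia     = c(95, 150, -10, 20)),
                             variables = default_variables(),
                             spatial_range_km = 500,
                             truth_spec = truth_preset("two-category"),
                             stems_mean = 600,
                             stems_sd = 100,
                             noise_sd = 0.08,
                             seed = 1) {
  if (length(n_plots_per_region) < 1 || any(n_plots_per_region < 1) ||
      any(n_plots_per_region != round(n_plots_per_region))) {
    stop("n_plots_per_region must be positive integers", call. = FALSE)
  }
  if (is.null(names(n_plots_per_region)) ||
      !setequal(names(n_plots_per_region), names(region_boxes))) {
    stop("region names of n_plots_per_region and region_boxes must match",
         call. = FALSE)
  }
  for (r in names(region_boxes)) {
    b <- region_boxes[[r]]
    if (length(b) != 4 || b[1] >= b[2] || b[3] >= b[4]) {
      stop(sprintf("region box '%s' is degenerate (zero area)", r),
           call. = FALSE)
    }
    if (b[1] < -180 || b[2] > 180 || b[3] < -30 || b[4] > 30) {
      stop(sprintf("region box '%s' outside [-180,180] x [-30,30]", r),
           call. = FALSE)
    }
  }
  req <- c("name", "category", "sd", names(region_boxes))
  if (!is.data.frame(variables) || !all(req %in% names(variables))) {
    stop("'variables' must have columns name, category, sd and one offset ",
         "column per region", call. = FALSE)
  }
  if (anyDuplicated(variables$name)) {
    stop("duplicate variable names", call. = FALSE)
  }
  check_scalar(spatial_range_km, "spatial_range_km", positive = TRUE)
  check_scalar(stems_mean, "stems_mean")
  if (stems_mean < 50) stop("stems_mean must be >= 50", call. = FALSE)
  check_scalar(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  tv <- unique(unlist(strsplit(names(truth_spec$terms), ":", fixed = TRUE)))
  missing_v <- setdiff(tv, variables$name)
  if (length(missing_v)) {
    stop("truth_spec variables not in 'variables': ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  }
  structure(list(n_plots_per_region = n_plots_per_region,
                 region_boxes = region_boxes,
                 variables = variables,
                 spatial_range_km = spatial_range_km,
                 truth_spec = truth_spec,
                 stems_mean = stems_mean,
                 stems_sd = stems_sd,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate plot coordinates within the configured regions
#'
#' Plots are placed uniformly at random inside each region's bounding box.
#'
#' @param config a [generator_config()].
#' @return data.frame with columns `plot_id`, `lon`, `lat`, `region`.
#' @export
generate_coordinates <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(derive_seed(config$seed, "coords"))
  out <- lapply(names(config$n_plots_per_region), function(r) {
    n <- config$n_plots_per_region[[r]]
    b <- config$region_boxes[[r]]
    data.frame(
      plot_id = sprintf("%s_%03d", substr(toupper(r), 1, 2), seq_len(n)),
      lon = stats::runif(n, b[1], b[2]),
      lat = stats::runif(n, b[3], b[4]),
      region = r,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$region <- factor(out$region, levels = names(config$n_plots_per_region))
  # uniform draws collide with probability zero, but guarantee distinctness
  if (anyDuplicated(out[, c("lon", "lat")])) {
    dup <- duplicated(out[, c("lon", "lat")])
    out$lon[dup] <- out$lon[dup] + stats::runif(sum(dup), -1e-6, 1e-6)
  }
  out
}

#' Generate spatially autocorrelated environmental fields
#'
#' Each variable is a Gaussian random field over the plot locations with
#' exponential covariance `exp(-d / rho)` (d great-circle km, rho =
#' `spatial_range_km`), scaled to the variable's marginal sd and shifted by
#' region-specific mean offsets. Fields are simulated exactly by Cholesky
#' factorisation of the covariance matrix with a 1e-8 diagonal jitter.
#'
#' @param coords data.frame from [generate_coordinates()] (columns `plot_id`,
#'   `lon`, `lat`, `region`).
#' @param config a [generator_config()].
#' @return object of class `env_matrix`: list with `X` (data.frame of plots
#'   x variables), `category_map` (named character), `plot_id`, `region`.
#' @export
generate_environment <- function(coords, config) {
  stopifnot(inherits(config, "generator_config"))
  check_coords(coords)
  rho <- config$spatial_range_km
  check_scalar(rho, "spatial_range_km", positive = TRUE)
  vars <- config$variables
  if (!all(as.character(coords$region) %in% names(config$region_boxes))) {
    stop("coords contain regions not present in the config", call. = FALSE)
  }
  n <- nrow(coords)
  D <- haversine_matrix(coords)
  Sigma <- exp(-D / rho)
  diag(Sigma) <- diag(Sigma) + 1e-8
  L <- tryCatch(chol(Sigma), error = function(e) {
    stop("covariance matrix not positive definite after jitter: ",
         conditionMessage(e), call. = FALSE)
  })
  set.seed(derive_seed(config$seed, "environment"))
  X <- matrix(NA_real_, n, nrow(vars),
              dimnames = list(coords$plot_id, vars$name))
  off <- as.matrix(vars[, names(config$region_boxes), drop = FALSE])
  region_idx <- match(as.character(coords$region), colnames(off))
  for (j in seq_len(nrow(vars))) {
    z <- drop(crossprod(L, stats::rnorm(n)))    # marginal sd 1 by construction
    X[, j] <- z * vars$sd[j] + off[j, region_idx]
  }
  structure(list(X = as.data.frame(X),
                 category_map = stats::setNames(vars$category, vars$name),
                 plot_id = coords$plot_id,
                 region = coords$region),
            class = "env_matrix")
}

#' @export
as.data.frame.env_matrix <- function(x, ...) x$X

#' True diversity parameter as a known function of the environment
#'
#' Encodes the ground-truth richness--environment law:
#' `log(alpha_true) = intercept + sum(coef * variable)` (product terms allowed
#' via "a:b" names) plus Normal(0, noise_sd) residual noise.
#'
#' @param env an `env_matrix`.
#' @param truth_spec list with `intercept` and named `terms` (see
#'   [truth_preset()]).
#' @param noise_sd residual sd on the log scale.
#' @param seed integer seed for the residual noise.
#' @return list of class `synthetic_truth`: `alpha_true` (named positive
#'   vector), `driver_categories` (categories with nonzero weight),
#'   `log_alpha`.
#' @export
latent_alpha <- function(env, truth_spec, noise_sd = 0, seed = 1) {
  stopifnot(inherits(env, "env_matrix"))
  X <- env$X
  la <- rep(truth_spec$intercept, nrow(X))
  cats <- character(0)
  for (term in names(truth_spec$terms)) {
    co <- truth_spec$terms[[term]]
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% names(X))) {
      stop("truth_spec variable(s) missing from environment: ",
           paste(setdiff(parts, names(X)), collapse = ", "), call. = FALSE)
    }
    val <- Reduce(`*`, X[parts])
    la <- la + co * val
    if (co != 0) cats <- c(cats, env$category_map[parts])
  }
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, "latent_alpha"))
    la <- la + stats::rnorm(length(la), 0, noise_sd)
  }
  if (any(la > 20)) {
    stop("log alpha_true exceeds 20 (overflow); use smaller coefficients",
         call. = FALSE)
  }
  structure(list(alpha_true = stats::setNames(exp(la), env$plot_id),
                 log_alpha = la,
                 driver_categories = sort(unique(unname(cats)))),
            class = "synthetic_truth")
}

#' Expected species count of a Hoppe-urn (Ewens) sample
#'
#' Closed form `sum_{i=0}^{n-1} theta / (theta + i)`, evaluated via digamma
#' for speed.
#'
#' @param theta diversity parameter (> 0).
#' @param n_stems sample size.
#' @return expected number of species.
#' @export
ewens_expected_s <- function(theta, n_stems) {
  check_scalar(theta, "theta", positive = TRUE)
  theta * (digamma(theta + n_stems) - digamma(theta))
}

#' Sample a community from a Hoppe urn
#'
#' Sequential (Chinese-restaurant) sampling with parameter `theta`: stem
#' i+1 founds a new species with probability `theta / (theta + i)`, else
#' copies an existing stem chosen uniformly. This is the exchangeable
#' analogue of a log-series community and has the exact expected richness
#' given by [ewens_expected_s()].
#'
#' @param alpha_true diversity parameter theta (> 0).
#' @param n_stems number of stems (>= 1).
#' @param seed optional integer seed.
#' @return named integer vector of species counts summing to `n_stems`.
#' @export
sample_community <- function(alpha_true, n_stems, seed = NULL) {
  check_scalar(alpha_true, "alpha_true")
  if (alpha_true <= 0) stop("alpha_true must be > 0", call. = FALSE)
  if (n_stems < 1 || n_stems != round(n_stems)) {
    stop("n_stems must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_stems <- as.integer(n_stems)
  labels <- integer(n_stems)
  n_sp <- 0L
  u <- stats::runif(n_stems)
  for (i in seq_len(n_stems)) {
    if (u[i] < alpha_true / (alpha_true + i - 1)) {
      n_sp <- n_sp + 1L
      labels[i] <- n_sp
    } else {
      labels[i] <- labels[sample.int(i - 1L, 1L)]
    }
  }
  counts <- tabulate(labels, nbins = n_sp)
  stats::setNames(as.integer(counts), sprintf("sp%04d", seq_len(n_sp)))
}

#' Generate a complete synthetic dataset
#'
#' Composes coordinates, environmental fields, the ground-truth diversity
#' law and per-plot community sampling into one reproducible dataset.
#'
#' @param config a [generator_config()].
#' @param dir optional directory; if given, CSVs (`plots.csv`,
#'   `abundance.csv`, `environment.csv`, `categories.csv`) are written there.
#' @return list of class `synthetic_dataset`: `plots`, `abundance` (long
#'   data.frame plot_id/species_id/count), `env` (`env_matrix`), `truth`
#'   (with per-plot `expected_S` and `n_stems` added), `config`.
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  plots <- generate_coordinates(config)
  env <- generate_environment(plots, config)
  truth <- latent_alpha(env, config$truth_spec, config$noise_sd, config$seed)

  set.seed(derive_seed(config$seed, "stems"))
  n_stems <- pmax(50L, as.integer(round(
    stats::rnorm(nrow(plots), config$stems_mean, config$stems_sd))))

  ab <- vector("list", nrow(plots))
  for (i in seq_len(nrow(plots))) {
    counts <- sample_community(truth$alpha_true[[i]], n_stems[i],
                               seed = derive_seed(config$seed,
                                                  paste0("comm_", i)))
    ab[[i]] <- data.frame(plot_id = plots$plot_id[i],
                          species_id = names(counts),
                          count = as.integer(counts),
                          stringsAsFactors = FALSE)
  }
  abundance <- do.call(rbind, ab)
  rownames(abundance) <- NULL

  truth$n_stems <- stats::setNames(n_stems, plots$plot_id)
  truth$expected_S <- stats::setNames(
    mapply(ewens_expected_s, truth$alpha_true, n_stems), plots$plot_id)

  ds <- structure(list(plots = plots, abundance = abundance, env = env,
                       truth = truth, config = config),
                  class = "synthetic_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' Write a synthetic dataset as CSV files
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("plots.csv", "abundance.csv",
                            "environment.csv", "categories.csv"))
  utils::write.csv(ds$plots, paths[1], row.names = FALSE)
  utils::write.csv(ds$abundance, paths[2], row.names = FALSE)
  env_out <- cbind(data.frame(plot_id = ds$env$plot_id,
                              stringsAsFactors = FALSE), ds$env$X)
  utils::write.csv(env_out, paths[3], row.names = FALSE)
  utils::write.csv(data.frame(variable = names(ds$env$category_map),
                              category = unname(ds$env$category_map),
                              stringsAsFactors = FALSE),
                   paths[4], row.names = FALSE)
  invisible(paths)
}
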