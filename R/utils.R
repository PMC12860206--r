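# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stage tag
#'
#' Every stochastic stage of the pipeline draws its own seed from the run
#' seed so that stages can be re-run independently without perturbing each
#' other's random streams. The result is always a valid 32-bit integer.
#'
#' @param seed master integer seed.
#' @param tag character tag naming the stage (e.g. "coords", "stems").
#' @return an integer in [0, 2^31 - 1).
#' @keywords internal
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 65521
  # 48271 is the classic Lehmer multiplier; arithmetic stays exact in doubles
  as.integer((abs(as.double(seed)) * 48271 + h * 104729) %% 2147483647)
}

# Stop unless `x` is a single finite number.
check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# Validate a lon/lat coordinate table (data.frame with lon and lat columns).
check_coords <- function(coords) {
  if (!is.data.frame(coords) || !all(c("lon", "lat") %in% names(coords))) {
    stop("coordinates must be a data.frame with 'lon' and 'lat' columns",
         call. = FALSE)
  }
  if (anyNA(coords$lon) || anyNA(coords$lat)) {
    stop("coordinates contain missing values", call. = FALSE)
  }
  if (any(coords$lat < -90 | coords$lat > 90) ||
      any(coords$lon < -180 | coords$lon > 180)) {
    stop("coordinates outside [-180,180] x [-90,90]", call. = FALSE)
  }
  invisible(coords)
}
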