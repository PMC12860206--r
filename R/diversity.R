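# Per-plot diversity measures from abundance vectors: observed richness,
# Fisher's alpha, sample coverage, and coverage-standardised richness
# (rarefaction below the observed effort, Chao1-based extrapolation above).
# All estimators are implemented directly from their defining formulas.

# Summarise an abundance vector into the quantities every estimator needs.
abundance_stats <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0) stop("empty abundance vector", call. = FALSE)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("abundance counts must be positive integers", call. = FALSE)
  }
  list(counts = as.numeric(counts),
       S = length(counts),
       N = sum(counts),
       f1 = sum(counts == 1),
       f2 = sum(counts == 2))
}

#' Fisher's alpha from species and stem counts
#'
#' Solves the log-series defining relation `S = alpha * log(1 + N / alpha)`
#' for alpha by bracketing and bisection. The left-hand side minus the
#' right-hand side is strictly monotone in alpha, so the positive root is
#' unique whenever `1 <= S < N`.
#'
#' @param S number of species observed.
#' @param N number of stems (total count).
#' @param tol absolute tolerance of the root (default 1e-8).
#' @return Fisher's alpha (positive scalar).
#' @export
fisher_alpha <- function(S, N, tol = 1e-8) {
  check_scalar(S, "S")
  check_scalar(N, "N")
  if (S < 1 || S > N) stop("require 1 <= S <= N", call. = FALSE)
  if (S == N) {
    stop("degenerate all-singleton sample: Fisher's alpha has no finite root",
         call. = FALSE)
  }
  f <- function(a) a * log1p(N / a) - S
  lo <- 1e-8
  hi <- N * 10
  # f is increasing from ~0 (a -> 0) to N (a -> Inf); expand if unbracketed
  while (f(hi) < 0) hi <- hi * 10
  while (f(lo) > 0) lo <- lo / 10
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Sample coverage of an abundance vector
#'
#' The coverage estimator
#' `C_hat = 1 - (f1/N) * ((N-1) f1) / ((N-1) f1 + 2 f2)`,
#' i.e. the estimated fraction of the community's individuals belonging to
#' species already present in the sample. Returns exactly 1 when there are
#' no singletons.
#'
#' @param abund named (or unnamed) vector of species counts.
#' @return coverage in [0, 1].
#' @export
sample_coverage <- function(abund) {
  st <- abundance_stats(abund)
  if (st$f1 == 0) return(1)
  A <- (st$N - 1) * st$f1 / ((st$N - 1) * st$f1 + 2 * st$f2)
  1 - (st$f1 / st$N) * A
}

#' Expected richness at a given subsample size (rarefaction/extrapolation)
#'
#' For `m <= N` this is the classical hypergeometric rarefaction expectation
#' `S(m) = S_obs - sum_k C(N - n_k, m) / C(N, m)`; for `m > N` the
#' Chao1-based extrapolation
#' `S_obs + f0 * (1 - (1 - f1 / (N f0 + f1))^(m - N))` with
#' `f0 = ((N-1)/N) f1^2 / (2 f2)` (bias-corrected
#' `((N-1)/N) f1 (f1 - 1) / (2 (f2 + 1))` when `f2 = 0`).
#' Non-integer sizes are linearly interpolated between adjacent integers.
#'
#' @param abund vector of species counts.
#' @param m target sample size (>= 1; may exceed N).
#' @return expected species richness (real).
#' @export
richness_at_size <- function(abund, m) {
  st <- abundance_stats(abund)
  check_scalar(m, "m")
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (m != round(m)) {
    m0 <- floor(m)
    w <- m - m0
    return((1 - w) * richness_at_size(abund, m0) +
           w * richness_at_size(abund, m0 + 1))
  }
  if (m <= st$N) {
    # exp(lchoose) keeps the ratio stable for large N
    lratio <- lchoose(st$N - st$counts, m) - lchoose(st$N, m)
    return(st$S - sum(exp(lratio)))
  }
  if (st$f1 == 0) return(st$S)
  f0 <- if (st$f2 > 0) {
    (st$N - 1) / st$N * st$f1^2 / (2 * st$f2)
  } else {
    (st$N - 1) / st$N * st$f1 * (st$f1 - 1) / (2 * (st$f2 + 1))
  }
  if (f0 == 0) return(st$S)
  st$S + f0 * (1 - (1 - st$f1 / (st$N * f0 + st$f1))^(m - st$N))
}

# Expected coverage of a subsample of size m (integer), following the
# standard coverage-based rarefaction/extrapolation conventions.
coverage_at_size <- function(abund, m) {
  st <- abundance_stats(abund)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (m >= st$N) {
    if (st$f1 == 0) return(1)
    A <- if (st$f2 > 0) {
      (st$N - 1) * st$f1 / ((st$N - 1) * st$f1 + 2 * st$f2)
    } else if (st$f1 > 1) {
      (st$N - 1) * (st$f1 - 1) / ((st$N - 1) * (st$f1 - 1) + 2)
    } else {
      0
    }
    return(1 - (st$f1 / st$N) * A^(m - st$N + 1))
  }
  lratio <- lchoose(st$N - st$counts, m) - lchoose(st$N - 1, m)
  1 - sum((st$counts / st$N) * exp(lratio))
}

#' Coverage-standardised richness
#'
#' Returns the expected species richness of the plot at a common sample
#' coverage. If the target lies below the sample's own coverage the
#' size-to-coverage map is inverted (integer search with linear
#' interpolation between adjacent sizes) and hypergeometric rarefaction is
#' applied; above it, Chao1-based extrapolation is used. The result is
#' monotone non-decreasing in the target coverage.
#'
#' @param abund vector of species counts.
#' @param target_coverage coverage in (0, 1].
#' @return expected richness (attribute `"extrapolated_beyond_2n"` flags
#'   extrapolation past twice the observed sample size).
#' @export
richness_at_coverage <- function(abund, target_coverage) {
  st <- abundance_stats(abund)
  check_scalar(target_coverage, "target_coverage")
  if (target_coverage <= 0 || target_coverage > 1) {
    stop("target_coverage must be in (0, 1]", call. = FALSE)
  }
  chat <- sample_coverage(abund)
  flag <- FALSE

  if (target_coverage <= chat) {
    # invert the (integer) size -> coverage map, then interpolate
    if (target_coverage <= coverage_at_size(abund, 1)) {
      out <- 1
    } else {
      lo <- 1L
      hi <- as.integer(st$N)
      while (hi - lo > 1L) {               # smallest m with C(m) >= target
        mid <- (lo + hi) %/% 2L
        if (coverage_at_size(abund, mid) >= target_coverage) hi <- mid
        else lo <- mid
      }
      c_lo <- coverage_at_size(abund, lo)
      c_hi <- coverage_at_size(abund, hi)
      w <- if (c_hi > c_lo) (target_coverage - c_lo) / (c_hi - c_lo) else 1
      out <- (1 - w) * richness_at_size(abund, lo) +
        w * richness_at_size(abund, hi)
    }
  } else {
    # extrapolate: solve the closed-form extrapolated coverage for m
    A <- if (st$f2 > 0) {
      (st$N - 1) * st$f1 / ((st$N - 1) * st$f1 + 2 * st$f2)
    } else if (st$f1 > 1) {
      (st$N - 1) * (st$f1 - 1) / ((st$N - 1) * (st$f1 - 1) + 2)
    } else {
      0
    }
    if (st$f1 == 0 || A == 0 || target_coverage == 1) {
      # asymptote: observed plus the Chao1 estimate of undetected richness
      out <- richness_at_size(abund, st$N * 1e6)
      flag <- TRUE
    } else {
      m <- st$N - 1 +
        log((1 - target_coverage) * st$N / st$f1) / log(A)
      m <- max(m, st$N)
      flag <- m > 2 * st$N
      out <- richness_at_size(abund, m)
    }
  }
  attr(out, "extrapolated_beyond_2n") <- flag
  out
}

#' Per-plot diversity table
#'
#' Vectorised driver computing, for every plot in a long abundance table,
#' the observed richness, Fisher's alpha, sample coverage and the richness
#' standardised to a common coverage. The default target coverage is the
#' minimum across plots of each plot's own coverage, so that no plot needs
#' extrapolation; it can be overridden.
#'
#' @param abundance long data.frame with columns `plot_id`, `species_id`,
#'   `count`.
#' @param target_coverage common coverage in (0, 1]; `NULL` (default) uses
#'   the minimum plot coverage.
#' @return data.frame with one row per plot: `plot_id`, `S_obs`, `N`, `f1`,
#'   `f2`, `coverage`, `fisher_alpha`, `S_at_coverage`, `target_coverage`,
#'   `flags`. Plots where Fisher's alpha is undefined (S = N) are flagged,
#'   not dropped.
#' @export
diversity_table <- function(abundance, target_coverage = NULL) {
  req <- c("plot_id", "species_id", "count")
  if (!is.data.frame(abundance) || !all(req %in% names(abundance))) {
    stop("abundance must have columns plot_id, species_id, count",
         call. = FALSE)
  }
  by_plot <- split(abundance$count, abundance$plot_id)
  ids <- names(by_plot)
  cov <- vapply(by_plot, sample_coverage, numeric(1))
  if (is.null(target_coverage)) target_coverage <- min(cov)
  check_scalar(target_coverage, "target_coverage")

  rows <- lapply(seq_along(by_plot), function(i) {
    st <- abundance_stats(by_plot[[i]])
    flags <- character(0)
    fa <- if (st$S < st$N) fisher_alpha(st$S, st$N) else {
      flags <- c(flags, "fisher_alpha_undefined")
      NA_real_
    }
    sc <- richness_at_coverage(by_plot[[i]], target_coverage)
    if (isTRUE(attr(sc, "extrapolated_beyond_2n"))) {
      flags <- c(flags, "extrapolated_beyond_2N")
    }
    data.frame(plot_id = ids[i], S_obs = st$S, N = st$N,
               f1 = st$f1, f2 = st$f2, coverage = cov[i],
               fisher_alpha = fa, S_at_coverage = as.numeric(sc),
               target_coverage = target_coverage,
               flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
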