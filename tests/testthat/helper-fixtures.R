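# Shared fixtures built in code.

# A small plot network (62 plots, default variables) that keeps most tests
# fast while exercising all three regions.
small_config <- function(seed = 1, truth = truth_preset("two-category"),
                         noise_sd = 0.08) {
  generator_config(
    n_plots_per_region = c(Americas = 30, Africa = 20, Asia = 12),
    truth_spec = truth,
    stems_mean = 300, stems_sd = 50,
    noise_sd = noise_sd,
    seed = seed)
}

# Deterministic abundance vector fixtures.
abund_hand <- function() c(a = 1, b = 1, c = 2, d = 6)          # N=10,f1=2,f2=1
abund_small <- function() c(a = 10, b = 5, c = 3, d = 1, e = 1) # N=20

# Regular grid coordinates (degrees), handy for lattice fixtures.
grid_coords <- function(nx, ny, step_deg = 1) {
  g <- expand.grid(lon = seq_len(nx) * step_deg,
                   lat = seq_len(ny) * step_deg)
  g$plot_id <- sprintf("g%02d", seq_len(nrow(g)))
  g
}

# Rook-adjacency weights for an nx x ny grid (row-major order), matching
# grid_coords().
rook_weights <- function(nx, ny) {
  n <- nx * ny
  W <- matrix(0, n, n)
  idx <- function(i, j) (j - 1) * nx + i
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (i < nx) W[idx(i, j), idx(i + 1, j)] <- W[idx(i + 1, j), idx(i, j)] <- 1
    if (j < ny) W[idx(i, j), idx(i, j + 1)] <- W[idx(i, j + 1), idx(i, j)] <- 1
  }
  W
}
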