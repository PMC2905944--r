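# Small fixture builders shared across the suite. Everything is generated
# in code; no data files.

# flat v-voxel grid (v x 1 x 1) with unit voxels
flat_geom <- function(v, tr = 1) geometry(c(v, 1, 1), tr = tr)

full_mask <- function(geom) brain_mask(rep(TRUE, n_voxels(geom)), geom)

# run from a plain matrix on a flat grid
mat_run <- function(x, tr = 1) {
  g <- flat_geom(ncol(x), tr = tr)
  fmri_run(x, full_mask(g))
}

# z-style map from a numeric vector on a flat grid
vec_map <- function(vals, statistic = "z") {
  g <- flat_geom(length(vals))
  stat_map(vals, full_mask(g), statistic)
}

vec_binary <- function(include) {
  g <- flat_geom(length(include))
  binary_map(as.logical(include), full_mask(g))
}

# noise-free X = M C fixture with non-collinear smooth time courses and
# sparse-ish maps; returns list(run, m, c)
mc_fixture <- function(t = 60, v = 2000, n = 3, seed = 1) {
  set.seed(seed)
  tt <- seq_len(t)
  m <- sapply(seq_len(n), function(k)
    sin(2 * pi * k * tt / t + k) + 0.2 * cos(2 * pi * (k + 2) * tt / t))
  cmaps <- matrix(rnorm(n * v), n, v)
  cmaps[abs(cmaps) < 1] <- 0          # sparse, non-Gaussian sources
  x <- m %*% cmaps
  list(run = mat_run(x), m = m, c = cmaps)
}

# best |correlation| match of each true source against estimated maps
best_match_r <- function(true_maps, est_maps) {
  apply(abs(cor(t(true_maps), t(est_maps))), 1, max)
}
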