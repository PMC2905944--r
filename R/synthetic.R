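#' Specify one embedded signal component of a phantom
#'
#' A component is a set of voxels (given as 1-based linear grid indices, a
#' logical array, or built with [voxels_box()] / [voxels_triangle()] /
#' [voxels_sphere()]), a waveform, and an amplitude expressed as a
#' percentage of the per-voxel baseline mean. `per_subject_amplitude_sd`
#' (percentage points) and `spatial_jitter_voxels` control between-subject
#' variability when a group is generated.
#'
#' @param name component label.
#' @param voxels integer linear indices (or logical vector over the grid).
#' @param waveform a waveform spec from [square_wave()] or [block_hrf()], or
#'   a numeric vector of length t (used as-is after zero-mean/unit-peak
#'   normalization).
#' @param amplitude_pct signal amplitude, percent of the voxel baseline.
#' @param per_subject_amplitude_sd between-subject amplitude SD (percent
#'   points).
#' @param spatial_jitter_voxels max per-axis integer shift applied per
#'   subject.
#' @return An object of class `component_spec`.
#' @export
component_spec <- function(name, voxels, waveform, amplitude_pct,
                           per_subject_amplitude_sd = 0,
                           spatial_jitter_voxels = 0) {
  if (is.logical(voxels)) voxels <- which(voxels)
  voxels <- sort(unique(as.integer(voxels)))
  stopifnot(length(voxels) >= 1, amplitude_pct >= 0)
  structure(list(name = name, voxels = voxels, waveform = waveform,
                 amplitude_pct = amplitude_pct,
                 per_subject_amplitude_sd = per_subject_amplitude_sd,
                 spatial_jitter_voxels = as.integer(spatial_jitter_voxels)),
            class = "component_spec")
}

#' Region builders in voxel index space
#'
#' Return 1-based linear indices on a grid: an axis-aligned box, a filled
#' triangle rasterized in one axial slice, or a sphere around a centre.
#' Indices are 0-based voxel coordinates, matching the package convention.
#'
#' @param geom a [geometry()].
#' @param lo,hi inclusive 0-based corner coordinates (length 3) of a box.
#' @return Integer vector of linear indices.
#' @export
voxels_box <- function(geom, lo, hi) {
  stopifnot(all(lo >= 0), all(hi < geom$shape), all(lo <= hi))
  idx <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
  linear_index(geom, as.matrix(idx))
}

#' @param a,b,c triangle vertices, 0-based (i, j) within the slice.
#' @param slice 0-based slice index (third axis).
#' @rdname voxels_box
#' @export
voxels_triangle <- function(geom, a, b, c, slice) {
  stopifnot(slice >= 0, slice < geom$shape[3])
  grid <- expand.grid(i = 0:(geom$shape[1] - 1), j = 0:(geom$shape[2] - 1))
  # barycentric half-plane test, tolerant to edge points
  sign_area <- function(p1, p2, p) {
    (p2[1] - p1[1]) * (p$j - p1[2]) - (p2[2] - p1[2]) * (p$i - p1[1])
  }
  d1 <- sign_area(a, b, grid)
  d2 <- sign_area(b, c, grid)
  d3 <- sign_area(c, a, grid)
  has_neg <- d1 < 0 | d2 < 0 | d3 < 0
  has_pos <- d1 > 0 | d2 > 0 | d3 > 0
  inside <- !(has_neg & has_pos)
  ijk <- cbind(grid$i[inside], grid$j[inside], slice)
  linear_index(geom, ijk)
}

#' @param centre 0-based centre (length 3).
#' @param radius radius in voxels.
#' @rdname voxels_box
#' @export
voxels_sphere <- function(geom, centre, radius) {
  grid <- expand.grid(i = 0:(geom$shape[1] - 1),
                      j = 0:(geom$shape[2] - 1),
                      k = 0:(geom$shape[3] - 1))
  d2 <- (grid$i - centre[1])^2 + (grid$j - centre[2])^2 +
    (grid$k - centre[3])^2
  linear_index(geom, as.matrix(grid[d2 <= radius^2, ]))
}

# 0-based ijk matrix -> 1-based linear indices
linear_index <- function(geom, ijk) {
  ijk <- matrix(as.integer(ijk), ncol = 3)
  as.integer(ijk[, 1] + geom$shape[1] * (ijk[, 2] + geom$shape[2] * ijk[, 3]) + 1L)
}

#' Waveform specifications
#'
#' `square_wave()` is a zero-mean, unit-peak square wave (+1 during the
#' first half-period); `block_hrf()` is a block design convolved with the
#' Gaussian haemodynamic kernel of [build_task_regressor()], rescaled to
#' zero mean and unit peak.
#'
#' @param period_s period in seconds.
#' @param phase_s phase offset in seconds.
#' @return A waveform spec understood by [make_phantom()].
#' @export
square_wave <- function(period_s, phase_s = 0) {
  structure(list(type = "square_wave", period_s = period_s,
                 phase_s = phase_s), class = "waveform_spec")
}

#' @param onsets,durations block onsets and durations in seconds.
#' @rdname square_wave
#' @export
block_hrf <- function(onsets, durations) {
  structure(list(type = "block_hrf", onsets = onsets, durations = durations),
            class = "waveform_spec")
}

# realize a waveform as a zero-mean, unit-peak length-t vector
render_waveform <- function(wf, t, tr) {
  if (is.numeric(wf)) {
    stopifnot(length(wf) == t)
    w <- wf
  } else if (wf$type == "square_wave") {
    times <- (seq_len(t) - 1) * tr + wf$phase_s
    w <- ifelse((times %% wf$period_s) < wf$period_s / 2, 1, -1)
  } else if (wf$type == "block_hrf") {
    w <- build_task_regressor(wf$onsets, wf$durations, t, tr)$values
  } else stop("unknown waveform type")
  w <- w - mean(w)
  peak <- max(abs(w))
  if (peak == 0) stop("waveform is constant")
  w / peak
}

#' Generate a synthetic BOLD phantom with known ground truth
#'
#' Builds a 4D run as
#' `data(voxel, time) = baseline(voxel) * (1 + sum_k amp_k/100 * wave_k(time)
#' * [voxel in mask_k]) + noise`, with additive Gaussian noise of standard
#' deviation `noise_sd_pct/100 * baseline(voxel)` (optionally with AR(1)
#' temporal correlation). Waveforms are zero-mean, unit-peak, so
#' `amplitude_pct` is the peak signal excursion in percent of the voxel
#' baseline. Fully deterministic given `rng_seed`.
#'
#' @param grid a [geometry()].
#' @param baseline_mean scalar baseline intensity, or a vector over the
#'   grid for a spatially varying baseline.
#' @param components list of [component_spec()]s.
#' @param noise_sd_pct noise SD, percent of the voxel baseline.
#' @param t number of volumes.
#' @param rng_seed integer seed.
#' @param ar1 lag-1 autocorrelation of the noise (0 = white).
#' @return list with `run` (an [fmri_run()] over a full-grid mask) and
#'   `truth` (class `simulation_truth`: per-component [binary_map()]s,
#'   waveform [time_course()]s, amplitudes, overlap voxels shared by more
#'   than one component, and the seed).
#' @export
make_phantom <- function(grid, baseline_mean = 1000, components = list(),
                         noise_sd_pct = 0.5, t = 190, rng_seed = 1,
                         ar1 = 0) {
  stopifnot(t >= 2)
  v <- n_voxels(grid)
  baseline <- rep_len(as.numeric(baseline_mean), v)
  mask <- brain_mask(rep(TRUE, v), grid)
  old_rng <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng,
                                        envir = globalenv()))
  set.seed(as.integer(rng_seed %% .Machine$integer.max))
  data <- matrix(rep(baseline, each = t), t, v)
  masks <- list(); waves <- list(); amps <- numeric(0)
  occupancy <- integer(v)
  for (cs in components) {
    if (any(cs$voxels < 1 | cs$voxels > v))
      stop("component '", cs$name, "' extends outside the grid")
    w <- render_waveform(cs$waveform, t, grid$tr)
    sig <- outer(w, baseline[cs$voxels] * cs$amplitude_pct / 100)
    data[, cs$voxels] <- data[, cs$voxels] + sig
    inc <- logical(v); inc[cs$voxels] <- TRUE
    occupancy[cs$voxels] <- occupancy[cs$voxels] + 1L
    masks[[cs$name]] <- binary_map(inc, mask)
    waves[[cs$name]] <- time_course(w, label = cs$name)
    amps[cs$name] <- cs$amplitude_pct
  }
  if (noise_sd_pct > 0) {
    noise <- matrix(stats::rnorm(t * v), t, v)
    if (ar1 != 0) {
      for (i in 2:t) noise[i, ] <- ar1 * noise[i - 1, ] +
          sqrt(1 - ar1^2) * noise[i, ]
    }
    data <- data + noise * rep(baseline * noise_sd_pct / 100, each = t)
  }
  truth <- structure(list(component_masks = masks, waveforms = waves,
                          amplitudes = amps,
                          overlap_voxels = which(occupancy > 1L),
                          rng_seed = rng_seed),
                     class = "simulation_truth")
  list(run = fmri_run(data, mask,
                      provenance = sprintf("make_phantom(seed=%d)",
                                           rng_seed)),
       truth = truth)
}

#' Inject a signal component into an existing run
#'
#' Adds `amplitude_pct/100 * mean_i(voxel) * waveform(t)` to the selected
#' voxels; with a zero-mean waveform the per-voxel temporal mean is
#' unchanged.
#'
#' @param run an [fmri_run()].
#' @param mask a [binary_map()] on the run's mask selecting target voxels.
#' @param waveform a [time_course()] (or numeric vector) of length t.
#' @param amplitude_pct amplitude, percent of the per-voxel temporal mean.
#' @return The modified [fmri_run()].
#' @export
inject_signal <- function(run, mask, waveform, amplitude_pct) {
  w <- if (inherits(waveform, "time_course")) waveform$values else waveform
  stopifnot(length(w) == run$t)
  if (!same_mask(mask$mask, run$mask))
    stop("injection mask is not on the run's mask")
  cols <- which(mask$include)
  mu <- colMeans(run$data[, cols, drop = FALSE])
  run$data[, cols] <- run$data[, cols, drop = FALSE] +
    outer(w, mu * amplitude_pct / 100)
  run$provenance <- c(run$provenance,
                      sprintf("inject_signal(%d voxels, %g%%)",
                              length(cols), amplitude_pct))
  run
}

#' Generate a multi-subject phantom group
#'
#' Draws one phantom per subject from a shared template, with per-subject
#' amplitude perturbations (`per_subject_amplitude_sd`, truncated at zero)
#' and integer spatial jitter (`spatial_jitter_voxels`, a uniform per-axis
#' shift of the component's voxel set). Subject seeds are derived
#' deterministically from `rng_seed`.
#'
#' @param template list with the [make_phantom()] arguments `grid`,
#'   `baseline_mean`, `components`, `noise_sd_pct`, `t` (see
#'   [experiment1_config()] for an example of the shape).
#' @param n_subjects number of subjects.
#' @param rng_seed integer seed.
#' @return A list of `n_subjects` elements, each a list with `run` and
#'   `truth` as from [make_phantom()].
#' @export
make_group <- function(template, n_subjects, rng_seed = 1) {
  stopifnot(n_subjects >= 1)
  grid <- template$grid
  lapply(seq_len(n_subjects), function(s) {
    seed_s <- as.integer((rng_seed + 7919L * s) %% .Machine$integer.max)
    old_rng <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng,
                                          envir = globalenv()))
    set.seed(seed_s)
    comps <- lapply(template$components, function(cs) {
      if (cs$per_subject_amplitude_sd > 0)
        cs$amplitude_pct <- max(0, stats::rnorm(1, cs$amplitude_pct,
                                                cs$per_subject_amplitude_sd))
      if (cs$spatial_jitter_voxels > 0) {
        j <- cs$spatial_jitter_voxels
        shift <- sample(seq(-j, j), 3, replace = TRUE)
        ijk <- voxel_coords(grid, cs$voxels)
        ijk <- sweep(ijk, 2, shift, "+")
        ijk <- pmin(pmax(ijk, 0), rep(grid$shape - 1L, each = nrow(ijk)))
        cs$voxels <- sort(unique(linear_index(grid, ijk)))
      }
      cs
    })
    make_phantom(grid, template$baseline_mean, comps,
                 noise_sd_pct = template$noise_sd_pct, t = template$t,
                 rng_seed = as.integer((seed_s + 13L) %%
                                         .Machine$integer.max),
                 ar1 = template$ar1 %||% 0)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default signal-injection phantom configuration
#'
#' The shipped two-component fixture emulating the signal-injection
#' experiment: a compact "natural" occipital-like blob driven by a
#' block-design haemodynamic waveform, and an "artificial" component — a
#' square wave with a 60 s period (30 volumes at TR 2 s) and amplitude
#' 0.5% of the per-voxel baseline — spanning three triangular regions in
#' one slice plus one extra voxel placed inside the natural blob, so the
#' two components share exactly one voxel. White Gaussian noise with SD
#' 0.5% of baseline puts the artificial component at roughly 3% of the
#' total data variance.
#'
#' @param grid_shape spatial extents; default 24 x 24 x 8.
#' @param t number of volumes; default 190 (380 s at TR 2 s).
#' @param tr repetition time in seconds.
#' @param noise_sd_pct noise SD in percent of baseline.
#' @param artificial_amplitude_pct square-wave amplitude in percent.
#' @return A template list for [make_phantom()] / [make_group()], with the
#'   extra fields `natural_name` and `artificial_name`.
#' @export
experiment1_config <- function(grid_shape = c(24, 24, 8), t = 190, tr = 2,
                               noise_sd_pct = 0.5,
                               artificial_amplitude_pct = 0.5) {
  grid <- geometry(grid_shape, voxel_size = c(3, 3, 3), tr = tr)
  natural_vox <- voxels_sphere(grid, centre = c(6, 5, 4), radius = 2.6)
  overlap_vox <- linear_index(grid, cbind(6, 5, 4))
  tri1 <- voxels_triangle(grid, a = c(14, 2), b = c(22, 2), c = c(18, 9),
                          slice = 4)
  tri2 <- voxels_triangle(grid, a = c(2, 14), b = c(10, 14), c = c(6, 21),
                          slice = 4)
  tri3 <- voxels_triangle(grid, a = c(14, 14), b = c(22, 14), c = c(18, 21),
                          slice = 4)
  artificial_vox <- sort(unique(c(tri1, tri2, tri3, overlap_vox)))
  blocks <- seq(10, (t - 1) * tr - 30, by = 40)
  components <- list(
    component_spec("natural", natural_vox,
                   block_hrf(onsets = blocks, durations = 15),
                   amplitude_pct = 1.0),
    component_spec("artificial", artificial_vox,
                   square_wave(period_s = 60),
                   amplitude_pct = artificial_amplitude_pct))
  list(grid = grid, baseline_mean = 1000, components = components,
       noise_sd_pct = noise_sd_pct, t = t,
       natural_name = "natural", artificial_name = "artificial",
       overlap_voxel = overlap_vox)
}
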