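#' Seed specifications for the five hybrid FC methods
#'
#' A seed spec records how a seed was constructed from an IC map (or map
#' set): `SV` (the single peak voxel), `FV` (all voxels within 1 z-unit of
#' the peak), `MV` (an integer z threshold chosen so the voxel count is
#' closest to a target), `DRS` (dual regression against one map) or `DRA`
#' (dual regression against a whole component set, one map of interest).
#'
#' @name seed_spec
NULL

new_seed_spec <- function(method, ...) {
  structure(c(list(method = method), list(...)), class = "seed_spec")
}

#' @export
print.seed_spec <- function(x, ...) {
  cat(sprintf("seed_spec: %s", x$method))
  if (!is.null(x$voxel_mask))
    cat(sprintf(", %d voxels", sum(x$voxel_mask$include)))
  if (!is.null(x$threshold_used) && !is.na(x$threshold_used))
    cat(sprintf(", threshold z > %g", x$threshold_used))
  cat("\n")
  invisible(x)
}

#' Single-voxel seed at the map peak
#'
#' Picks the voxel with the highest value; ties are broken by the lowest
#' linear voxel index.
#'
#' @param map a nonconstant [stat_map()].
#' @return A `seed_spec` with method `"SV"`; `peak_index` is the position in
#'   the masked vector, `peak_linear` the 1-based full-grid linear index,
#'   `peak_world` the world-mm coordinates and `peak_value` the map value.
#' @export
peak_voxel <- function(map) {
  vals <- map$values
  if (max(vals) == min(vals)) stop("constant map has no peak")
  i <- which.max(vals)   # first maximum = lowest linear index on ties
  lin <- mask_indices(map$mask)[i]
  inc <- logical(map$mask$v); inc[i] <- TRUE
  new_seed_spec("SV", source_map = map,
                voxel_mask = binary_map(inc, map$mask,
                                        threshold_used = NA_real_),
                peak_index = i, peak_linear = lin,
                peak_world = drop(world_coords(map$mask$geometry, lin)),
                peak_value = vals[i])
}

#' Few-voxel seed: within one z-unit of the peak
#'
#' Keeps every voxel whose value is strictly greater than `max - 1`, so the
#' seed always contains the peak (e.g. a peak of 18.27 keeps voxels above
#' 17.27).
#'
#' @param map a nonconstant [stat_map()].
#' @return A `seed_spec` with method `"FV"` and the materialized voxel mask.
#' @export
few_voxel_seed <- function(map) {
  vals <- map$values
  if (max(vals) == min(vals)) stop("constant map has no peak")
  thr <- max(vals) - 1
  new_seed_spec("FV", source_map = map,
                voxel_mask = binary_map(vals > thr, map$mask,
                                        threshold_used = thr))
}

#' Many-voxel seed by integer z-threshold closest to a target count
#'
#' Evaluates candidate thresholds at every whole z-score from 1 up to
#' `ceiling(max)` and keeps the threshold whose suprathreshold voxel count
#' has the smallest absolute difference from `target_count`; ties go to the
#' lower threshold (more voxels).
#'
#' @param map a nonconstant [stat_map()].
#' @param target_count desired number of seed voxels (e.g. 100).
#' @return A `seed_spec` with method `"MV"`, the voxel mask and
#'   `threshold_used`.
#' @export
many_voxel_seed <- function(map, target_count = 100) {
  stopifnot(target_count >= 1)
  vals <- map$values
  if (max(vals) == min(vals)) stop("constant map has no peak")
  cand <- seq_len(max(1L, ceiling(max(vals))))
  counts <- vapply(cand, function(z) sum(vals > z), integer(1))
  ok <- counts > 0
  if (!any(ok)) stop("no integer threshold yields a nonempty seed")
  cand <- cand[ok]; counts <- counts[ok]
  dist <- abs(counts - target_count)
  best <- cand[dist == min(dist)]
  thr <- min(best)   # tie -> lower threshold, more voxels
  new_seed_spec("MV", source_map = map, target_count = target_count,
                voxel_mask = binary_map(vals > thr, map$mask,
                                        threshold_used = thr))
}

#' Seed spec for dual regression
#'
#' `DRS` regresses the data against a single spatial map; `DRA` against a
#' whole component set, with one component of interest.
#'
#' @param map a [stat_map()] (DRS).
#' @return A `seed_spec`.
#' @export
drs_seed <- function(map) new_seed_spec("DRS", source_map = map)

#' @param components a [component_set()] (DRA).
#' @param interest_index which component's FC map is of interest.
#' @rdname drs_seed
#' @export
dra_seed <- function(components, interest_index) {
  stopifnot(interest_index >= 1, interest_index <= n_components(components))
  new_seed_spec("DRA", source_set = components,
                interest_index = as.integer(interest_index))
}

#' ROI-average seed time course
#'
#' Unweighted mean of the run's series over the seed voxels, normalized to
#' zero mean and unit variance. If the averaged series is constant (e.g.
#' perfectly cancelling voxels) the returned course is all zeros with
#' attribute `degenerate = TRUE`.
#'
#' @param run an [fmri_run()].
#' @param seed an SV/FV/MV `seed_spec` whose mask voxels lie in the run mask.
#' @return A [time_course()].
#' @export
roi_timecourse <- function(run, seed) {
  stopifnot(inherits(seed, "seed_spec"),
            seed$method %in% c("SV", "FV", "MV"))
  keep <- seed$voxel_mask$include
  if (!same_grid(seed$voxel_mask$mask$geometry, run$geometry))
    stop("seed and run are on different grids")
  # map seed voxels (defined on the seed's mask) into run columns
  lin <- mask_indices(seed$voxel_mask$mask)[keep]
  cols <- match(lin, mask_indices(run$mask))
  if (anyNA(cols)) stop("seed voxels fall outside the run mask")
  series <- rowMeans(run$data[, cols, drop = FALSE])
  normalize_course(series, label = paste0(seed$method, " seed"))
}

normalize_course <- function(series, label = "", role = "interest") {
  mu <- mean(series)
  s <- stats::sd(series)
  if (s == 0) {
    tc <- time_course(rep(0, length(series)), label = label, role = role)
    attr(tc, "degenerate") <- TRUE
    return(tc)
  }
  time_course((series - mu) / s, label = label, role = role)
}

#' Stage-1 dual regression: spatial maps to time courses
#'
#' For every time point the data volume is regressed jointly on the supplied
#' spatial maps (each demeaned over the mask, plus an intercept), yielding
#' one time course per map. This is the spatial-then-temporal half of dual
#' regression; each returned course is normalized to zero mean, unit
#' variance.
#'
#' @param run an [fmri_run()].
#' @param maps a [stat_map()], a list of them, or a [component_set()] (whose
#'   raw maps are used).
#' @param interest_index when several maps are given, which course is
#'   labelled interest (others nuisance); default all interest.
#' @param max_condition condition-number tolerance for collinearity.
#' @return A list of [time_course()] objects.
#' @export
dual_regression_stage1 <- function(run, maps, interest_index = NULL,
                                   max_condition = 1e8) {
  if (inherits(maps, "component_set")) {
    m <- maps$maps
  } else if (inherits(maps, "stat_map")) {
    m <- matrix(maps$values, nrow = 1)
  } else {
    m <- do.call(rbind, lapply(maps, function(sm) sm$values))
  }
  stopifnot(ncol(m) == run$mask$v)
  design <- cbind(1, t(m - rowMeans(m)))     # v x (1 + n)
  if (kappa(crossprod(design), exact = TRUE) > max_condition^2)
    stop("seed maps are collinear")
  coef <- solve(crossprod(design), crossprod(design, t(run$data)))
  courses <- t(coef[-1, , drop = FALSE])     # t x n
  n <- ncol(courses)
  lapply(seq_len(n), function(i) {
    role <- if (is.null(interest_index) || i == interest_index)
      "interest" else "nuisance"
    normalize_course(courses[, i], label = paste0("stage1_map", i),
                     role = role)
  })
}

#' Write a seed spec to JSON
#'
#' Records the method, threshold, voxel indices (0-based), world-mm
#' coordinates and target count, enough to re-create the seed on the same
#' grid.
#'
#' @param seed a `seed_spec`.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
save_seed <- function(seed, path) {
  out <- list(method = seed$method)
  if (!is.null(seed$voxel_mask)) {
    lin <- mask_indices(seed$voxel_mask$mask)[seed$voxel_mask$include]
    out$voxel_index_0based <- voxel_coords(seed$voxel_mask$mask$geometry, lin)
    out$world_mm <- world_coords(seed$voxel_mask$mask$geometry, lin)
    out$threshold_used <- seed$voxel_mask$threshold_used
  }
  if (!is.null(seed$target_count)) out$target_count <- seed$target_count
  if (!is.null(seed$interest_index)) out$interest_index <- seed$interest_index
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
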