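#' Signal-injection experiment at desk scale
#'
#' End-to-end driver for the injected-signal validation study: generates the
#' two-component phantom of [experiment1_config()], normalizes it, runs
#' spatial ICA, matches the natural and artificial components against the
#' injection truth, thresholds the artificial component's z-map, and derives
#' seed-based FC maps from three single-voxel seeds — the overlap voxel
#' shared by both components, the natural component's peak, and the
#' artificial component's peak. Sensitivity and specificity of every
#' thresholded map are reported against the injected-voxel ground truth.
#'
#' @param config template from [experiment1_config()].
#' @param rng_seed integer seed driving both the phantom and the ICA.
#' @param n_components ICA model order (enough to cover both sources plus
#'   noise structure).
#' @param ic_threshold_z fixed z threshold for the IC maps.
#' @param fc_alpha familywise alpha for Bonferroni thresholding of FC maps.
#' @return list of class `experiment1_report`: per-map sensitivity and
#'   specificity, the matched component indices and correlations, and the
#'   intermediate objects (`phantom`, `components`, FC maps).
#' @export
experiment1 <- function(config = experiment1_config(), rng_seed = 1,
                        n_components = 8, ic_threshold_z = 3.1,
                        fc_alpha = 0.05) {
  phantom <- make_phantom(config$grid, config$baseline_mean,
                          config$components,
                          noise_sd_pct = config$noise_sd_pct,
                          t = config$t, rng_seed = rng_seed)
  run_n <- normalize_run(phantom$run)
  white <- pca_reduce(run_n, n_components)
  comps <- fastica_spatial(white, rng_seed = rng_seed)
  mask <- phantom$run$mask
  truth_art <- phantom$truth$component_masks[[config$artificial_name]]
  truth_nat <- phantom$truth$component_masks[[config$natural_name]]
  ref_art <- stat_map(as.numeric(truth_art$include), mask, "raw")
  ref_nat <- stat_map(as.numeric(truth_nat$include), mask, "raw")
  m_art <- match_component(comps, ref_art)
  m_nat <- match_component(comps, ref_nat)
  art_z <- stat_map(m_art$component$zmaps[1, ], mask, "z",
                    label = "artificial IC")
  nat_z <- stat_map(m_nat$component$zmaps[1, ], mask, "z",
                    label = "natural IC")
  ic_bin <- threshold_map(art_z, "fixed_z", ic_threshold_z)
  ic_stats <- sens_spec(ic_bin, truth_art)

  seed_at <- function(linear_voxel, label) {
    inc <- logical(mask$v); inc[match(linear_voxel, mask_indices(mask))] <- TRUE
    sp <- new_seed_spec("SV", source_map = NULL,
                        voxel_mask = binary_map(inc, mask))
    fc <- seed_fc(phantom$run, sp)
    fc$label <- label
    fc
  }
  overlap_fc <- seed_at(config$overlap_voxel, "overlap-voxel FC")
  nat_peak <- mask_indices(mask)[which.max(nat_z$values)]
  art_peak <- mask_indices(mask)[which.max(art_z$values)]
  natural_fc <- seed_at(nat_peak, "natural-peak FC")
  artificial_fc <- seed_at(art_peak, "artificial-peak FC")

  fc_stats <- lapply(list(overlap = overlap_fc, natural = natural_fc,
                          artificial = artificial_fc), function(fc) {
    bin <- threshold_map(fc, "bonferroni", fc_alpha)
    c(sens_spec(bin, truth_art),
      list(n_suprathreshold = sum(bin$include)))
  })
  structure(list(
    ic = c(ic_stats, list(component = m_art$index,
                          match_r = m_art$correlation,
                          natural_component = m_nat$index,
                          natural_match_r = m_nat$correlation,
                          threshold_z = ic_threshold_z)),
    fc = fc_stats,
    phantom = phantom, components = comps,
    maps = list(artificial_ic = art_z, natural_ic = nat_z,
                overlap_fc = overlap_fc, natural_fc = natural_fc,
                artificial_fc = artificial_fc),
    rng_seed = rng_seed), class = "experiment1_report")
}

#' @export
print.experiment1_report <- function(x, ...) {
  cat(sprintf("experiment1_report (seed %d)\n", x$rng_seed))
  cat(sprintf("  artificial IC (z > %g): sensitivity %.1f%%, specificity %.2f%%\n",
              x$ic$threshold_z, x$ic$sensitivity, x$ic$specificity))
  for (nm in names(x$fc))
    cat(sprintf("  %s-seed FC: sensitivity %.1f%%, specificity %.2f%%\n",
                nm, x$fc[[nm]]$sensitivity, x$fc[[nm]]$specificity))
  invisible(x)
}

#' Default multi-subject phantom configuration
#'
#' A block-paradigm group template for group-ICA comparisons: a left
#' "sensorimotor" blob and a "visual" blob, both driven by the block
#' haemodynamic waveform of a 10-block, 24-second paradigm (12 s rest +
#' 12 s task at TR 4 s), plus a square-wave "physiological" confound
#' component, with between-subject amplitude variability and one voxel of
#' spatial jitter.
#'
#' @param grid_shape,t,tr,noise_sd_pct as in [experiment1_config()].
#' @param n_subjects number of subjects the template is intended for.
#' @return A template list for [make_group()], with `task_onsets`,
#'   `task_durations` and `n_subjects` fields used by [experiment_group()].
#' @export
group_config <- function(grid_shape = c(14, 14, 4), t = 60, tr = 4,
                         noise_sd_pct = 1, n_subjects = 6) {
  grid <- geometry(grid_shape, voxel_size = c(4, 4, 4), tr = tr)
  onsets <- seq(12, by = 24, length.out = 10)
  durations <- 12
  motor <- component_spec(
    "motor", voxels_sphere(grid, c(3, 7, 2), 2.2),
    block_hrf(onsets, durations), amplitude_pct = 1.5,
    per_subject_amplitude_sd = 0.3, spatial_jitter_voxels = 1)
  # the visual stream follows its own block timing (32 s cycle) so the two
  # networks span a genuinely two-dimensional temporal subspace
  visual <- component_spec(
    "visual", voxels_sphere(grid, c(10, 3, 1), 2.2),
    block_hrf(seq(8, by = 32, length.out = 7), 16), amplitude_pct = 1.2,
    per_subject_amplitude_sd = 0.3, spatial_jitter_voxels = 1)
  confound <- component_spec(
    "confound", voxels_box(grid, c(0, 11, 3), c(13, 13, 3)),
    square_wave(period_s = 80), amplitude_pct = 1.0,
    per_subject_amplitude_sd = 0.2, spatial_jitter_voxels = 0)
  list(grid = grid, baseline_mean = 1000,
       components = list(motor, visual, confound),
       noise_sd_pct = noise_sd_pct, t = t,
       task_onsets = onsets, task_durations = durations,
       task_component = "motor", n_subjects = n_subjects)
}

#' Group comparison of the hybrid FC methods
#'
#' Simulates a subject group, runs temporal-concatenation group ICA,
#' selects the component of interest by matching against the voxelwise
#' mean of the subjects' task-GLM z maps (the group task reference), builds
#' the requested seeds from the group component, and evaluates each
#' method's per-subject FC maps against each subject's own task-GLM z map
#' with the criteria table of [run_comparison()] (Fisher-z correlation,
#' threshold-adjusted overlap, adjusted partial AUC). Back-reconstruction
#' rows can be added alongside the five seed methods.
#'
#' @param config template from [group_config()].
#' @param rng_seed integer seed.
#' @param n_components group ICA order.
#' @param methods subset of `c("SV","FV","MV","DRS","DRA","BR")`.
#' @param mv_target MV target voxel count.
#' @return list of class `experiment_group_report`: the `report`
#'   ([run_comparison()] output, plus BR rows if requested), the group
#'   model, matched component index and per-subject task maps.
#' @export
experiment_group <- function(config = group_config(), rng_seed = 1,
                             n_components = 5,
                             methods = c("SV", "FV", "MV", "DRS", "DRA"),
                             mv_target = 30) {
  subjects <- make_group(config, config$n_subjects, rng_seed = rng_seed)
  runs <- lapply(subjects, function(s) normalize_run(s$run))
  raw_runs <- lapply(subjects, function(s) s$run)
  mask <- runs[[1]]$mask
  task <- build_task_regressor(config$task_onsets, config$task_durations,
                               config$t, config$grid$tr)
  task_maps <- lapply(raw_runs, function(r) glm_fit(r, task)$zmaps[[1]])
  group_ref <- stat_map(rowMeans(vapply(task_maps, function(m) m$values,
                                        numeric(mask$v))),
                        mask, "z", label = "group task reference")
  model <- group_ica(runs, n_components, rng_seed = rng_seed)
  match <- match_component(model$group_components, group_ref)
  ic_map <- stat_map(model$group_components$zmaps[match$index, ], mask, "z",
                     label = sprintf("group IC%d", match$index))
  seeds <- list()
  for (m in setdiff(methods, "BR")) {
    seeds[[m]] <- switch(m,
      SV = peak_voxel(ic_map),
      FV = few_voxel_seed(ic_map),
      MV = many_voxel_seed(ic_map, mv_target),
      DRS = drs_seed(ic_map),
      DRA = dra_seed(model$group_components, match$index),
      stop("unknown method: ", m))
  }
  report <- run_comparison(raw_runs, task_maps, seeds)
  if ("BR" %in% methods) {
    br_rows <- lapply(seq_along(runs), function(s) {
      cs <- back_reconstruct(model, runs, s)
      fc <- stat_map(cs$zmaps[match$index, ], mask, "z", label = "BR")
      refbin <- threshold_map(task_maps[[s]], "bonferroni", 0.05)
      data.frame(method = "BR", subject = s,
                 r_reference = spatial_correlation(fc, task_maps[[s]])$r,
                 r_seed_source = spatial_correlation(fc, ic_map)$r,
                 overlap_pct =
                   threshold_adjusted_overlap(fc, refbin)$percent_covered,
                 pauc_adjusted = roc_pauc(fc, refbin)$pauc_adjusted)
    })
    report$table <- rbind(report$table, do.call(rbind, br_rows))
  }
  structure(list(report = report, model = model,
                 interest_index = match$index, match_r = match$correlation,
                 task_maps = task_maps, group_reference = group_ref,
                 seeds = seeds, rng_seed = rng_seed),
            class = "experiment_group_report")
}

#' @export
print.experiment_group_report <- function(x, ...) {
  cat(sprintf("experiment_group_report (seed %d): group IC%d (|r|=%.2f)\n",
              x$rng_seed, x$interest_index, x$match_r))
  print(x$report)
  invisible(x)
}
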