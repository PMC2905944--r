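#' Masked spatial correlation with Fisher z transform
#'
#' Pearson correlation of two maps over the voxels of a mask, plus the
#' variance-stabilizing Fisher z value `atanh(r)`. |r| is clipped to
#' `1 - 1e-12` before the transform so perfect correlations stay finite.
#'
#' @param a,b [stat_map()] objects on the same mask (or numeric vectors).
#' @param mask optional [brain_mask()]; defaults to the maps' shared mask.
#' @return list with elements `r` and `fisher_z`.
#' @export
spatial_correlation <- function(a, b, mask = NULL) {
  av <- if (inherits(a, "stat_map")) a$values else as.numeric(a)
  bv <- if (inherits(b, "stat_map")) b$values else as.numeric(b)
  stopifnot(length(av) == length(bv))
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("constant map: correlation undefined")
  r <- stats::cor(av, bv)
  list(r = r, fisher_z = atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)))
}

#' Threshold-adjusted overlap with a reference map
#'
#' Re-thresholds the FC map so that it keeps exactly as many voxels as the
#' reference (its k suprathreshold voxels), which makes the number of false
#' positives equal the number of false negatives, then reports the
#' percentage of the reference that is covered. Implemented by taking the
#' k highest-valued FC voxels; ties at the cut are included in ascending
#' linear-index order, so with a tied group of size g the FP/FN mismatch is
#' at most g - 1.
#'
#' @param fc a z-scale [stat_map()].
#' @param reference a nonempty, non-full [binary_map()] on the same mask.
#' @return list of class `overlap_result`: `percent_covered`,
#'   `adjusted_threshold` (value of the k-th kept voxel), `fp`, `fn`, `k`.
#' @export
threshold_adjusted_overlap <- function(fc, reference) {
  ref <- reference$include
  k <- sum(ref)
  v <- length(ref)
  if (k == 0 || k == v) stop("reference must be nonempty and non-full")
  vals <- fc$values
  # descending by value, ties included in ascending linear-index order
  ord <- order(-vals, seq_along(vals))
  keep <- logical(v)
  keep[ord[seq_len(k)]] <- TRUE
  inter <- sum(keep & ref)
  structure(list(percent_covered = 100 * inter / k,
                 adjusted_threshold = vals[ord[k]],
                 fp = sum(keep & !ref), fn = sum(!keep & ref), k = k),
            class = "overlap_result")
}

#' ROC partial AUC with a largest-acceptable false positive rate
#'
#' Sweeps a threshold over the FC values (descending, ties grouped) against
#' a binary reference, builds the ROC curve, and integrates the area between
#' false positive rates 0 and `lfpr` by the trapezoidal rule (interpolating
#' at `lfpr`). The partial area is also rescaled by `1 / lfpr` so a perfect
#' ranking scores 1 and a reversed ranking 0.
#'
#' @param fc a z-scale [stat_map()] (any strictly monotone rescaling of it
#'   gives the same result).
#' @param reference a [binary_map()] with at least one positive and one
#'   negative voxel.
#' @param lfpr largest acceptable false positive rate, in (0, 1].
#' @return list of class `roc_result`: `fpr`, `tpr`, `pauc_raw`,
#'   `pauc_adjusted`, `lfpr`.
#' @export
roc_pauc <- function(fc, reference, lfpr = 0.05) {
  stopifnot(lfpr > 0, lfpr <= 1)
  truth <- reference$include
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0 || nn == 0) stop("degenerate reference")
  vals <- fc$values
  ord <- order(vals, decreasing = TRUE)
  tv <- truth[ord]
  vv <- vals[ord]
  # group tied values: cumulative counts at the end of each tie group
  last_of_group <- c(vv[-1] != vv[-length(vv)], TRUE)
  ctp <- cumsum(tv)[last_of_group]
  cfp <- cumsum(!tv)[last_of_group]
  fpr <- c(0, cfp / nn)
  tpr <- c(0, ctp / np)
  pauc <- trapezoid_partial(fpr, tpr, lfpr)
  structure(list(fpr = fpr, tpr = tpr, pauc_raw = pauc,
                 pauc_adjusted = pauc / lfpr, lfpr = lfpr),
            class = "roc_result")
}

# area under piecewise-linear curve (x, y) on [0, xmax]
trapezoid_partial <- function(x, y, xmax) {
  area <- 0
  for (i in seq_len(length(x) - 1)) {
    x0 <- x[i]; x1 <- x[i + 1]
    if (x0 >= xmax) break
    if (x1 <= x0) next
    xe <- min(x1, xmax)
    y0 <- y[i]
    ye <- y0 + (y[i + 1] - y0) * (xe - x0) / (x1 - x0)
    area <- area + (xe - x0) * (y0 + ye) / 2
  }
  area
}

#' Sensitivity and specificity of a thresholded map against ground truth
#'
#' Sensitivity is the percentage of true voxels that are flagged;
#' specificity the percentage of non-true voxels left unflagged.
#'
#' @param predicted,truth [binary_map()] objects on the same mask.
#' @return list with `sensitivity` and `specificity`, both in percent.
#' @export
sens_spec <- function(predicted, truth) {
  p <- predicted$include; tr <- truth$include
  stopifnot(length(p) == length(tr))
  if (!any(tr)) stop("empty truth: sensitivity undefined")
  sens <- 100 * sum(p & tr) / sum(tr)
  spec <- if (all(tr)) 100 else 100 * sum(!p & !tr) / sum(!tr)
  list(sensitivity = sens, specificity = spec)
}

#' Criteria table across subjects and methods
#'
#' For every subject x method pair, computes the seed-based FC map and the
#' evaluation statistics against the subject's reference map: Fisher-z
#' spatial correlation with the reference and with the seed-source map,
#' threshold-adjusted overlap, and adjusted ROC partial AUC. Per-method
#' means and 95% confidence intervals are computed on the Fisher-z scale
#' and back-transformed.
#'
#' @param runs list of [fmri_run()] objects (one per subject).
#' @param references list of reference z [stat_map()]s, one per subject
#'   (e.g. each subject's task GLM map).
#' @param seeds named list of `seed_spec`s to evaluate (names become method
#'   labels); specs are shared across subjects (seed maps from a group
#'   decomposition).
#' @param ref_threshold list(method, alpha_or_z) used to binarize each
#'   subject's reference for overlap/PAUC; default Bonferroni 0.05.
#' @param lfpr largest acceptable FPR for the partial AUC.
#' @return list of class `comparison_report`: `table` (one row per
#'   method x subject) and `summary` (per-method back-transformed mean
#'   correlation with 95% CI, mean overlap, mean PAUC).
#' @export
run_comparison <- function(runs, references, seeds,
                           ref_threshold = list(method = "bonferroni",
                                                alpha_or_z = 0.05),
                           lfpr = 0.05) {
  stopifnot(length(runs) == length(references), length(seeds) >= 1)
  methods <- names(seeds)
  if (is.null(methods)) methods <- paste0("method", seq_along(seeds))
  rows <- list()
  for (s in seq_along(runs)) {
    ref <- references[[s]]
    refbin <- threshold_map(ref, ref_threshold$method,
                            ref_threshold$alpha_or_z)
    for (m in seq_along(seeds)) {
      fc <- seed_fc(runs[[s]], seeds[[m]])
      src <- seed_source_map(seeds[[m]], runs[[s]]$mask)
      rows[[length(rows) + 1]] <- data.frame(
        method = methods[m], subject = s,
        r_reference = spatial_correlation(fc, ref)$r,
        r_seed_source = spatial_correlation(fc, src)$r,
        overlap_pct = threshold_adjusted_overlap(fc, refbin)$percent_covered,
        pauc_adjusted = roc_pauc(fc, refbin, lfpr)$pauc_adjusted)
    }
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(methods, function(m) {
    d <- tab[tab$method == m, ]
    zc <- atanh(pmin(pmax(d$r_reference, -1 + 1e-12), 1 - 1e-12))
    n <- length(zc)
    se <- stats::sd(zc) / sqrt(n)
    ci <- mean(zc) + c(-1, 1) * stats::qt(0.975, n - 1) * se
    data.frame(method = m, mean_r_reference = tanh(mean(zc)),
               ci_lo = tanh(ci[1]), ci_hi = tanh(ci[2]),
               mean_overlap_pct = mean(d$overlap_pct),
               mean_pauc_adjusted = mean(d$pauc_adjusted))
  }))
  structure(list(table = tab, summary = summ), class = "comparison_report")
}

seed_source_map <- function(seed, mask) {
  if (!is.null(seed$source_map)) return(seed$source_map)
  cs <- seed$source_set
  stat_map(cs$zmaps[seed$interest_index, ], mask = mask,
           statistic = "z", label = "seed source")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
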