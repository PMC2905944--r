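#' Design matrix of regressor time courses
#'
#' @param columns list of [time_course()] objects (their `role` fields give
#'   the interest/nuisance labelling).
#' @return An object of class `design_matrix` with the t x s matrix `g`.
#' @export
design_matrix <- function(columns) {
  stopifnot(length(columns) >= 1)
  g <- vapply(columns, function(tc) tc$values,
              numeric(length(columns[[1]]$values)))
  g <- as.matrix(g)
  interest <- vapply(columns, function(tc) tc$role == "interest", logical(1))
  if (!any(interest)) stop("need at least one interest column")
  if (qr(g)$rank < ncol(g)) stop("design matrix is rank deficient")
  structure(list(g = g, t = nrow(g), columns = columns,
                 interest_flags = interest), class = "design_matrix")
}

#' Task regressor: boxcar convolved with a Gaussian haemodynamic kernel
#'
#' Builds a block-design boxcar sampled at the repetition time and convolves
#' it with a unit-area Gaussian kernel with its peak `peak_lag` seconds after
#' the stimulus and standard deviation `hrf_sigma` seconds (truncated at
#' +/- 4 sigma), the smooth delayed BOLD response model. The result is
#' normalized to zero mean, unit variance.
#'
#' @param block_onsets block onset times in seconds.
#' @param block_durations block durations in seconds (recycled).
#' @param t number of volumes.
#' @param tr repetition time in seconds.
#' @param peak_lag response peak delay in seconds.
#' @param hrf_sigma kernel standard deviation in seconds.
#' @return A [time_course()] of length `t`.
#' @export
build_task_regressor <- function(block_onsets, block_durations, t, tr,
                                 peak_lag = 5, hrf_sigma = 2.8) {
  if (length(block_onsets) == 0) stop("empty block list")
  stopifnot(all(block_durations > 0), t >= 2, tr > 0)
  block_durations <- rep_len(block_durations, length(block_onsets))
  times <- (seq_len(t) - 1) * tr
  box <- numeric(t)
  for (i in seq_along(block_onsets)) {
    on <- block_onsets[i]
    if (on < 0 || on >= t * tr) stop("block onset outside the run")
    box[times >= on & times < on + block_durations[i]] <- 1
  }
  if (all(box == 0))
    stop("boxcar is all zero: blocks shorter than the sampling grid")
  lags <- seq(0, peak_lag + 4 * hrf_sigma, by = tr)
  kern <- stats::dnorm(lags, mean = peak_lag, sd = hrf_sigma)
  kern[lags < peak_lag - 4 * hrf_sigma] <- 0
  kern <- kern / sum(kern)          # unit area at this sampling
  conv <- stats::convolve(box, rev(kern), type = "open")
  reg <- conv[seq_len(t)]
  tc <- normalize_course(reg, label = "task")
  if (isTRUE(attr(tc, "degenerate"))) stop("degenerate task regressor")
  tc
}

#' Voxelwise GLM fit with Gaussianised z maps
#'
#' Ordinary least squares of every voxel's series on the design (an
#' intercept is added internally), with t statistics `beta / SE(beta)`
#' Gaussianised to z by mapping the Student-t cumulative probability at the
#' residual degrees of freedom through the standard normal quantile
#' function; |z| is capped at 38 so noise-free fits stay finite.
#'
#' @param run an [fmri_run()].
#' @param design a [design_matrix()] (or a single [time_course()], promoted).
#' @param prewhiten apply one-step AR(1) prewhitening before the fit
#'   (estimated from the pooled lag-1 residual autocorrelation). Off by
#'   default; phantom noise is white, where OLS is exact.
#' @return A list of class `glm_result`: `betas` and `zmaps` (lists of
#'   [stat_map()], one per design column), `residual_variance` ([stat_map()])
#'   and `dof`.
#' @export
glm_fit <- function(run, design, prewhiten = FALSE) {
  if (inherits(design, "time_course")) design <- design_matrix(list(design))
  stopifnot(inherits(design, "design_matrix"), design$t == run$t)
  y <- run$data
  g <- cbind(`(intercept)` = 1, design$g)
  s <- ncol(g)
  if (s >= run$t) stop("more regressors than time points")
  if (prewhiten) {
    fit0 <- stats::lm.fit(g, y)
    res <- as.matrix(fit0$residuals)
    num <- sum(res[-1, ] * res[-nrow(res), ])
    den <- sum(res^2)
    rho <- if (den > 0) num / den else 0
    y <- y[-1, , drop = FALSE] - rho * y[-nrow(y), , drop = FALSE]
    g <- g[-1, , drop = FALSE] - rho * g[-nrow(g), , drop = FALSE]
  }
  gtg <- crossprod(g)
  xtx_inv <- tryCatch(solve(gtg), error = function(e)
    stop("rank-deficient design"))
  coef <- xtx_inv %*% crossprod(g, y)             # s x v
  resid <- y - g %*% coef
  dof <- nrow(y) - s
  sigma2 <- colSums(resid^2) / dof
  # numerically constant voxels carry no evidence (z = 0); numerically
  # perfect fits saturate (z = +/-cap); tolerances are relative so that
  # noise-free fixtures with round-off-level residuals behave exactly
  tss <- colSums(sweep(y, 2, colMeans(y), "-")^2)
  const_vox <- tss <= 1e-16 * colSums(y^2)
  perfect <- !const_vox & sigma2 * dof <= 1e-12 * tss
  zmaps <- betas <- vector("list", ncol(design$g))
  for (j in seq_len(ncol(design$g))) {
    jj <- j + 1L                                   # skip intercept
    se <- sqrt(sigma2 * xtx_inv[jj, jj])
    tt <- ifelse(se > 0, coef[jj, ] / se, 0)
    cj <- coef[jj, perfect]
    tt[perfect] <- ifelse(cj == 0, 0, sign(cj) * Inf)
    tt[const_vox] <- 0
    z <- t_to_z(tt, dof)
    lab <- design$columns[[j]]$label
    betas[[j]] <- stat_map(coef[jj, ], run$mask, "beta", label = lab)
    zmaps[[j]] <- stat_map(z, run$mask, "z", label = lab)
  }
  structure(list(betas = betas, zmaps = zmaps,
                 residual_variance = stat_map(sigma2, run$mask, "raw",
                                              label = "residual variance"),
                 dof = dof, interest_flags = design$interest_flags),
            class = "glm_result")
}

# Gaussianise t statistics: z = qnorm(pt(t, dof)), computed in log space for
# tail accuracy, capped at |z| = 38
t_to_z <- function(tt, dof, cap = 38) {
  z <- numeric(length(tt))
  pos <- tt >= 0
  if (any(pos)) {
    lp <- stats::pt(tt[pos], dof, lower.tail = FALSE, log.p = TRUE)
    z[pos] <- stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  }
  if (any(!pos)) {
    lp <- stats::pt(tt[!pos], dof, lower.tail = TRUE, log.p = TRUE)
    z[!pos] <- stats::qnorm(lp, lower.tail = TRUE, log.p = TRUE)
  }
  pmin(pmax(z, -cap), cap)
}

#' Threshold a z map
#'
#' One-tailed thresholding of a z-scale map: `fixed_z` keeps voxels above a
#' given z; `bonferroni` keeps voxels above the familywise-corrected cutoff
#' `qnorm(1 - alpha / v)`; `fdr` applies the Benjamini-Hochberg step-up
#' procedure to the one-tailed p-values.
#'
#' @param map a z-scale [stat_map()].
#' @param method `"fixed_z"`, `"bonferroni"` or `"fdr"`.
#' @param alpha_or_z the z cutoff (fixed_z) or alpha level (corrected).
#' @return A [binary_map()] with `threshold_used` set to the z cutoff
#'   actually applied (for fdr, the smallest surviving z, or `Inf` if none).
#' @export
threshold_map <- function(map, method = c("fixed_z", "bonferroni", "fdr"),
                          alpha_or_z = 0.05) {
  method <- match.arg(method)
  vals <- map$values
  v <- length(vals)
  if (method != "fixed_z" && (alpha_or_z <= 0 || alpha_or_z >= 1))
    stop("alpha must be in (0, 1)")
  if (method == "fixed_z") {
    thr <- alpha_or_z
    keep <- vals > thr
  } else if (method == "bonferroni") {
    thr <- stats::qnorm(1 - alpha_or_z / v)
    keep <- vals > thr
  } else {
    p <- stats::pnorm(vals, lower.tail = FALSE)
    keep <- stats::p.adjust(p, method = "BH") <= alpha_or_z & vals > 0
    thr <- if (any(keep)) min(vals[keep]) else Inf
  }
  binary_map(keep, map$mask, threshold_used = thr)
}

#' Seed-to-FC-map estimation for all five hybrid methods
#'
#' The two-step seed-based FC construction: derive a time course from the
#' seed (ROI average for SV/FV/MV; stage-1 dual regression for DRS/DRA),
#' then regress the whole run against it voxelwise and return the
#' Gaussianised z map. For DRA the GLM includes all component courses and
#' the interest component's z map is returned.
#'
#' @param run an [fmri_run()].
#' @param seed a `seed_spec` (see [peak_voxel()], [few_voxel_seed()],
#'   [many_voxel_seed()], [drs_seed()], [dra_seed()]).
#' @param nuisance optional list of additional nuisance [time_course()]s.
#' @return A z-scale [stat_map()]. The regressor used is attached as
#'   attribute `"seed_course"`.
#' @export
seed_fc <- function(run, seed, nuisance = NULL) {
  stopifnot(inherits(seed, "seed_spec"))
  if (seed$method %in% c("SV", "FV", "MV")) {
    course <- roi_timecourse(run, seed)
    if (isTRUE(attr(course, "degenerate")))
      stop("seed time course is degenerate (constant)")
    courses <- list(course)
    interest <- 1L
  } else if (seed$method == "DRS") {
    courses <- dual_regression_stage1(run, seed$source_map)
    interest <- 1L
  } else {
    courses <- dual_regression_stage1(run, seed$source_set,
                                      interest_index = seed$interest_index)
    interest <- seed$interest_index
  }
  if (!is.null(nuisance)) {
    nuisance <- lapply(nuisance, function(tc) {
      tc$role <- "nuisance"; tc
    })
    courses <- c(courses, nuisance)
  }
  fit <- glm_fit(run, design_matrix(courses))
  out <- fit$zmaps[[interest]]
  out$label <- paste0(seed$method, " FC")
  attr(out, "seed_course") <- courses[[interest]]
  out
}
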