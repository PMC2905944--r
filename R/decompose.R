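#' PCA whitening with dimensionality reduction
#'
#' Projects a (normalized) run into an N-dimensional whitened spatial
#' subspace. The linear model behind all decompositions here is
#' `X = M C + E`: the t x v data are split by PCA into a rank-N part `M C`
#' carrying structured signal and a residual `E` of predominately Gaussian
#' noise. The whitened scores are the N x v spatial matrix whose rows have
#' identity covariance.
#'
#' @param run an [fmri_run()] (demeaned; usually variance-normalized too).
#' @param n_components number of principal components to retain.
#' @return A list of class `whitened_data` with elements `scores` (N x v),
#'   `whitening` (N x t), `dewhitening` (t x N), `explained_variance`
#'   (fraction of total variance per kept component) and
#'   `residual_variance_fraction`.
#' @export
pca_reduce <- function(run, n_components) {
  x <- run$data
  t <- nrow(x); v <- ncol(x)
  n <- as.integer(n_components)
  if (n < 1 || n > min(t - 1, v))
    stop("n_components must be in [1, min(t-1, v)]")
  x <- sweep(x, 2, colMeans(x), "-")
  cov_t <- tcrossprod(x) / v            # t x t temporal covariance
  eig <- eigen(cov_t, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  total <- sum(vals)
  if (vals[n] <= total * 1e-12)
    stop("data rank is below n_components")
  u <- eig$vectors[, seq_len(n), drop = FALSE]
  d <- sqrt(vals[seq_len(n)])
  whitening <- t(u) / d                  # N x t
  dewhitening <- u * rep(d, each = t)    # t x N
  scores <- whitening %*% x              # N x v, rows ~ identity covariance
  structure(list(scores = scores, whitening = whitening,
                 dewhitening = dewhitening,
                 explained_variance = vals[seq_len(n)] / total,
                 residual_variance_fraction =
                   sum(vals[-seq_len(n)]) / total,
                 eigenvalues = vals, t = t, v = v),
            class = "whitened_data")
}

zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sds <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  sds[sds == 0] <- 1
  (m - mu) / sds
}

row_skewness <- function(m) {
  mu <- rowMeans(m)
  cm <- m - mu
  s2 <- rowMeans(cm^2)
  rowMeans(cm^3) / (s2^1.5 + (s2 == 0))
}

#' Paired time courses and spatial maps from a decomposition
#'
#' Container for the `M` (t x N time courses) and `C` (N x v maps) factors of
#' `X = M C + E`, with per-map z-scored versions and explained-variance
#' ordering.
#'
#' @param timecourses t x N matrix.
#' @param maps N x v matrix of raw spatial maps.
#' @param variance_fraction per-component fraction of total data variance.
#' @param seed_used RNG seed the estimate came from.
#' @param converged logical convergence flag.
#' @return An object of class `component_set`.
#' @export
component_set <- function(timecourses, maps, variance_fraction = NULL,
                          seed_used = NA_integer_, converged = TRUE) {
  timecourses <- as.matrix(timecourses)
  maps <- as.matrix(maps)
  stopifnot(ncol(timecourses) == nrow(maps))
  if (is.null(variance_fraction)) {
    ss <- colSums(timecourses^2) * rowSums(maps^2)
    variance_fraction <- ss / sum(ss)
  }
  structure(list(timecourses = timecourses, maps = maps,
                 zmaps = zscore_rows(maps),
                 variance_fraction = as.numeric(variance_fraction),
                 order = order(variance_fraction, decreasing = TRUE),
                 seed_used = seed_used, converged = converged),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("component_set: %d components, t=%d, v=%d%s\n",
              nrow(x$maps), nrow(x$timecourses), ncol(x$maps),
              if (isTRUE(x$converged)) "" else " (not converged)"))
  cat("  variance fractions:",
      paste(signif(x$variance_fraction, 3), collapse = " "), "\n")
  invisible(x)
}

n_components <- function(cs) nrow(cs$maps)

#' Fixed-point spatial ICA on whitened data
#'
#' Estimates N spatially independent source maps simultaneously by the
#' fixed-point iteration with a logcosh (tanh) contrast and symmetric
#' decorrelation, the variant where all components are updated at once
#' rather than deflated one at a time. Iteration stops when every
#' component's direction changes by less than `epsilon` (measured as
#' `1 - |<w_new, w_old>|`), or after `max_iter` sweeps; on non-convergence
#' the estimation restarts up to 3 times from seeds derived from `rng_seed`
#' and the best iterate is returned with `converged = FALSE`.
#'
#' Maps are z-scored; component sign is fixed so each z-map's skewness is
#' nonnegative; components are ordered by descending explained variance.
#' Identical seeds give identical output.
#'
#' @param white a [pca_reduce()] result.
#' @param epsilon convergence tolerance on the direction change.
#' @param max_iter maximum fixed-point sweeps per restart.
#' @param rng_seed integer seed for the random orthogonal initialisation.
#' @return A [component_set()]; `timecourses` are the dewhitened mixing
#'   columns, `maps` the estimated source maps.
#' @export
fastica_spatial <- function(white, epsilon = 1e-8, max_iter = 500,
                            rng_seed = 1) {
  stopifnot(epsilon > 0)
  n <- nrow(white$scores)
  best <- NULL
  for (restart in 0:3) {
    seed <- as.integer((rng_seed + 9973L * restart) %% .Machine$integer.max)
    fit <- fastica_once(white$scores, epsilon, max_iter, seed)
    if (is.null(best) || fit$delta < best$delta) best <- fit
    if (fit$converged) { best <- fit; break }
  }
  w <- best$w                                    # N x N unmixing (orthogonal)
  maps <- w %*% white$scores                     # N x v source maps
  mixing <- white$dewhitening %*% t(w)           # t x N time courses
  # resolve sign indeterminacy: nonnegative map skewness
  flip <- row_skewness(maps) < 0
  maps[flip, ] <- -maps[flip, , drop = FALSE]
  mixing[, flip] <- -mixing[, flip, drop = FALSE]
  ss <- colSums(mixing^2) * rowSums(maps^2)
  # fractions of *total* data variance: scale by the PCA-retained share
  vf <- ss / sum(ss) * (1 - white$residual_variance_fraction)
  ord <- order(vf, decreasing = TRUE)
  component_set(mixing[, ord, drop = FALSE], maps[ord, , drop = FALSE],
                variance_fraction = vf[ord], seed_used = rng_seed,
                converged = best$converged)
}

fastica_once <- function(scores, epsilon, max_iter, seed) {
  n <- nrow(scores); v <- ncol(scores)
  old_rng <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng,
                                        envir = globalenv()))
  set.seed(seed)
  w <- sym_decorrelate(matrix(stats::rnorm(n * n), n, n))
  delta <- Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    wx <- w %*% scores
    g <- tanh(wx)
    gp <- rowMeans(1 - g^2)
    w_new <- tcrossprod(g, scores) / v - gp * w
    w_new <- sym_decorrelate(w_new)
    delta <- max(1 - abs(rowSums(w_new * w)))
    w <- w_new
    if (delta < epsilon) { converged <- TRUE; break }
  }
  list(w = w, converged = converged, delta = delta)
}

# W <- (W W^T)^(-1/2) W, via symmetric eigendecomposition
sym_decorrelate <- function(w) {
  e <- eigen(tcrossprod(w), symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% (t(e$vectors) / sqrt(vals)) %*% w
}

#' Re-rank components by explained variance
#'
#' Reorders a component set so `variance_fraction` is nonincreasing, with
#' ties kept in their original order; fractions are recomputed against the
#' run so they sum to the PCA-retained variance fraction.
#'
#' @param components a [component_set()].
#' @param run the [fmri_run()] the components were estimated from.
#' @return The reordered [component_set()].
#' @export
rank_by_variance <- function(components, run) {
  x <- sweep(run$data, 2, colMeans(run$data), "-")
  total <- sum(x^2)
  ss <- colSums(components$timecourses^2) * rowSums(components$maps^2)
  vf <- ss / total
  ord <- order(-vf)   # stable for ties: order() breaks ties by index
  component_set(components$timecourses[, ord, drop = FALSE],
                components$maps[ord, , drop = FALSE],
                variance_fraction = vf[ord],
                seed_used = components$seed_used,
                converged = components$converged)
}

#' Group ICA by temporal concatenation
#'
#' Concatenates the (already normalized) runs along time, whitens, and runs
#' spatial ICA, keeping track of which rows belong to which subject so that
#' per-subject components can be back-reconstructed.
#'
#' @param runs list of [fmri_run()] objects sharing one mask.
#' @param n_components group model order.
#' @param rng_seed integer seed.
#' @param epsilon,max_iter passed to [fastica_spatial()].
#' @return A list of class `group_model` with `group_components`
#'   (a [component_set()]), `subject_ranges` and `subject_ids`.
#' @export
group_ica <- function(runs, n_components, rng_seed = 1,
                      epsilon = 1e-8, max_iter = 500) {
  cat_run <- concat_group(runs)
  white <- pca_reduce(cat_run, n_components)
  comps <- fastica_spatial(white, epsilon = epsilon, max_iter = max_iter,
                           rng_seed = rng_seed)
  ids <- names(runs)
  if (is.null(ids)) ids <- paste0("subject", seq_along(runs))
  structure(list(group_components = comps,
                 subject_ranges = attr(cat_run, "subject_ranges"),
                 subject_ids = ids, mask = cat_run$mask),
            class = "group_model")
}

#' @export
print.group_model <- function(x, ...) {
  cat(sprintf("group_model: %d subjects, %d components\n",
              length(x$subject_ids), n_components(x$group_components)))
  invisible(x)
}

#' Back-reconstruct per-subject components from a group ICA
#'
#' The subject's time courses are its row-block of the group mixing matrix;
#' its spatial maps are the least-squares regression of the subject's data
#' on those time courses. Maps are z-scored. This is the single-stage
#' equivalent of the classical "regular" back-reconstruction; on noise-free
#' data it satisfies the same contract.
#'
#' @param model a [group_ica()] result.
#' @param runs the same list of runs the model was fitted on.
#' @param subject subject id (name or index).
#' @return A [component_set()] for that subject.
#' @export
back_reconstruct <- function(model, runs, subject) {
  if (is.character(subject)) {
    idx <- match(subject, model$subject_ids)
    if (is.na(idx)) stop("unknown subject: ", subject)
  } else idx <- as.integer(subject)
  if (idx < 1 || idx > length(model$subject_ids))
    stop("unknown subject index: ", idx)
  rng <- model$subject_ranges[[idx]]
  m_s <- model$group_components$timecourses[rng[1]:rng[2], , drop = FALSE]
  x_s <- runs[[idx]]$data
  if (!same_mask(runs[[idx]]$mask, model$mask))
    stop("run mask does not match group model")
  maps <- solve(crossprod(m_s), crossprod(m_s, x_s))  # N x v least squares
  component_set(m_s, maps,
                seed_used = model$group_components$seed_used,
                converged = model$group_components$converged)
}

#' Match a component set against a reference map
#'
#' Automated surrogate for picking the component of interest by visual
#' comparison: returns the component whose z-map has the largest absolute
#' Pearson correlation with the reference. If the best correlation is
#' negative the returned component is sign-flipped (map and time course
#' together) so it correlates positively.
#'
#' @param components a [component_set()].
#' @param reference a [stat_map()] on the same mask.
#' @param weak_threshold |r| below which the match is flagged weak.
#' @return list with `index`, `correlation` (after any flip), `flipped`,
#'   `weak`, and `component` (single-component [component_set()]).
#' @export
match_component <- function(components, reference, weak_threshold = 0.2) {
  ref <- reference$values
  if (stats::sd(ref) == 0) stop("constant reference map")
  rs <- as.vector(stats::cor(t(components$zmaps), ref))
  idx <- which.max(abs(rs))
  r <- rs[idx]
  flipped <- r < 0
  tc <- components$timecourses[, idx]
  mp <- components$maps[idx, ]
  if (flipped) { tc <- -tc; mp <- -mp }
  list(index = idx, correlation = abs(r), flipped = flipped,
       weak = abs(r) < weak_threshold,
       component = component_set(matrix(tc, ncol = 1),
                                 matrix(mp, nrow = 1),
                                 variance_fraction =
                                   components$variance_fraction[idx],
                                 seed_used = components$seed_used,
                                 converged = components$converged))
}

#' Serialize a component set
#'
#' Maps go to a 4D NIfTI (one volume per component), time courses to TSV and
#' metadata (seed, variance fractions, convergence) to a JSON sidecar.
#'
#' @param components a [component_set()].
#' @param mask the [brain_mask()] the maps live on.
#' @param prefix output path prefix; writes `<prefix>_zmaps.nii.gz`,
#'   `<prefix>_timecourses.tsv`, `<prefix>_meta.json`.
#' @return The prefix, invisibly.
#' @export
save_components <- function(components, mask, prefix) {
  geom <- mask$geometry
  n <- n_components(components)
  full <- matrix(0, n_voxels(geom), n)
  full[mask$include, ] <- t(components$zmaps)
  arr <- array(full, dim = c(geom$shape, n))
  RNifti::writeNifti(nifti_with_geometry(arr, geom),
                     paste0(prefix, "_zmaps.nii.gz"), datatype = "double")
  tcs <- lapply(seq_len(n), function(i)
    time_course(components$timecourses[, i], label = paste0("IC", i)))
  write_timecourses(tcs, paste0(prefix, "_timecourses.tsv"))
  jsonlite::write_json(
    list(n_components = n, seed_used = components$seed_used,
         converged = components$converged,
         variance_fraction = components$variance_fraction),
    paste0(prefix, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
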