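#' Masked 4D fMRI run as a time-by-voxel matrix
#'
#' The central data container: a t x v matrix holding one row per volume and
#' one column per in-mask voxel (columns ordered by ascending linear voxel
#' index), plus the mask, grid geometry and a free-text provenance log.
#'
#' @param data numeric t x v matrix.
#' @param mask a [brain_mask()] with `v` columns' worth of voxels.
#' @param provenance character vector of processing steps applied so far.
#' @return An object of class `fmri_run`.
#' @export
fmri_run <- function(data, mask, provenance = character()) {
  data <- as.matrix(data)
  stopifnot(ncol(data) == mask$v, nrow(data) >= 2)
  if (!all(is.finite(data))) stop("run data must be finite")
  structure(list(data = data, mask = mask, geometry = mask$geometry,
                 t = nrow(data), provenance = as.character(provenance)),
            class = "fmri_run")
}

#' @export
print.fmri_run <- function(x, ...) {
  cat(sprintf("fmri_run: t=%d volumes, v=%d voxels, TR %g s\n",
              x$t, x$mask$v, x$geometry$tr))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Voxelwise statistical map on a mask
#'
#' @param values numeric vector, one value per in-mask voxel.
#' @param mask a [brain_mask()].
#' @param statistic one of `"beta"`, `"t"`, `"z"`, `"raw"`.
#' @param label free-text description.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(values, mask, statistic = c("raw", "beta", "t", "z"),
                     label = "") {
  statistic <- match.arg(statistic)
  values <- as.numeric(values)
  stopifnot(length(values) == mask$v)
  if (!all(is.finite(values))) stop("stat_map values must be finite")
  structure(list(values = values, statistic = statistic, mask = mask,
                 label = label), class = "stat_map")
}

#' Binary (thresholded) map on a mask
#'
#' @param include logical vector, one entry per in-mask voxel.
#' @param mask a [brain_mask()].
#' @param threshold_used threshold that produced the map, or `NA`.
#' @return An object of class `binary_map`.
#' @export
binary_map <- function(include, mask, threshold_used = NA_real_) {
  include <- as.logical(include)
  stopifnot(length(include) == mask$v, !anyNA(include))
  structure(list(include = include, mask = mask,
                 threshold_used = threshold_used), class = "binary_map")
}

#' Normalized regressor time course
#'
#' @param values numeric vector of length t.
#' @param label free-text name.
#' @param role `"interest"` or `"nuisance"`.
#' @return An object of class `time_course`.
#' @export
time_course <- function(values, label = "", role = c("interest", "nuisance")) {
  role <- match.arg(role)
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("time course values must be finite")
  structure(list(values = values, label = label, role = role),
            class = "time_course")
}

geometry_from_header <- function(img) {
  hdr <- RNifti::niftiHeader(img)
  shape <- hdr$dim[2:4]
  vs <- abs(hdr$pixdim[2:4])
  vs[vs == 0] <- 1
  tr <- hdr$pixdim[5]
  if (!is.finite(tr) || tr <= 0) tr <- 1
  aff <- RNifti::xform(img)
  geometry(shape, vs, affine = aff, tr = tr)
}

#' Load a 4D NIfTI image (and optional 3D mask) as an fmri_run
#'
#' When no mask is given, an automatic mask keeps the voxels whose temporal
#' standard deviation is strictly positive.
#'
#' @param image_path path to a 4D `.nii`/`.nii.gz` image.
#' @param mask_path optional path to a 3D mask on the same grid (non-zero
#'   voxels are kept).
#' @return An [fmri_run()].
#' @export
load_run <- function(image_path, mask_path = NULL) {
  img <- RNifti::readNifti(image_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4)
    stop("image must be 4D, got ", length(dim(arr)), "D")
  geom <- geometry_from_header(img)
  t <- dim(arr)[4]
  if (t < 2) stop("need at least 2 volumes")
  flat <- matrix(arr, nrow = prod(dim(arr)[1:3]), ncol = t)  # voxel x time
  if (!all(is.finite(flat))) stop("non-finite values in image")
  if (is.null(mask_path)) {
    sds <- matrixStats_rowSds(flat)
    include <- sds > 0
  } else {
    mimg <- RNifti::readNifti(mask_path)
    marr <- as.array(mimg)
    if (!identical(as.integer(dim(marr)[1:3]), geom$shape) ||
        length(dim(marr)) != 3)
      stop("mask grid does not match image grid")
    include <- as.vector(marr != 0)
  }
  mask <- brain_mask(include, geom)
  fmri_run(t(flat[include, , drop = FALSE]), mask,
           provenance = sprintf("load_run(%s)", basename(image_path)))
}

# row-wise sd without matrixStats (not pre-installed); vectorized
matrixStats_rowSds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(pmax(rowSums(m^2) / n - mu^2, 0) * n / (n - 1))
}

#' Write a statistical or binary map to a 3D NIfTI file
#'
#' Out-of-mask voxels are written as 0; values are stored at double precision
#' so a round-trip load reproduces them bit-exactly.
#'
#' @param map a [stat_map()] or [binary_map()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return The path, invisibly.
#' @export
save_map <- function(map, path) {
  mask <- map$mask
  geom <- mask$geometry
  full <- numeric(n_voxels(geom))
  vals <- if (inherits(map, "binary_map")) as.numeric(map$include) else map$values
  full[mask$include] <- vals
  arr <- array(full, dim = geom$shape)
  RNifti::writeNifti(nifti_with_geometry(arr, geom), path,
                     datatype = "double")
  invisible(path)
}

nifti_with_geometry <- function(arr, geom) {
  img <- RNifti::asNifti(arr)
  img$pixdim <- c(1, geom$voxel_size, geom$tr, 0, 0, 0)
  img <- RNifti::`sform<-`(img, structure(geom$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(geom$affine, code = 1L))
  img
}

#' Save a run as a 4D NIfTI image
#'
#' Companion to [load_run()]; out-of-mask voxels are 0 in every volume.
#'
#' @param run an [fmri_run()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
save_run <- function(run, path) {
  geom <- run$geometry
  full <- matrix(0, n_voxels(geom), run$t)
  full[run$mask$include, ] <- t(run$data)
  arr <- array(full, dim = c(geom$shape, run$t))
  RNifti::writeNifti(nifti_with_geometry(arr, geom), path,
                     datatype = "double")
  invisible(path)
}

#' Voxelwise temporal normalization
#'
#' Removes each voxel's temporal mean and/or scales each voxel's temporal
#' variance to one. Voxels with zero temporal variance are mapped to all-zero
#' series rather than producing NaNs, so degenerate phantom voxels stay
#' usable.
#'
#' @param run an [fmri_run()].
#' @param demean remove the per-voxel temporal mean.
#' @param variance_normalize scale each voxel's series to unit variance.
#' @return A normalized [fmri_run()] with provenance appended.
#' @export
normalize_run <- function(run, demean = TRUE, variance_normalize = TRUE) {
  x <- run$data
  if (demean) x <- sweep(x, 2, colMeans(x), "-")
  if (variance_normalize) {
    sds <- sqrt(colSums(sweep(x, 2, colMeans(x), "-")^2) / (nrow(x) - 1))
    scale <- ifelse(sds > 0, 1 / sds, 0)
    x <- sweep(x, 2, scale, "*")
    if (!demean) {
      # keep the original mean when only scaling (constant voxels zeroed)
      x[, sds == 0] <- 0
    }
  }
  fmri_run(x, run$mask,
           provenance = c(run$provenance,
                          sprintf("normalize(demean=%s,varnorm=%s)",
                                  demean, variance_normalize)))
}

#' Highpass temporal filter by Gaussian-weighted running-line fitting
#'
#' Each voxel's series is replaced by its residual from a locally weighted
#' straight-line fit: at every time point a line is fitted by least squares
#' with Gaussian weights of standard deviation `sigma_seconds / tr` samples
#' centred on that point, and the fitted value is subtracted. Slow drifts
#' (periods much longer than the kernel) are removed while fast oscillations
#' pass through nearly untouched. The output is demeaned per voxel.
#'
#' @param run an [fmri_run()].
#' @param sigma_seconds kernel standard deviation in seconds.
#' @return The filtered [fmri_run()].
#' @export
highpass <- function(run, sigma_seconds) {
  stopifnot(sigma_seconds > 0)
  tr <- run$geometry$tr
  if (sigma_seconds < tr)
    warning("highpass sigma is smaller than TR; filter is nearly all-pass")
  s <- sigma_seconds / tr
  t <- run$t
  x <- seq_len(t)
  w <- exp(-0.5 * outer(x, x, "-")^2 / s^2)   # t x t weights
  s0 <- rowSums(w)
  s1 <- as.vector(w %*% x)
  s2 <- as.vector(w %*% x^2)
  y <- run$data
  t0 <- w %*% y                 # sum_j w y
  t1 <- w %*% (x * y)           # sum_j w x y
  den <- s0 * s2 - s1^2
  fitted <- ((s2 - s1 * x) * t0 + (s0 * x - s1) * t1) / den
  res <- y - fitted
  res <- sweep(res, 2, colMeans(res), "-")
  fmri_run(res, run$mask,
           provenance = c(run$provenance,
                          sprintf("highpass(sigma=%gs)", sigma_seconds)))
}

#' Temporally concatenate runs that share a mask
#'
#' Stacks the rows of each run in input order (the multisubject
#' temporal-concatenation construction used for group ICA). Each run is
#' expected to be normalized already.
#'
#' @param runs list of [fmri_run()] objects on the same mask.
#' @return An [fmri_run()] with `t = sum(t_i)`; the per-subject row ranges
#'   are recorded in `provenance` and in attribute `subject_ranges`.
#' @export
concat_group <- function(runs) {
  if (length(runs) == 0) stop("empty run list")
  mask <- runs[[1]]$mask
  for (r in runs[-1])
    if (!same_mask(r$mask, mask)) stop("runs have mismatched masks")
  ts <- vapply(runs, function(r) r$t, integer(1))
  ends <- cumsum(ts)
  starts <- c(1L, head(ends, -1) + 1L)
  out <- fmri_run(do.call(rbind, lapply(runs, function(r) r$data)), mask,
                  provenance = sprintf("concat_group(%s)",
                                       paste(ts, collapse = "+")))
  attr(out, "subject_ranges") <- Map(function(a, b) c(a, b), starts, ends)
  out
}

#' Read and write time courses as TSV
#'
#' One column per time course with a header row of labels.
#'
#' @param courses list of [time_course()] objects.
#' @param path TSV path.
#' @return `write_timecourses()` the path invisibly; `read_timecourses()` a
#'   list of [time_course()] objects (roles default to interest).
#' @export
write_timecourses <- function(courses, path) {
  m <- vapply(courses, function(tc) tc$values,
              numeric(length(courses[[1]]$values)))
  m <- as.data.frame(m)
  labels <- vapply(courses, function(tc) tc$label, character(1))
  labels[labels == ""] <- paste0("tc", seq_along(courses))[labels == ""]
  names(m) <- labels
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourses
#' @export
read_timecourses <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  lapply(names(m), function(nm) time_course(m[[nm]], label = nm))
}
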