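#' Spatial geometry of a volumetric grid
#'
#' Bundles the spatial extents, voxel dimensions, voxel-to-world affine and
#' repetition time that every image, mask and statistical map in the package
#' carries along.
#'
#' @param shape integer vector of length 3, spatial extents in voxels.
#' @param voxel_size numeric vector of length 3, voxel edge lengths in mm.
#' @param affine 4x4 voxel-index (0-based) to world-mm transform. Defaults to
#'   a diagonal scaling by `voxel_size`.
#' @param tr repetition time in seconds.
#'
#' @return An object of class `geometry`.
#' @export
geometry <- function(shape, voxel_size = c(1, 1, 1),
                     affine = NULL, tr = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1L),
            length(voxel_size) == 3, all(voxel_size > 0),
            length(tr) == 1, tr > 0)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- unname(matrix(as.numeric(affine), 4, 4))
  if (abs(det(affine)) < .Machine$double.eps * 100)
    stop("affine must be invertible")
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 affine = affine, tr = as.numeric(tr)),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("geometry: %s voxels, %s mm, TR %g s\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"), x$tr))
  invisible(x)
}

n_voxels <- function(geom) prod(geom$shape)

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$affine - b$affine)) < tol
}

#' Convert between linear voxel indices and coordinates
#'
#' Masked data columns are ordered by ascending linear voxel index with the
#' first (fastest-varying) axis first, i.e. R's native array order. These
#' helpers translate a linear index (1-based, as used for subsetting in R)
#' into 0-based voxel indices or world-mm coordinates via the affine.
#'
#' @param geom a [geometry()].
#' @param linear_index 1-based linear index into the full grid.
#' @return `voxel_coords()` returns an n x 3 matrix of 0-based indices;
#'   `world_coords()` an n x 3 matrix of mm coordinates.
#' @export
voxel_coords <- function(geom, linear_index) {
  idx <- as.integer(linear_index) - 1L
  nx <- geom$shape[1]; ny <- geom$shape[2]
  cbind(i = idx %% nx,
        j = (idx %/% nx) %% ny,
        k = idx %/% (nx * ny))
}

#' @rdname voxel_coords
#' @export
world_coords <- function(geom, linear_index) {
  ijk <- voxel_coords(geom, linear_index)
  xyz <- cbind(ijk, 1) %*% t(geom$affine)
  colnames(xyz) <- c("x", "y", "z", "w")
  xyz[, 1:3, drop = FALSE]
}

#' Brain mask over a spatial grid
#'
#' @param include logical vector (or 3D array) with one entry per grid voxel.
#' @param geom the grid [geometry()].
#' @return An object of class `brain_mask` with fields `geometry`, `include`
#'   (logical vector in linear-index order) and `v` (number of voxels kept).
#' @export
brain_mask <- function(include, geom) {
  include <- as.logical(include)
  stopifnot(length(include) == n_voxels(geom), !anyNA(include))
  v <- sum(include)
  if (v < 1) stop("mask must include at least one voxel")
  structure(list(geometry = geom, include = include, v = as.integer(v)),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("brain_mask: %d of %d voxels on %s grid\n", x$v,
              length(x$include), paste(x$geometry$shape, collapse = "x")))
  invisible(x)
}

# linear indices (1-based, full grid) of the voxels inside the mask
mask_indices <- function(mask) which(mask$include)

same_mask <- function(a, b) {
  same_grid(a$geometry, b$geometry) && identical(a$include, b$include)
}
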