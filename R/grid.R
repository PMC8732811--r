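#' Voxel grid of SUV values
#'
#' A minimal 3-D image container: an array of standardized uptake values
#' (SUV, dimensionless) together with the anisotropic voxel spacing in mm
#' and a world-space origin. The origin is the world coordinate of the
#' *center* of voxel `[1, 1, 1]`.
#'
#' @param values numeric 3-D array of SUV values (all finite).
#' @param voxel_size_mm positive numeric length-3 vector, spacing per axis in mm.
#' @param origin_mm numeric length-3 vector, world position (mm) of the center
#'   of the first voxel. Defaults to `voxel_size_mm / 2` so the grid occupies
#'   `[0, dim * spacing]`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, voxel_size_mm, origin_mm = voxel_size_mm / 2) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  if (!all(is.finite(values)))
    stop("voxel grid contains non-finite values")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 positive spacings")
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L) stop("`origin_mm` must have length 3")
  structure(
    list(values = values, voxel_size_mm = voxel_size_mm, origin_mm = origin_mm),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, SUV range [%.3g, %.3g]\n",
    d[1], d[2], d[3], x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

#' Spherical volume of interest
#'
#' @param center_mm numeric length-3, world-space sphere center in mm.
#' @param diameter_mm positive sphere diameter in mm.
#' @param label optional name used in diagnostics.
#' @return Object of class `sphere_voi`.
#' @export
sphere_voi <- function(center_mm, diameter_mm, label = NULL) {
  center_mm <- as.numeric(center_mm)
  if (length(center_mm) != 3L) stop("`center_mm` must have length 3")
  if (!is.numeric(diameter_mm) || diameter_mm <= 0)
    stop("`diameter_mm` must be > 0")
  structure(list(center_mm = center_mm, diameter_mm = diameter_mm,
                 label = label),
            class = "sphere_voi")
}

# World coordinates (mm) of voxel centers along one axis.
axis_centers <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(dim(grid$values)[axis]) - 1L) *
    grid$voxel_size_mm[axis]
}

#' Linear indices of voxels whose centers lie inside a spherical VOI
#'
#' Membership is voxel-center-in-sphere: a voxel belongs to the VOI when its
#' center is within `diameter_mm / 2` of the sphere center. No partial-volume
#' weighting is applied.
#'
#' @param grid a [voxel_grid()].
#' @param voi a [sphere_voi()].
#' @return Integer vector of linear indices into `grid$values` (may be empty).
#' @export
voi_voxels <- function(grid, voi) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(voi, "sphere_voi"))
  r <- voi$diameter_mm / 2
  cx <- axis_centers(grid, 1L); cy <- axis_centers(grid, 2L)
  cz <- axis_centers(grid, 3L)
  # bounding-box pre-cut keeps the distance evaluation small
  ix <- which(abs(cx - voi$center_mm[1]) <= r)
  iy <- which(abs(cy - voi$center_mm[2]) <= r)
  iz <- which(abs(cz - voi$center_mm[3]) <= r)
  if (!length(ix) || !length(iy) || !length(iz)) return(integer(0))
  g <- expand.grid(i = ix, j = iy, k = iz)
  d2 <- (cx[g$i] - voi$center_mm[1])^2 + (cy[g$j] - voi$center_mm[2])^2 +
    (cz[g$k] - voi$center_mm[3])^2
  keep <- d2 <= r^2
  if (!any(keep)) return(integer(0))
  d <- dim(grid$values)
  g <- g[keep, , drop = FALSE]
  as.integer(g$i + (g$j - 1L) * d[1] + (g$k - 1L) * d[1] * d[2])
}

# array [i, j, k] subscripts for linear indices
linear_to_sub <- function(idx, dims) {
  idx0 <- idx - 1L
  i <- idx0 %% dims[1]
  j <- (idx0 %/% dims[1]) %% dims[2]
  k <- idx0 %/% (dims[1] * dims[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

#' Read / write a voxel grid as NIfTI
#'
#' Thin wrappers around \pkg{RNifti}. On write, the voxel spacing is stored
#' in the NIfTI `pixdim`; on read it is recovered from there. The origin is
#' kept at the package default (`spacing / 2`): full affine bookkeeping is
#' out of scope for phantom work.
#'
#' @param grid a [voxel_grid()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_nifti_grid()` returns `path` invisibly; `read_nifti_grid()`
#'   returns a [voxel_grid()].
#' @export
write_nifti_grid <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_grid
#' @export
read_nifti_grid <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  voxel_grid(array(as.numeric(img), dim = dim(img)[1:3]), vox)
}
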