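#' Voxel grid: a 3D scalar field with physical geometry
#'
#' The basic spatial container used throughout the package, carrying either an
#' activity-concentration image (Bq/mL), an organ label map, or any scalar
#' field. Axis order is `(z, y, x)` with 0-based voxel indices, physical units
#' mm, and the voxel-centre convention: the centre of voxel `(0, 0, 0)` sits at
#' `origin` in world coordinates.
#'
#' @param values 3D numeric array, dimension `(nz, ny, nx)`. All values must be
#'   finite.
#' @param spacing Numeric length-3, voxel spacing `(dz, dy, dx)` in mm;
#'   strictly positive.
#' @param origin Numeric length-3, world coordinate (mm) of the centre of voxel
#'   `(0, 0, 0)`, in `(z, y, x)` order.
#' @return An object of class `voxel_grid` with fields `values`, `spacing`,
#'   `origin`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 4, 4)), spacing = c(4.42, 4.42, 4.42))
#' voxel_volume_mL(g)
#' @export
voxel_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("voxel_grid values must be a rank-3 array")
  if (!all(is.finite(values)))
    stop("voxel_grid values must be finite")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive numbers (dz, dy, dx) in mm")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers (z, y, x) in mm")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d (z,y,x), spacing %.3f x %.3f x %.3f mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm; value range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Geometry of a voxel grid without values
#'
#' A lightweight description (`dim`, `spacing`, `origin`) used as a resampling
#' target. Any `voxel_grid` can stand in wherever a geometry is accepted.
#'
#' @param dim Integer length-3 `(nz, ny, nx)`.
#' @param spacing,origin As in [voxel_grid()].
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(dim, spacing, origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L)) stop("dim must be 3 positive integers")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be positive")
  structure(list(dim = dim, spacing = spacing, origin = origin),
            class = "grid_geometry")
}

#' @rdname grid_geometry
#' @param x A `voxel_grid` or `grid_geometry`.
#' @export
as_grid_geometry <- function(x) {
  if (inherits(x, "grid_geometry")) return(x)
  if (inherits(x, "voxel_grid"))
    return(grid_geometry(dim(x$values), x$spacing, x$origin))
  stop("cannot interpret object as a grid geometry")
}

#' Voxel volume in mL
#'
#' @param grid A `voxel_grid` or `grid_geometry`.
#' @return Volume of one voxel in mL (1 mL = 1000 mm^3).
#' @export
voxel_volume_mL <- function(grid) {
  g <- as_grid_geometry(grid)
  prod(g$spacing) / 1000
}

same_geometry <- function(a, b, tol = 1e-6) {
  ga <- as_grid_geometry(a); gb <- as_grid_geometry(b)
  identical(ga$dim, gb$dim) &&
    all(abs(ga$spacing - gb$spacing) < tol) &&
    all(abs(ga$origin - gb$origin) < tol)
}

# world coordinate (z,y,x) of 0-based index along one axis
axis_coords <- function(geom, axis) {
  geom$origin[axis] + (seq_len(geom$dim[axis]) - 1) * geom$spacing[axis]
}

#' Read / write a voxel grid as NIfTI-1
#'
#' Spacing and origin are carried in the NIfTI qform (code 2). Internally the
#' package orders axes `(z, y, x)`; files follow the NIfTI `(x, y, z)`
#' convention, so arrays are permuted on the way in and out.
#'
#' @param grid A `voxel_grid`.
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_grid_nifti` returns `path` invisibly; `read_grid_nifti`
#'   returns a `voxel_grid`.
#' @export
write_grid_nifti <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  arr <- aperm(grid$values, c(3, 2, 1))  # (x,y,z) for NIfTI
  img <- RNifti::asNifti(arr)
  sp_xyz <- rev(grid$spacing)
  m <- diag(c(sp_xyz, 1))
  m[1:3, 4] <- rev(grid$origin)
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::pixdim(img) <- sp_xyz
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_grid_nifti
#' @export
read_grid_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume")
  xf <- RNifti::xform(img)
  sp_xyz <- RNifti::pixdim(img)[1:3]
  origin_xyz <- xf[1:3, 4]
  voxel_grid(aperm(arr, c(3, 2, 1)), spacing = rev(sp_xyz),
             origin = rev(origin_xyz))
}

#' Separable Gaussian blur of a voxel grid
#'
#' Convolves the field with an isotropic Gaussian point-spread function of the
#' given full width at half maximum, `sigma = FWHM / 2.3548`, applied
#' separably per axis with a discrete kernel normalised to unit sum (so total
#' activity is conserved away from the grid edges). Zero padding is assumed
#' beyond the grid.
#'
#' @param grid A `voxel_grid`.
#' @param fwhm_mm PSF full width at half maximum in mm; 0 returns the input
#'   unchanged.
#' @return A `voxel_grid` with blurred values.
#' @export
blur_grid <- function(grid, fwhm_mm) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(grid)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  vals <- grid$values
  for (axis in 1:3) {
    sigma_vox <- sigma_mm / grid$spacing[axis]
    vals <- convolve_axis(vals, gaussian_kernel(sigma_vox), axis)
  }
  voxel_grid(vals, grid$spacing, grid$origin)
}

gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# 1D convolution along `axis` of a 3D array, zero-padded, via a banded matrix
convolve_axis <- function(a, k, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- d[axis]
  m <- matrix(ap, nrow = n)
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (j in seq_along(k)) {
    off <- j - r - 1L  # output row = input row + off
    i_in <- seq_len(n)
    i_out <- i_in + off
    ok <- i_out >= 1L & i_out <= n
    K[cbind(i_out[ok], i_in[ok])] <- k[j]
  }
  out <- K %*% m
  dim(out) <- d[perm]
  aperm(out, order(perm))
}
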