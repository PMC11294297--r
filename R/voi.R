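#' Volume of interest bound to a grid geometry
#'
#' A VOI is a mask congruent with a voxel grid: binary after manual
#' delineation, possibly fractional (values in \[0, 1\]) after resampling to a
#' coarser grid. The label records the organ and the time-point tag
#' (`B_L`, `D0`, `D1`, `D2`, `D7`) the delineation belongs to.
#'
#' @param mask 3D array with values in \[0, 1\].
#' @param geometry A `voxel_grid` or `grid_geometry` the mask lives on.
#' @param label Character label, conventionally `"<organ>@<tag>"`.
#' @return An object of class `voi` with fields `mask`, `geometry`, `label`.
#' @export
voi <- function(mask, geometry, label = "organ@B_L") {
  mask <- as.array(mask)
  geom <- as_grid_geometry(geometry)
  if (!identical(dim(mask), as.integer(geom$dim)))
    stop("mask shape must equal grid shape")
  if (!all(is.finite(mask)) || any(mask < 0) || any(mask > 1))
    stop("mask values must be finite and in [0, 1]")
  structure(list(mask = mask, geometry = geom, label = as.character(label)),
            class = "voi")
}

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("<voi> %s: %.2f mL on %d x %d x %d grid (spacing %.3f x %.3f x %.3f mm)\n",
              x$label, voi_volume_mL(x), x$geometry$dim[1], x$geometry$dim[2],
              x$geometry$dim[3], x$geometry$spacing[1], x$geometry$spacing[2],
              x$geometry$spacing[3]))
  invisible(x)
}

#' VOI volume in mL
#'
#' `sum(mask) * voxel_volume`; fractional voxels contribute fractionally.
#'
#' @param x A `voi`.
#' @return Volume in mL.
#' @export
voi_volume_mL <- function(x) {
  stopifnot(inherits(x, "voi"))
  sum(x$mask) * voxel_volume_mL(x$geometry)
}

#' Resample a VOI onto a new grid geometry
#'
#' Each target voxel receives the fraction of its physical volume covered by
#' the source mask. Because both grids are axis-aligned boxes, the coverage
#' fraction is computed exactly as a separable product of per-axis interval
#' overlaps (the limit of infinitely fine supersampling), so fractional
#' resampling conserves total mask volume to machine precision wherever the
#' target grid covers the source. This is the CT-to-SPECT step of the
#' workflow: delineations drawn on a ~1 mm CT grid are transferred to the
#' 4.42 mm SPECT grid, where plain nearest-neighbour resampling would alias
#' volumes badly.
#'
#' @param voi Source `voi`.
#' @param target Target geometry (`voxel_grid` or `grid_geometry`) sharing the
#'   source's world coordinate frame.
#' @param binarize_threshold Either a fraction in \[0, 1\] (mask thresholded at
#'   it; voxels with coverage `>= threshold` become 1) or the string
#'   `"fractional"` to keep coverage fractions (the mode used for
#'   quantification).
#' @return A `voi` on the target geometry.
#' @export
resample_voi <- function(voi, target, binarize_threshold = 0.5) {
  stopifnot(inherits(voi, "voi"))
  tg <- as_grid_geometry(target)
  fractional <- identical(binarize_threshold, "fractional")
  if (!fractional &&
      (!is.numeric(binarize_threshold) || binarize_threshold < 0 ||
       binarize_threshold > 1))
    stop("binarize_threshold must be in [0, 1] or \"fractional\"")
  if (same_geometry(voi$geometry, tg)) {
    # identity geometry: coverage equals the source mask itself
    m <- voi$mask
    if (!fractional) m <- (m >= binarize_threshold) * 1
    return(voi(m, tg, voi$label))
  }
  frac <- resample_field(voi$mask, voi$geometry, tg)
  if (sum(voi$mask) > 0 && sum(frac) == 0)
    stop("VOI outside target grid")
  frac <- pmin(frac, 1)  # guard rounding just above 1
  m <- if (fractional) frac else (frac >= binarize_threshold) * 1
  if (sum(voi$mask) > 0 && sum(m) == 0)
    stop("VOI degenerate after thresholding (volume 0)")
  voi(array(m, tg$dim), tg, voi$label)
}

# per-axis interval-overlap matrix: O[i, j] = overlap length of target voxel i
# with source voxel j along `axis`, divided by the target spacing
overlap_matrix <- function(tg, src_geom, axis) {
  tc <- axis_coords(tg, axis); sc <- axis_coords(src_geom, axis)
  th <- tg$spacing[axis] / 2; sh <- src_geom$spacing[axis] / 2
  ov <- pmin(outer(tc + th, sc + sh, pmin) - outer(tc - th, sc - sh, pmax),
             Inf)
  pmax(ov, 0) / tg$spacing[axis]
}

# Volume-weighted (box-overlap) resampling of a source field onto a target
# geometry: out[T] = sum_S src[S] * vol(T intersect S) / vol(T), computed as
# a separable tensor contraction along the three axes.
resample_field <- function(src, src_geom, tg) {
  src_geom <- as_grid_geometry(src_geom)
  tg <- as_grid_geometry(tg)
  Oz <- overlap_matrix(tg, src_geom, 1)
  Oy <- overlap_matrix(tg, src_geom, 2)
  Ox <- overlap_matrix(tg, src_geom, 3)
  d <- dim(src)
  # contract z: (tz, sy*sx)
  a <- Oz %*% matrix(src, d[1], d[2] * d[3])
  dim(a) <- c(nrow(Oz), d[2], d[3])
  # contract y
  a <- aperm(a, c(2, 1, 3))
  a2 <- Oy %*% matrix(a, d[2], nrow(Oz) * d[3])
  dim(a2) <- c(nrow(Oy), nrow(Oz), d[3])
  # contract x
  a2 <- aperm(a2, c(3, 2, 1))
  a3 <- Ox %*% matrix(a2, d[3], nrow(Oz) * nrow(Oy))
  dim(a3) <- c(nrow(Ox), nrow(Oz), nrow(Oy))
  aperm(a3, c(2, 3, 1))
}

#' Propagate a single-time-point VOI to other time points
#'
#' Reproduces the single-CT delineation strategies: the mask defined at one
#' time point is applied to every other time point without any geometric
#' modification, only the label's time tag changes.
#'
#' @param source A `voi`.
#' @param timepoints Character vector of time tags (e.g. `c("D0","D1","D2","D7")`).
#' @return Named list of `voi`s, one per requested tag, all masks identical to
#'   the source mask.
#' @export
propagate_voi <- function(source, timepoints) {
  stopifnot(inherits(source, "voi"))
  if (length(timepoints) == 0) stop("timepoints must be non-empty")
  organ <- sub("@.*$", "", source$label)
  out <- lapply(as.character(timepoints), function(tag)
    voi(source$mask, source$geometry, paste0(organ, "@", tag)))
  names(out) <- as.character(timepoints)
  out
}

#' Align a VOI to an image by integer-voxel translation
#'
#' Surrogate for the manual repositioning of CT-defined kidney VOIs on each
#' SPECT: searches all integer-voxel shifts within `+/- max_shift_voxels` per
#' axis and returns the shifted VOI maximising the mask-weighted mean image
#' value. Ties are broken by the smallest shift magnitude, then
#' lexicographically in (z, y, x).
#'
#' @param image A `voxel_grid` sharing the VOI's geometry.
#' @param voi A `voi`.
#' @param max_shift_voxels Non-negative integer search radius; 0 returns the
#'   VOI unchanged.
#' @return The shifted `voi` (attribute `"shift"` records the chosen
#'   (z, y, x) voxel shift).
#' @export
align_voi <- function(image, voi, max_shift_voxels = 2L) {
  stopifnot(inherits(image, "voxel_grid"), inherits(voi, "voi"))
  if (!same_geometry(image, voi$geometry))
    stop("image and VOI must share geometry")
  m <- as.integer(max_shift_voxels)
  if (m < 0) stop("max_shift_voxels must be >= 0")
  if (m == 0L) {
    attr(voi, "shift") <- c(0L, 0L, 0L)
    return(voi)
  }
  d <- dim(image$values)
  nzlin <- which(voi$mask > 0)
  w <- voi$mask[nzlin]
  idx <- arrayInd(nzlin, d)
  wsum <- sum(w)
  best <- NULL
  for (dz in -m:m) for (dy in -m:m) for (dx in -m:m) {
    iz <- idx[, 1] + dz; iy <- idx[, 2] + dy; ix <- idx[, 3] + dx
    ok <- iz >= 1L & iz <= d[1] & iy >= 1L & iy <= d[2] & ix >= 1L & ix <= d[3]
    val <- sum(image$values[cbind(iz[ok], iy[ok], ix[ok])] * w[ok]) / wsum
    cand <- list(score = val, shift = c(dz, dy, dx),
                 mag2 = dz^2 + dy^2 + dx^2)
    if (is.null(best) || cand$score > best$score + 1e-12 ||
        (abs(cand$score - best$score) <= 1e-12 &&
         (cand$mag2 < best$mag2 ||
          (cand$mag2 == best$mag2 && lex_before(cand$shift, best$shift))))) {
      best <- cand
    }
  }
  out <- shift_voi(voi, best$shift)
  attr(out, "shift") <- as.integer(best$shift)
  out
}

lex_before <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

shift_voi <- function(voi, shift) {
  d <- dim(voi$mask)
  out <- array(0, d)
  src_rng <- dst_rng <- vector("list", 3)
  for (a in 1:3) {
    s <- shift[a]
    src <- seq.int(max(1L, 1L - s), min(d[a], d[a] - s))
    if (length(src) == 0) return(voi(out, voi$geometry, voi$label))
    src_rng[[a]] <- src
    dst_rng[[a]] <- src + s
  }
  out[dst_rng[[1]], dst_rng[[2]], dst_rng[[3]]] <-
    voi$mask[src_rng[[1]], src_rng[[2]], src_rng[[3]]]
  voi(out, voi$geometry, voi$label)
}

#' Mask-weighted mean activity concentration inside a VOI
#'
#' `sum(values * mask) / sum(mask)`; for a binary mask this is the plain mean
#' over the VOI. This is the quantity read off each SPECT for every delineated
#' kidney or spleen VOI.
#'
#' @param image A `voxel_grid` (activity concentration, Bq/mL).
#' @param voi A `voi` on the same geometry with positive volume.
#' @return Mean concentration (Bq/mL).
#' @export
mean_concentration <- function(image, voi) {
  stopifnot(inherits(image, "voxel_grid"), inherits(voi, "voi"))
  if (!same_geometry(image, voi$geometry))
    stop("image and VOI must share geometry")
  w <- sum(voi$mask)
  if (w <= 0) stop("zero-volume VOI")
  sum(image$values * voi$mask) / w
}
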