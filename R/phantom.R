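#' Organ specification for the synthetic phantom
#'
#' Describes one organ (kidney or spleen surrogate) as a smooth parametric
#' shape whose volume changes over the imaging time points through per-tag
#' multipliers. Kidneys swell transiently after the renoprotective amino-acid
#' infusion; the spleen serves as the no-change control.
#'
#' @param name Organ name (e.g. `"kidney_L"`, `"spleen"`).
#' @param base_volume_mL Volume at baseline (`B_L`), mL. Kidney defaults are
#'   drawn from the observed parenchymal range 27.7-248.8 mL.
#' @param shape `"ellipsoid"` or `"bean"` (ellipsoid with a spherical
#'   indentation on one side, a kidney-like concavity).
#' @param shape_params List: `axis_ratios` length-3 positive (z, y, x)
#'   semi-axis proportions; for `"bean"` also `concavity_depth` (indentation
#'   sphere radius as a fraction of the x semi-axis, default 0.45).
#' @param center_mm World position of the organ centre, (z, y, x) mm.
#' @param volume_multipliers Named numeric, tag -> positive factor relative to
#'   `base_volume_mL`; defaults to [default_volume_multipliers()] for kidneys
#'   and to all-1 for any organ whose name contains "spleen".
#' @return An object of class `organ_spec`.
#' @export
organ_spec <- function(name, base_volume_mL,
                       shape = c("ellipsoid", "bean"),
                       shape_params = list(axis_ratios = c(1.6, 1.0, 0.85)),
                       center_mm = c(0, 0, 0),
                       volume_multipliers = NULL) {
  shape <- match.arg(shape)
  if (!is.numeric(base_volume_mL) || base_volume_mL <= 0)
    stop("base_volume_mL must be positive")
  if (is.null(volume_multipliers)) {
    volume_multipliers <- if (grepl("spleen", name, ignore.case = TRUE))
      default_volume_multipliers("spleen") else default_volume_multipliers()
  }
  if (any(volume_multipliers <= 0)) stop("volume multipliers must be positive")
  if (is.null(shape_params$axis_ratios)) shape_params$axis_ratios <- c(1.6, 1.0, 0.85)
  if (shape == "bean" && is.null(shape_params$concavity_depth))
    shape_params$concavity_depth <- 0.45
  structure(list(name = name, base_volume_mL = base_volume_mL, shape = shape,
                 shape_params = shape_params, center_mm = as.numeric(center_mm),
                 volume_multipliers = volume_multipliers),
            class = "organ_spec")
}

#' Default per-time-point volume multipliers
#'
#' The kidney multipliers encode the observed baseline-relative parenchymal
#' volume biases during therapy: +8.77% at D0 (~4 h), +10.07% at D1 (~24 h),
#' +1.10% at D2 and D7. The spleen control does not change volume.
#'
#' @param organ `"kidney"` (default) or `"spleen"`.
#' @return Named numeric vector over tags `B_L, D0, D1, D2, D7`.
#' @examples
#' default_volume_multipliers()["D1"]  # 1.1007
#' @export
default_volume_multipliers <- function(organ = c("kidney", "spleen")) {
  organ <- match.arg(organ)
  if (organ == "kidney")
    c(B_L = 1.0, D0 = 1.0877, D1 = 1.1007, D2 = 1.0110, D7 = 1.0110)
  else
    c(B_L = 1.0, D0 = 1.0, D1 = 1.0, D2 = 1.0, D7 = 1.0)
}

organ_volume_mL <- function(organ, tag) {
  mult <- organ$volume_multipliers[[tag]]
  if (is.null(mult)) stop(sprintf("organ %s has no multiplier for tag %s",
                                  organ$name, tag))
  organ$base_volume_mL * mult
}

#' Rasterise organs into a CT-resolution label map
#'
#' Builds the synthetic anatomy at one time point: each organ is rasterised on
#' the (CT-like) grid at its tag-scaled volume. The shape's scale is solved so
#' the voxelised volume matches `base_volume_mL * multiplier(tag)` to within
#' half a voxel volume. Returns the label map plus the exact per-organ VOIs
#' (the synthetic stand-in for manual CT delineation).
#'
#' @param organs List of [organ_spec()] objects; must not overlap after
#'   scaling.
#' @param time_tag One of `B_L, D0, D1, D2, D7`.
#' @param geometry Target `grid_geometry` (or `voxel_grid`); must enclose all
#'   organs.
#' @return List with `labels` (a `voxel_grid` of integer labels, 0 background,
#'   i for `organs[[i]]`), `vois` (named list of binary `voi`s labelled
#'   `"<organ>@<tag>"`), and `volumes_mL` (named numeric of achieved volumes).
#' @export
make_phantom <- function(organs, time_tag, geometry) {
  geom <- as_grid_geometry(geometry)
  if (inherits(organs, "organ_spec")) organs <- list(organs)
  lab <- array(0L, geom$dim)
  vois <- list(); vols <- numeric(0)
  for (i in seq_along(organs)) {
    org <- organs[[i]]
    target_mL <- organ_volume_mL(org, time_tag)
    m <- rasterize_organ(org, target_mL, geom)
    hit <- which(m)
    if (length(hit) == 0)
      stop(sprintf("organ %s rasterised to zero volume", org$name))
    if (any(lab[hit] != 0L)) stop("organ collision")
    lab[hit] <- i
    v <- voi(m * 1, geom, paste0(org$name, "@", time_tag))
    vois[[org$name]] <- v
    vols[org$name] <- voi_volume_mL(v)
  }
  list(labels = voxel_grid(lab, geom$spacing, geom$origin),
       vois = vois, volumes_mL = vols)
}

# Solve the shape scale so that the number of voxel centres inside matches the
# target volume as closely as the raster allows, then return the logical mask.
# The final mask is the `round(target / voxel_volume)` voxels of smallest
# shape-normalised radius (exact ties broken by array order), so the achieved
# volume is always within half a voxel volume of the target.
rasterize_organ <- function(org, target_mL, geom) {
  vvox <- voxel_volume_mL(geom)
  ratios <- org$shape_params$axis_ratios
  # analytic scale guess for an ellipsoid of the target volume
  s0 <- (3 * target_mL * 1000 / (4 * pi * prod(ratios)))^(1 / 3)
  bb <- lapply(1:3, function(a) {
    co <- axis_coords(geom, a)
    pad <- 1.3 * s0 * ratios[a] + 2 * geom$spacing[a]
    which(co >= org$center_mm[a] - pad & co <= org$center_mm[a] + pad)
  })
  if (any(vapply(bb, length, 1L) == 0))
    stop(sprintf("organ %s lies outside the grid", org$name))
  co <- lapply(1:3, function(a) axis_coords(geom, a)[bb[[a]]] - org$center_mm[a])
  nb <- vapply(bb, length, 1L)
  # shape-normalised squared radius of every bbox voxel centre
  Z <- rep.int(co[[1]], nb[2] * nb[3])
  Y <- rep.int(rep(co[[2]], each = nb[1]), nb[3])
  X <- rep(co[[3]], each = nb[1] * nb[2])
  u <- (Z / ratios[1])^2 + (Y / ratios[2])^2 + (X / ratios[3])^2
  n_target <- target_mL / vvox
  N <- max(1L, round(n_target))
  if (org$shape == "ellipsoid") {
    eligible <- rep(TRUE, length(u))
  } else {
    # bean: ellipsoid minus an indentation sphere of radius k*r3*s riding on
    # the +x surface point; carve geometry fixed at the bisected scale, then
    # rank-select on u for the exact count
    k <- org$shape_params$concavity_depth
    r3 <- ratios[3]
    count_at <- function(s)
      sum(u <= s^2 & (Z^2 + Y^2 + (X - r3 * s)^2) > (k * r3 * s)^2)
    lo <- 0.7 * s0; hi <- 1.3 * s0
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (count_at(mid) < n_target) lo <- mid else hi <- mid
    }
    s_hat <- (lo + hi) / 2
    eligible <- (Z^2 + Y^2 + (X - r3 * s_hat)^2) > (k * r3 * s_hat)^2
  }
  idx_el <- which(eligible)
  if (length(idx_el) < N)
    stop(sprintf("organ %s cannot reach %.1f mL inside the grid (truncated?)",
                 org$name, target_mL))
  sel <- idx_el[order(u[idx_el])[seq_len(N)]]
  inside_bb <- logical(length(u))
  inside_bb[sel] <- TRUE
  m <- array(FALSE, geom$dim)
  m[bb[[1]], bb[[2]], bb[[3]]] <- array(inside_bb, nb)
  m
}

#' Ground-truth tri-exponential kinetics for a phantom organ
#'
#' Parameters of the five-parameter tri-exponential time course
#' `f(t) = A1 e^(-b t) + A2 e^(-c t) - (A1 + A2) e^(-d t)` used as the
#' generating truth. In `"activity_primary"` mode (the default mechanism) `f`
#' is the organ's total activity (Bq) and the concentration is `f(t) / V(tag)`,
#' so transient volume swelling dilutes concentration; in
#' `"concentration_primary"` mode `f` is the concentration itself (Bq/mL).
#'
#' @param A1,A2 Positive amplitudes (Bq or Bq/mL depending on `mode`).
#' @param b,c,d Positive rate constants (1/h). For physically meaningful
#'   Lu-177 phantoms the slowest rate should be at least the physical decay
#'   constant `log(2)/159.53 h ~ 4.34e-3 /h`.
#' @param mode `"activity_primary"` or `"concentration_primary"`.
#' @return An object of class `kinetics_truth`.
#' @export
kinetics_truth <- function(A1, A2, b, c, d,
                           mode = c("activity_primary", "concentration_primary")) {
  mode <- match.arg(mode)
  if (any(c(b, c, d) <= 0)) stop("rate constants must be positive")
  if (A1 < 0 || A2 < 0) stop("amplitudes must be non-negative")
  structure(list(A1 = A1, A2 = A2, b = b, c = c, d = d, mode = mode),
            class = "kinetics_truth")
}

#' Evaluate the true activity concentration of an organ at time t
#'
#' @param truth A [kinetics_truth()].
#' @param organ An [organ_spec()] (supplies the tag-dependent volume in
#'   `"activity_primary"` mode).
#' @param t Time since administration start, hours (>= 0).
#' @param tag Time-point tag used to look up the organ volume; required in
#'   `"activity_primary"` mode.
#' @return Concentration in Bq/mL.
#' @export
true_concentration <- function(truth, organ, t, tag = NULL) {
  stopifnot(inherits(truth, "kinetics_truth"))
  if (t < 0) stop("t must be >= 0")
  f <- triexp_value(triexp_params(truth$A1, truth$A2, truth$b, truth$c, truth$d), t)
  if (f < -1e-9 * max(truth$A1 + truth$A2, 1))
    stop("invalid truth parameters: negative model value at requested time")
  if (truth$mode == "concentration_primary") return(max(f, 0))
  if (is.null(tag)) stop("tag is required in activity_primary mode")
  max(f, 0) / organ_volume_mL(organ, tag)
}

#' Acquisition settings for SPECT rendering
#'
#' @param times_h Named numeric of nominal sample times (hours post
#'   administration) per tag; defaults to D0 = 4, D1 = 24, D2 = 48, D7 = 168.
#' @param jitter Logical; if `TRUE`, per-phantom acquisition times are drawn
#'   uniformly within the observed scheduling windows
#'   (D0 1.3-5.8, D1 19.5-24.5, D2 43.8-51.2, D7 169.1-173 h).
#' @param psf_fwhm_mm Isotropic Gaussian PSF FWHM, mm (default 12, a
#'   representative medium-energy-collimator resolution for the 208 keV
#'   Lu-177 photopeak).
#' @param noise `"none"` or `"poisson"`.
#' @param counts_per_Bq_mL_voxel Calibration factor mapping concentration to
#'   expected counts per voxel when `noise = "poisson"`.
#' @param seed Integer seed governing every stochastic draw of the generator.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(times_h = c(D0 = 4, D1 = 24, D2 = 48, D7 = 168),
                             jitter = FALSE,
                             psf_fwhm_mm = 12,
                             noise = c("none", "poisson"),
                             counts_per_Bq_mL_voxel = 1e-4,
                             seed = 1L) {
  noise <- match.arg(noise)
  if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0")
  if (is.unsorted(times_h, strictly = TRUE)) stop("times must be strictly increasing")
  structure(list(times_h = times_h, jitter = isTRUE(jitter),
                 psf_fwhm_mm = psf_fwhm_mm, noise = noise,
                 counts_per_Bq_mL_voxel = counts_per_Bq_mL_voxel,
                 seed = as.integer(seed)),
            class = "acquisition_spec")
}

# observed scheduling windows (hours) for optional acquisition-time jitter
acquisition_windows <- function() {
  list(D0 = c(1.3, 5.8), D1 = c(19.5, 24.5), D2 = c(43.8, 51.2),
       D7 = c(169.1, 173.0))
}

#' Render a SPECT-like image from a phantom label map
#'
#' Paints each organ at its true concentration on the CT-resolution label
#' grid, downsamples to the SPECT geometry by volume-weighted averaging,
#' convolves with the isotropic Gaussian PSF (`sigma = FWHM/2.3548`), and
#' optionally applies Poisson noise on calibrated counts. This Gaussian-PSF
#' chain is the package's declared surrogate for a full Monte Carlo OSEM
#' reconstruction; it reproduces partial-volume spill-out, which is the
#' mechanism under study, but no attenuation, scatter, or septal penetration.
#'
#' @param labels Label `voxel_grid` from [make_phantom()].
#' @param concentrations Numeric vector of per-organ concentrations (Bq/mL),
#'   indexed by label id (`concentrations[i]` for label `i`).
#' @param acq An [acquisition_spec()].
#' @param spect_geometry Target SPECT geometry; default covers the label
#'   grid's physical extent with 4.42 mm isotropic voxels.
#' @param rng Optional RNG seed overriding `acq$seed` for the noise draw.
#' @return A `voxel_grid` of activity concentration (Bq/mL) on the SPECT
#'   geometry.
#' @export
render_spect <- function(labels, concentrations, acq,
                         spect_geometry = NULL, rng = NULL) {
  stopifnot(inherits(labels, "voxel_grid"), inherits(acq, "acquisition_spec"))
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (is.null(spect_geometry))
    spect_geometry <- default_spect_geometry(labels)
  tg <- as_grid_geometry(spect_geometry)
  painted <- array(0, dim(labels$values))
  for (i in seq_along(concentrations)) {
    if (concentrations[i] != 0)
      painted[labels$values == i] <- concentrations[i]
  }
  vals <- resample_field(painted, labels, tg)
  img <- blur_grid(voxel_grid(vals, tg$spacing, tg$origin), acq$psf_fwhm_mm)
  if (acq$noise == "poisson") {
    cal <- acq$counts_per_Bq_mL_voxel
    if (cal <= 0) stop("counts_per_Bq_mL_voxel must be positive")
    seed <- if (is.null(rng)) acq$seed else rng
    counts <- withr_seed(seed, stats::rpois(length(img$values),
                                            pmax(img$values, 0) * cal))
    img <- voxel_grid(array(counts / cal, dim(img$values)),
                      tg$spacing, tg$origin)
  }
  img
}

# run expr under a temporary RNG state restored afterwards
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default SPECT geometry covering a grid's physical extent
#'
#' 4.42 mm isotropic voxels (the clinical SPECT matrix), centred on the same
#' physical extent as `grid`.
#'
#' @param grid A `voxel_grid` or `grid_geometry`.
#' @param spacing_mm SPECT voxel size (default 4.42 mm isotropic).
#' @return A `grid_geometry`.
#' @export
default_spect_geometry <- function(grid, spacing_mm = 4.42) {
  g <- as_grid_geometry(grid)
  sp <- rep(spacing_mm, 3)
  # physical extent (outer voxel faces) of the source grid
  lo <- g$origin - g$spacing / 2
  hi <- g$origin + (g$dim - 0.5) * g$spacing
  n <- pmax(1L, as.integer(ceiling((hi - lo) / sp)))
  centre <- (lo + hi) / 2
  origin <- centre - (n - 1) / 2 * sp
  grid_geometry(n, sp, origin)
}

#' Default CT-like label-grid geometry
#'
#' 1.105 mm in-plane (one quarter of the SPECT voxel, so in-plane CT-to-SPECT
#' resampling nests 4:1) and 5 mm slices, matching the acquisition CT slice
#' thickness.
#'
#' @param extent_mm Physical extent (z, y, x) in mm.
#' @param center_mm World centre of the grid.
#' @return A `grid_geometry`.
#' @export
default_ct_geometry <- function(extent_mm = c(160, 160, 160),
                                center_mm = c(0, 0, 0)) {
  sp <- c(5, 1.105, 1.105)
  n <- pmax(1L, as.integer(round(extent_mm / sp)))
  origin <- center_mm - (n - 1) / 2 * sp
  grid_geometry(n, sp, origin)
}
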