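#' VoxelGrid: a 3D scalar field with geometry
#'
#' Container for activity (Bq/mL, relative units), density (g/cm^3) or
#' integer label volumes.  World coordinates follow the voxel-centre
#' convention: the centre of voxel `(i, j, k)` (1-based) lies at
#' `origin + (c(i, j, k) - 1) * voxelSize` mm.
#'
#' @slot values 3D numeric array.
#' @slot voxelSize numeric length 3, voxel edge lengths in mm.
#' @slot origin numeric length 3, world mm of the first voxel centre.
#' @slot kind one of `"activity"`, `"density"`, `"label"`.
#' @export
setClass("VoxelGrid",
  representation(values = "array", voxelSize = "numeric",
                 origin = "numeric", kind = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "values must be a 3D array")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive numbers (mm)")
    if (length(object@origin) != 3L)
      msg <- c(msg, "origin must have length 3")
    if (!object@kind %in% c("activity", "density", "label"))
      msg <- c(msg, "kind must be activity, density or label")
    if (any(!is.finite(object@values)))
      msg <- c(msg, "values must be finite")
    if (object@kind %in% c("activity", "density") &&
        any(object@values < 0))
      msg <- c(msg, sprintf("%s values must be non-negative", object@kind))
    if (length(msg)) msg else TRUE
  })

#' Construct a VoxelGrid
#'
#' @param values 3D numeric array.
#' @param voxelSize voxel edge length(s) in mm; scalar or length 3.
#' @param origin world mm of the first voxel centre; default centres the
#'   grid on the world origin.
#' @param kind `"activity"`, `"density"` or `"label"`.
#' @return A [VoxelGrid-class] object.
#' @export
VoxelGrid <- function(values, voxelSize, origin = NULL, kind = "activity") {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  d <- dim(values)
  if (is.null(origin)) origin <- -(d - 1) / 2 * voxelSize
  new("VoxelGrid", values = values, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin), kind = kind)
}

#' APSFParams: annihilation point-spread profile parameters
#'
#' Parameters of the radial annihilation point-spread function
#' `aPSF(r) = C * ((a*r + 1) * (1 - r/r0)^n - epsilon/r^n) / r^2`,
#' clamped at zero where the bracket is negative and zero beyond the
#' maximum range `r0`.  Distances are in water-equivalent mm at the
#' reference density `rhoRef`.
#'
#' @slot C normalization constant.
#' @slot a linear shape parameter (1/mm).
#' @slot n exponent (unitless).
#' @slot epsilon tail/core parameter (unitless).
#' @slot r0 maximum range (mm).
#' @slot rhoRef reference density (g/cm^3); water = 1.
#' @export
setClass("APSFParams",
  representation(C = "numeric", a = "numeric", n = "numeric",
                 epsilon = "numeric", r0 = "numeric", rhoRef = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@r0 <= 0) msg <- c(msg, "r0 must be > 0")
    if (object@rhoRef <= 0) msg <- c(msg, "rhoRef must be > 0")
    if (object@epsilon < 0) msg <- c(msg, "epsilon must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @param C,a,n,epsilon,r0,rhoRef see [APSFParams-class].
#' @return An [APSFParams-class] object.
#' @rdname APSFParams-class
#' @export
apsfParams <- function(C = 1, a = 0, n = 1, epsilon = 0, r0 = 17,
                       rhoRef = 1) {
  # Class= must be named: the slot "C" would otherwise partially match it
  new(Class = "APSFParams", C = C, a = a, n = n, epsilon = epsilon,
      r0 = r0, rhoRef = rhoRef)
}

#' RadialProfile: sampled radial annihilation density
#'
#' The fit target for [fitAPSF()]: annihilation density per unit volume
#' sampled at strictly increasing radii (mm).
#'
#' @slot radii numeric, mm, strictly increasing, > 0.
#' @slot values numeric, non-negative densities.
#' @export
setClass("RadialProfile",
  representation(radii = "numeric", values = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@radii) != length(object@values))
      msg <- c(msg, "radii and values must have equal length")
    if (any(object@radii <= 0) || any(diff(object@radii) <= 0))
      msg <- c(msg, "radii must be strictly increasing and > 0")
    if (any(object@values < 0)) msg <- c(msg, "values must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @param radii,values see [RadialProfile-class].
#' @rdname RadialProfile-class
#' @export
radialProfile <- function(radii, values)
  new("RadialProfile", radii = as.numeric(radii), values = as.numeric(values))

#' DiscreteKernel: a normalized 3D convolution stencil
#'
#' @slot size odd integer, voxels per axis.
#' @slot weights `size^3` array of non-negative weights summing to 1.
#' @slot voxelSize numeric length 3, mm.
#' @slot contextDensity g/cm^3 for uniform kernels; `NA` for spatially
#'   variant kernels.
#' @export
setClass("DiscreteKernel",
  representation(size = "integer", weights = "array",
                 voxelSize = "numeric", contextDensity = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@size %% 2L == 0L) msg <- c(msg, "size must be odd")
    if (!all(dim(object@weights) == object@size))
      msg <- c(msg, "weights must be a size^3 array")
    if (any(object@weights < 0)) msg <- c(msg, "weights must be >= 0")
    if (abs(sum(object@weights) - 1) > 1e-9)
      msg <- c(msg, "weights must sum to 1 within 1e-9")
    if (length(msg)) msg else TRUE
  })

#' ProjectionGeometry: stacked-2D parallel-beam sampling
#'
#' @slot angles projection angles in radians over `[0, pi)`, strictly
#'   increasing.
#' @slot nRadial number of radial bins.
#' @slot radialSpacing radial bin width in mm.
#' @slot nSlices number of axial slices.
#' @export
setClass("ProjectionGeometry",
  representation(angles = "numeric", nRadial = "integer",
                 radialSpacing = "numeric", nSlices = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(diff(object@angles) <= 0))
      msg <- c(msg, "angles must be strictly increasing")
    if (any(object@angles < 0) || any(object@angles >= pi))
      msg <- c(msg, "angles must lie in [0, pi)")
    if (object@radialSpacing <= 0) msg <- c(msg, "radialSpacing must be > 0")
    if (object@nRadial < 1L || object@nSlices < 1L)
      msg <- c(msg, "nRadial and nSlices must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' @param nAngles number of projection angles, evenly spaced over
#'   `[0, pi)`.
#' @param nRadial number of radial bins.
#' @param radialSpacing radial bin width (mm).
#' @param nSlices number of axial slices.
#' @rdname ProjectionGeometry-class
#' @export
projectionGeometry <- function(nAngles, nRadial, radialSpacing, nSlices) {
  new("ProjectionGeometry",
      angles = (seq_len(nAngles) - 1) / nAngles * pi,
      nRadial = as.integer(nRadial),
      radialSpacing = as.numeric(radialSpacing),
      nSlices = as.integer(nSlices))
}

#' ProjectionData: a sinogram stack with subset partition
#'
#' @slot values array `(nRadial, nAngles, nSlices)` of counts or expected
#'   values.
#' @slot geometry the [ProjectionGeometry-class].
#' @slot subsets list of disjoint, covering angle-index vectors used by
#'   OSEM (default 16 interleaved subsets).
#' @slot meta list of provenance fields (seed, scale, truth blur mode,
#'   expected sinogram when requested).
#' @export
setClass("ProjectionData",
  representation(values = "array", geometry = "ProjectionGeometry",
                 subsets = "list", meta = "list"),
  validity = function(object) {
    msg <- character()
    g <- object@geometry
    if (!all(dim(object@values) ==
             c(g@nRadial, length(g@angles), g@nSlices)))
      msg <- c(msg, "values dims must be (nRadial, nAngles, nSlices)")
    if (any(object@values < 0)) msg <- c(msg, "values must be >= 0")
    idx <- sort(unlist(object@subsets))
    if (!identical(as.integer(idx), seq_along(g@angles)))
      msg <- c(msg, "subsets must partition the angle indices")
    if (length(msg)) msg else TRUE
  })

#' TissueSegmentation: labelled tissue classes with densities
#'
#' @slot labels integer 3D array, one label per voxel.
#' @slot classes data.frame with columns `label`, `name`, `density`
#'   (g/cm^3) used to build per-class kernels.
#' @export
setClass("TissueSegmentation",
  representation(labels = "array", classes = "data.frame"),
  validity = function(object) {
    msg <- character()
    need <- c("label", "name", "density")
    if (!all(need %in% names(object@classes)))
      msg <- c(msg, "classes needs columns label, name, density")
    else {
      if (any(object@classes$density <= 0))
        msg <- c(msg, "class densities must be > 0")
      if (!all(unique(as.vector(object@labels)) %in% object@classes$label))
        msg <- c(msg, "every voxel label must appear in the class table")
    }
    if (length(msg)) msg else TRUE
  })

#' ReconConfig: OSEM + PRC reconstruction settings
#'
#' @slot iterations number of full iterations (1-100 in the sweeps).
#' @slot subsets number of ordered subsets (default 16).
#' @slot prcMode `"none"`, `"td"` or `"tdsv"`.
#' @slot tdLevels segmentation levels for TD mode (1-3): 1 = water
#'   everywhere, 2 = air/water, 3 = lung/water/bone.
#' @slot kernelSize odd stencil size in voxels (21 or 41 in the naming
#'   convention "TDSV 41"); also used for TD kernels.
#' @slot boundary `"air"` or `"clamp"`: density assumed outside the grid
#'   when tracing rays.
#' @slot sliceIndependent logical; treat axial slices as independent
#'   slab experiments (in-plane blur, axial spread as escape) -- for
#'   quasi-2D thick-slab volumes.
#' @export
setClass("ReconConfig",
  representation(iterations = "integer", subsets = "integer",
                 prcMode = "character", tdLevels = "integer",
                 kernelSize = "integer", boundary = "character",
                 sliceIndependent = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@iterations < 1L) msg <- c(msg, "iterations must be >= 1")
    if (object@subsets < 1L) msg <- c(msg, "subsets must be >= 1")
    if (!object@prcMode %in% c("none", "td", "tdsv"))
      msg <- c(msg, "prcMode must be none, td or tdsv")
    if (!object@tdLevels %in% 1:3) msg <- c(msg, "tdLevels must be 1-3")
    if (object@kernelSize %% 2L == 0L)
      msg <- c(msg, "kernelSize must be odd")
    if (!object@boundary %in% c("air", "clamp"))
      msg <- c(msg, "boundary must be air or clamp")
    if (length(msg)) msg else TRUE
  })

#' @param iterations,subsets,prcMode,tdLevels,kernelSize,boundary see
#'   [ReconConfig-class].
#' @rdname ReconConfig-class
#' @export
reconConfig <- function(iterations = 40, subsets = 16,
                        prcMode = c("none", "td", "tdsv"), tdLevels = 1,
                        kernelSize = 41, boundary = c("air", "clamp"),
                        sliceIndependent = FALSE) {
  new("ReconConfig", iterations = as.integer(iterations),
      subsets = as.integer(subsets), prcMode = match.arg(prcMode),
      tdLevels = as.integer(tdLevels), kernelSize = as.integer(kernelSize),
      boundary = match.arg(boundary),
      sliceIndependent = isTRUE(sliceIndependent))
}

#' GatingScheme: respiratory-binned acquisitions
#'
#' @slot phases representative phase per bin (midpoints of equal-width
#'   phase bins).
#' @slot edges bin edges on `[0, 1)`.
#' @slot projections list of per-bin [ProjectionData-class].
#' @slot densities list of per-bin density [VoxelGrid-class] (the phantom
#'   frozen at each bin's phase).
#' @export
setClass("GatingScheme",
  representation(phases = "numeric", edges = "numeric",
                 projections = "list", densities = "list"))

#' LineProfile: a sampled 1D profile
#'
#' @slot positions mm along the line from its start, strictly increasing.
#' @slot values interpolated activity values.
#' @export
setClass("LineProfile",
  representation(positions = "numeric", values = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(diff(object@positions) <= 0))
      msg <- c(msg, "positions must be strictly increasing")
    if (any(!is.finite(object@values)))
      msg <- c(msg, "values must be finite")
    if (length(msg)) msg else TRUE
  })

#' FrameSchedule: dynamic frame schedule
#'
#' @slot counts frame repeat counts.
#' @slot durations frame durations in seconds.
#' @slot discard interval discarded at the start of the scan (s).
#' @export
setClass("FrameSchedule",
  representation(counts = "integer", durations = "numeric",
                 discard = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@counts < 1L)) msg <- c(msg, "counts must be >= 1")
    if (any(object@durations <= 0)) msg <- c(msg, "durations must be > 0")
    if (object@discard < 0) msg <- c(msg, "discard must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' OsemResult: per-iteration reconstruction snapshots
#'
#' @slot volumes named list of [VoxelGrid-class] snapshots.
#' @slot iterations iteration index of each snapshot.
#' @slot logLik Poisson log-likelihood per full iteration (when computed).
#' @slot config the [ReconConfig-class] used.
#' @export
setClass("OsemResult",
  representation(volumes = "list", iterations = "integer",
                 logLik = "numeric", config = "ReconConfig"))
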