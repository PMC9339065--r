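# Stacked-2D parallel-beam projection model and the Poisson acquisition
# simulator.  The forward/back projector pair is matched (exact
# transpose), which OSEM relies on.

#' Default projection geometry for a volume
#'
#' @param grid a [VoxelGrid-class] (defines the field of view).
#' @param nAngles number of evenly spaced angles over `[0, pi)`; must be
#'   divisible by the OSEM subset count (default 128 = 8 x 16).
#' @param radialFactor radial coverage relative to the widest in-plane
#'   grid dimension.
#' @return A [ProjectionGeometry-class]; radial spacing equals the
#'   in-plane voxel size.
#' @export
defaultGeometry <- function(grid, nAngles = 128, radialFactor = 1.45) {
  stopifnot(is(grid, "VoxelGrid"))
  d <- dim(grid)
  nr <- ceiling(max(d[1:2]) * radialFactor)
  if (nr %% 2L == 0L) nr <- nr + 1L
  projectionGeometry(nAngles, nr, grid@voxelSize[1], d[3])
}

# interleaved angle subsets; processed in bit-reversed order by OSEM
.makeSubsets <- function(nAngles, nSubsets) {
  if (nAngles %% nSubsets != 0)
    stop(sprintf("subsets (%d) must divide the angle count (%d)",
                 nSubsets, nAngles))
  lapply(seq_len(nSubsets), function(s)
    as.integer(seq(s, nAngles, by = nSubsets)))
}

.bitReverse <- function(n) {
  ord <- integer(n)
  bits <- ceiling(log2(n))
  for (i in seq_len(n)) {
    v <- i - 1L
    r <- 0L
    for (b in seq_len(bits)) {
      r <- bitwShiftL(r, 1L) + bitwAnd(v, 1L)
      v <- bitwShiftR(v, 1L)
    }
    ord[i] <- r + 1L
  }
  ord[ord <= n]
}

.checkGridGeom <- function(grid, geom) {
  if (dim(grid)[3] != geom@nSlices)
    stop("grid and geometry disagree on the number of axial slices")
}

#' Forward project a volume
#'
#' Line integrals (mm-weighted) of the volume along every line of
#' response; a linear operator implemented as a pixel-driven projector
#' with linear radial interpolation.
#'
#' @param image a [VoxelGrid-class].
#' @param geom a [ProjectionGeometry-class].
#' @param subsets number of OSEM subsets recorded in the result (default
#'   16 when it divides the angle count, else 1).
#' @return A [ProjectionData-class] of expected line integrals.
#' @export
forwardProject <- function(image, geom, subsets = NULL) {
  stopifnot(is(image, "VoxelGrid"), is(geom, "ProjectionGeometry"))
  .checkGridGeom(image, geom)
  p <- .fproj(image@values, image@voxelSize, geom)
  if (is.null(subsets))
    subsets <- if (length(geom@angles) %% 16L == 0L) 16L else 1L
  new("ProjectionData", values = p, geometry = geom,
      subsets = .makeSubsets(length(geom@angles), subsets), meta = list())
}

.fproj <- function(values, vox, geom, angleIdx = NULL) {
  ang <- if (is.null(angleIdx)) geom@angles else geom@angles[angleIdx]
  d <- dim(values)
  array(cppForwardProject(as.numeric(values), as.integer(d), vox, ang,
                          geom@nRadial, geom@radialSpacing),
        dim = c(geom@nRadial, length(ang), d[3]))
}

.bproj <- function(proj, dims, vox, geom, angleIdx = NULL) {
  ang <- if (is.null(angleIdx)) geom@angles else geom@angles[angleIdx]
  array(cppBackProject(as.numeric(proj), as.integer(dims), vox, ang,
                       geom@nRadial, geom@radialSpacing), dim = dims)
}

#' Back project a sinogram
#'
#' The exact adjoint of [forwardProject()].
#'
#' @param proj a [ProjectionData-class].
#' @param grid a [VoxelGrid-class] template defining the output grid.
#' @return A [VoxelGrid-class].
#' @export
backProject <- function(proj, grid) {
  stopifnot(is(proj, "ProjectionData"), is(grid, "VoxelGrid"))
  .checkGridGeom(grid, proj@geometry)
  v <- .bproj(proj@values, dim(grid), grid@voxelSize, proj@geometry)
  VoxelGrid(v, grid@voxelSize, grid@origin, "activity")
}

#' Attenuation factors for a density volume
#'
#' Per line of response: `exp(-muWater * integral of rho dl)`, the linear
#' attenuation coefficient scaling linearly with density.
#'
#' @param density a density [VoxelGrid-class].
#' @param geom a [ProjectionGeometry-class].
#' @param muWater linear attenuation coefficient of water at 511 keV,
#'   1/mm (default 0.0096).
#' @return Array of factors in `(0, 1]` with sinogram dimensions.
#' @export
attenuationFactors <- function(density, geom, muWater = 0.0096) {
  stopifnot(is(density, "VoxelGrid"))
  if (any(density@values < 0)) stop("attenuationFactors: negative density")
  .checkGridGeom(density, geom)
  exp(-muWater * .fproj(density@values, density@voxelSize, geom))
}

# Gaussian detector blur along the radial coordinate (applied in
# projection space; models intrinsic scanner resolution in simulation
# only -- the reconstruction does not model it)
.radialBlurMatrix <- function(nRadial, ds, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / ds
  d <- abs(outer(seq_len(nRadial), seq_len(nRadial), "-"))
  W <- exp(-d^2 / (2 * sigma^2))
  sweep(W, 1, colSums(W), "/") # column-normalized: counts preserved
}

.applyRadialBlur <- function(p, W) {
  d <- dim(p)
  array(W %*% matrix(p, nrow = d[1]), dim = d)
}

#' Simulate a PET acquisition
#'
#' Applies positron-range blur to the activity (the annihilation-site
#' image), forward projects, attenuates, blurs radially with the detector
#' response, scales the expected total to `totalCounts` and draws Poisson
#' counts.  Fully reproducible from the seed.
#'
#' @param activity activity [VoxelGrid-class].
#' @param density density [VoxelGrid-class] (required for attenuation and
#'   for `prcTruthMode = "variant"`).
#' @param params [APSFParams-class] (required unless
#'   `prcTruthMode = "none"`).
#' @param geom a [ProjectionGeometry-class].
#' @param totalCounts expected total number of coincidences.
#' @param seed RNG seed.
#' @param prcTruthMode `"none"` (no range blur), `"uniform"` (water
#'   kernel everywhere) or `"variant"` (spatially variant kernels from
#'   the density map).
#' @param detectorFwhm intrinsic detector resolution, mm FWHM (0
#'   disables).
#' @param attenuate apply attenuation factors?
#' @param muWater water attenuation coefficient, 1/mm.
#' @param kernelSize stencil size for the truth blur.
#' @param boundary out-of-grid density rule for ray tracing
#'   (see [rayMeanDensity()]).
#' @param poisson draw Poisson counts? `FALSE` returns the expected
#'   (noiseless) sinogram.
#' @param sliceIndependent treat axial slices as independent slab
#'   experiments: range blur acts in-plane only and axial spread counts
#'   as escape (quasi-2D thick-slab volumes).
#' @param subsets OSEM subsets recorded in the result.
#' @return A [ProjectionData-class]; `meta` holds seed, scaling and the
#'   expected sinogram.
#' @export
simulateAcquisition <- function(activity, density = NULL, params = NULL,
                                geom, totalCounts, seed = 1,
                                prcTruthMode = c("none", "uniform",
                                                 "variant"),
                                detectorFwhm = 1.6, attenuate = !is.null(density),
                                muWater = 0.0096, kernelSize = 41,
                                boundary = "air", poisson = TRUE,
                                sliceIndependent = FALSE, subsets = NULL) {
  prcTruthMode <- match.arg(prcTruthMode)
  stopifnot(is(activity, "VoxelGrid"), totalCounts > 0)
  .checkGridGeom(activity, geom)

  img <- activity@values
  if (prcTruthMode == "uniform") {
    stopifnot(!is.null(params))
    k <- buildUniformKernel(params, params@rhoRef, kernelSize,
                            activity@voxelSize)
    img <- .applyKernel(img, k, zOnly = sliceIndependent)
  } else if (prcTruthMode == "variant") {
    stopifnot(!is.null(params), !is.null(density))
    bank <- .kernelBank(params, density, .checkOdd(kernelSize), boundary,
                        sliceIndependent = sliceIndependent)
    img <- array(cppTdsvApply(as.numeric(img), as.integer(dim(img)),
                              bank$w, bank$size, FALSE, sliceIndependent),
                 dim = dim(img))
  }

  p <- .fproj(img, activity@voxelSize, geom)
  if (attenuate) {
    stopifnot(!is.null(density))
    p <- p * attenuationFactors(density, geom, muWater)
  }
  if (detectorFwhm > 0) {
    W <- .radialBlurMatrix(geom@nRadial, geom@radialSpacing, detectorFwhm)
    p <- .applyRadialBlur(p, W)
  }
  scale <- totalCounts / sum(p)
  lambda <- p * scale
  if (poisson) {
    set.seed(seed)
    counts <- array(rpois(length(lambda), lambda), dim = dim(lambda))
  } else {
    counts <- lambda
  }
  if (is.null(subsets))
    subsets <- if (length(geom@angles) %% 16L == 0L) 16L else 1L
  new("ProjectionData", values = counts, geometry = geom,
      subsets = .makeSubsets(length(geom@angles), subsets),
      meta = list(seed = seed, scale = scale, truthMode = prcTruthMode,
                  expected = lambda, detectorFwhm = detectorFwhm,
                  attenuated = attenuate))
}

# crop a centred kernel to the axes' useful extent and apply by direct
# convolution (mass spread beyond the volume is dropped).  zOnly keeps
# the central axial plane without renormalizing: slices are treated as
# independent slab experiments and axial spread as escape.
.applyKernel <- function(values, kernel, adjoint = FALSE, zOnly = FALSE) {
  w <- kernel@weights
  if (zOnly) {
    R <- (dim(w)[3] + 1) / 2
    w <- w[, , R, drop = FALSE]
  }
  keep <- lapply(1:3, function(ax) {
    m <- apply(w, ax, sum)
    R <- (length(m) - 1) / 2
    use <- max(abs(which(m > 1e-12) - R - 1), 0)
    (R + 1 - use):(R + 1 + use)
  })
  w <- w[keep[[1]], keep[[2]], keep[[3]], drop = FALSE]
  array(cppConvolve3d(as.numeric(values), as.integer(dim(values)),
                      as.numeric(w), as.integer(dim(w)), adjoint),
        dim = dim(values))
}
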