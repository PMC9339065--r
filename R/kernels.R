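# Discretized annihilation kernels.  All kernels share the voxel
# integration rule: off-centre voxels take the aPSF value at the
# equivalent distance of their centre times the voxel volume; the centre
# voxel integrates the radial density over the half-voxel sphere, which
# absorbs the 1/r^2 singularity.  Weights outside the size^3 stencil are
# discarded and the stencil renormalized to sum 1 (the paper-style fixed
# kernel sizes 21 and 41 truncate the profile, deliberately).

.airDensity <- 0.0012

# half-voxel sphere radius: half the smallest voxel edge
.halfVoxelRadius <- function(voxelSize) min(voxelSize) / 2

.asVox3 <- function(voxelSize) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  stopifnot(length(voxelSize) == 3L, all(voxelSize > 0))
  as.numeric(voxelSize)
}

.checkOdd <- function(size) {
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L)
    stop("kernel size must be a positive odd integer")
  size
}

# Sources whose annihilation yield within the stencil is negligible
# (under 0.1%, e.g. air: the positron escapes the stencil before
# meeting matter; the least dense tissue class retains ~50%)
# degrade to delta kernels -- the emission is kept local instead of
# creating an ill-conditioned spreader with near-zero mass.
.minKernelYield <- 1e-3

.normalizeKernel <- function(w, size, voxelSize, contextDensity) {
  total <- sum(w)
  if (total <= .minKernelYield) {
    w[] <- 0
    w[(length(w) + 1) / 2] <- 1
  } else {
    w <- w / total
  }
  new("DiscreteKernel", size = size,
      weights = array(w, dim = rep(size, 3L)),
      voxelSize = voxelSize, contextDensity = contextDensity)
}

#' Build a uniform-density annihilation kernel
#'
#' Discretizes the aPSF into a `size^3` stencil for a homogeneous medium
#' of density `rho`: the tissue-dependent (TD) kernel for one segmented
#' tissue class.  Distances are scaled by `rho / rhoRef` (the
#' water-equivalent distance), so denser tissue yields a narrower kernel.
#'
#' @param params an [APSFParams-class].
#' @param rho tissue density, g/cm^3.
#' @param size odd stencil size in voxels (e.g. 21 or 41).
#' @param voxelSize voxel edge length(s), mm (scalar or length 3).
#' @return A normalized [DiscreteKernel-class].
#' @export
buildUniformKernel <- function(params, rho, size = 41, voxelSize = 0.4) {
  stopifnot(is(params, "APSFParams"), rho > 0)
  size <- .checkOdd(size)
  vox <- .asVox3(voxelSize)
  lut <- apsfLut(params)
  w <- cppUniformKernel(size, vox, lut$B, lut$M, lut$r0,
                        .halfVoxelRadius(vox), rho, params@rhoRef)
  .normalizeKernel(w, size, vox, rho)
}

#' Ray-averaged density between two voxels
#'
#' The length-weighted mean density of the voxels penetrated by the
#' straight segment from the centre of `center` to the centre of
#' `center + offset` -- the density that the spatially variant (TDSV)
#' kernel assigns to that offset.  Voxels outside the grid contribute the
#' air density (default) or, with `boundary = "clamp"`, the density of
#' the nearest edge voxel (appropriate for cropped/extruded objects).
#'
#' @param density a density [VoxelGrid-class].
#' @param center voxel index (1-based, length 3).
#' @param offset voxel displacement (length 3, integers).
#' @param boundary `"air"` or `"clamp"`.
#' @param airDensity density used outside the grid in `"air"` mode.
#' @return Mean density in g/cm^3.
#' @export
rayMeanDensity <- function(density, center, offset,
                           boundary = c("air", "clamp"),
                           airDensity = .airDensity) {
  stopifnot(is(density, "VoxelGrid"))
  boundary <- match.arg(boundary)
  d <- dim(density@values)
  center <- as.integer(center)
  offset <- as.integer(offset)
  stopifnot(length(center) == 3L, length(offset) == 3L,
            all(center >= 1L), all(center <= d))
  cppRayMeanDensity(as.numeric(density@values), as.integer(d),
                    center - 1L, offset, airDensity,
                    boundary == "clamp")
}

#' Build a spatially variant (TDSV) annihilation kernel
#'
#' The kernel for one source voxel in a heterogeneous density map: each
#' offset's weight is evaluated at the equivalent distance computed with
#' the ray-averaged density along the segment from the source to that
#' offset ([rayMeanDensity()]), so the kernel adapts to tissue borders.
#'
#' @param params an [APSFParams-class].
#' @param density a density [VoxelGrid-class].
#' @param center source voxel index (1-based, length 3).
#' @param size odd stencil size in voxels.
#' @param boundary,airDensity out-of-grid handling, see
#'   [rayMeanDensity()].
#' @return A normalized [DiscreteKernel-class] (`contextDensity = NA`).
#' @export
buildTDSVKernel <- function(params, density, center, size = 41,
                            boundary = c("air", "clamp"),
                            airDensity = .airDensity) {
  stopifnot(is(params, "APSFParams"), is(density, "VoxelGrid"))
  boundary <- match.arg(boundary)
  size <- .checkOdd(size)
  d <- dim(density@values)
  center <- as.integer(center)
  stopifnot(all(center >= 1L), all(center <= d))
  vox <- density@voxelSize
  lut <- apsfLut(params)
  w <- cppTdsvKernel(size, vox, lut$B, lut$M, lut$r0,
                     .halfVoxelRadius(vox), as.numeric(density@values),
                     as.integer(d), center - 1L, params@rhoRef,
                     airDensity, boundary == "clamp")
  .normalizeKernel(w, size, vox, NA_real_)
}

# Per-voxel kernel bank backing the TDSV blur operator.  Normalization is
# over the full stencil; only in-volume targets are stored, so activity
# spread beyond the grid is modelled as lost (and the matched OSEM
# operator pair accounts for it through the sensitivity image).  Banks
# are cached per session: simulation truth and reconstruction share one
# build for the same density map.
.bankCache <- new.env(parent = emptyenv())

.kernelBank <- function(params, density, size, boundary = "air",
                        airDensity = .airDensity, sliceIndependent = FALSE,
                        maxBytes = 4e9) {
  key <- .md5Raw(list(v = as.numeric(density@values),
                           vox = density@voxelSize,
                           p = c(params@C, params@a, params@n,
                                 params@epsilon, params@r0, params@rhoRef),
                           size = size, boundary = boundary,
                           air = airDensity, si = sliceIndependent))
  if (!is.null(.bankCache[[key]])) return(.bankCache[[key]])
  bank <- .kernelBankBuild(params, density, size, boundary, airDensity,
                           sliceIndependent, maxBytes)
  if (as.numeric(object.size(bank$w)) < 1.5e9) .bankCache[[key]] <- bank
  bank
}

.kernelBankBuild <- function(params, density, size, boundary,
                             airDensity, sliceIndependent, maxBytes) {
  d <- dim(density@values)
  R <- size %/% 2
  ext <- function(n) sum(pmin(R, seq_len(n) - 1) + pmin(R, n - seq_len(n)) + 1)
  zext <- if (sliceIndependent) d[3] else ext(d[3])
  need <- 8 * ext(d[1]) / d[1] * ext(d[2]) / d[2] * zext / d[3] *
    prod(d)
  if (need > maxBytes)
    stop(sprintf(
      "TDSV kernel bank would need %.1f GB (> %.1f GB); use a smaller grid or kernel",
      need / 1e9, maxBytes / 1e9))
  lut <- apsfLut(params)
  bank <- cppKernelBank(as.numeric(density@values), as.integer(d), size,
                        density@voxelSize, lut$B, lut$M, lut$r0,
                        .halfVoxelRadius(density@voxelSize), params@rhoRef,
                        airDensity, boundary == "clamp", sliceIndependent)
  bank$sliceIndependent <- sliceIndependent
  bank
}

#' Write a kernel as a NIfTI volume
#'
#' @param kernel a [DiscreteKernel-class].
#' @param path output path (`.nii` / `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeKernel <- function(kernel, path) {
  stopifnot(is(kernel, "DiscreteKernel"))
  writeVolume(VoxelGrid(kernel@weights, kernel@voxelSize,
                        kind = "activity"), path)
  invisible(path)
}
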