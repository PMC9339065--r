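# OSEM reconstruction with optional positron range correction.  With PRC
# the system operator is (project o blur) and its adjoint
# (blur-adjoint o backproject): a matched operator pair, so EM
# monotonicity holds with one subset.

#' Segment a density volume into tissue classes
#'
#' CT-surrogate segmentation used by the TD kernels: 1 level maps every
#' voxel to water; 2 levels threshold at 0.5 g/cm^3 into air/water; 3
#' levels use thresholds 0.6 and 1.4 into lung/water/bone (voxels below
#' 0.15 are also assigned lung -- outside-animal air is range-irrelevant
#' once masked by sensitivity).
#'
#' @param density a density [VoxelGrid-class].
#' @param levels 1, 2 or 3 segmentation levels.
#' @return A [TissueSegmentation-class]; the class table carries the
#'   representative density used to build each class kernel.
#' @export
segmentDensity <- function(density, levels = 1) {
  stopifnot(is(density, "VoxelGrid"))
  if (!levels %in% 1:3)
    stop("segmentDensity: levels must be 1, 2 or 3")
  v <- density@values
  if (levels == 1) {
    lab <- array(1L, dim(v))
    classes <- data.frame(label = 1L, name = "water", density = 1.0)
  } else if (levels == 2) {
    lab <- array(1L + (v >= 0.5), dim(v))
    classes <- data.frame(label = 1:2, name = c("air", "water"),
                          density = c(.airDensity, 1.0))
  } else {
    lab <- array(1L + (v >= 0.6) + (v > 1.4), dim(v))
    classes <- data.frame(label = 1:3, name = c("lung", "water", "bone"),
                          density = c(0.3, 1.0, 1.9))
  }
  classes <- classes[classes$label %in% unique(as.vector(lab)), ,
                     drop = FALSE]
  new("TissueSegmentation", labels = lab, classes = classes)
}

# Build the positron-range blur operator for a reconstruction: a list
# with forward/adjoint closures over precomputed kernels (TD) or the
# per-voxel kernel bank (TDSV).
.makeBlurOperator <- function(mode, params = NULL, seg = NULL,
                              density = NULL, kernelSize = 41,
                              voxelSize = NULL, boundary = "air",
                              sliceIndependent = FALSE) {
  if (mode == "none")
    return(list(mode = "none", forward = identity, adjoint = identity))
  stopifnot(!is.null(params))
  if (mode == "td") {
    stopifnot(!is.null(seg))
    classes <- seg@classes
    kernels <- lapply(classes$density, function(rho)
      buildUniformKernel(params, rho, kernelSize, voxelSize))
    masks <- lapply(classes$label, function(l) seg@labels == l)
    fwd <- function(img) {
      out <- array(0, dim(img))
      for (i in seq_along(kernels))
        out <- out + .applyKernel(img * masks[[i]], kernels[[i]],
                                  zOnly = sliceIndependent)
      out
    }
    adj <- function(img) {
      out <- array(0, dim(img))
      for (i in seq_along(kernels))
        out <- out + masks[[i]] * .applyKernel(img, kernels[[i]],
                                               adjoint = TRUE,
                                               zOnly = sliceIndependent)
      out
    }
    return(list(mode = "td", forward = fwd, adjoint = adj,
                kernels = kernels))
  }
  stopifnot(!is.null(density))
  bank <- .kernelBank(params, density, kernelSize, boundary,
                      sliceIndependent = sliceIndependent)
  d <- dim(density@values)
  list(mode = "tdsv",
       forward = function(img)
         array(cppTdsvApply(as.numeric(img), as.integer(d), bank$w,
                            bank$size, FALSE, sliceIndependent), dim = d),
       adjoint = function(img)
         array(cppTdsvApply(as.numeric(img), as.integer(d), bank$w,
                            bank$size, TRUE, sliceIndependent), dim = d))
}

#' Apply the positron-range blur of a reconstruction mode
#'
#' TD: each segmented class is masked, convolved with that class's
#' uniform kernel, and the results summed.  TDSV: every voxel's value is
#' spread with its own ray-mean-density kernel.  Both conserve total
#' activity for sources whose kernel lies fully inside the grid.
#'
#' @param image activity [VoxelGrid-class].
#' @param mode `"none"`, `"td"` or `"tdsv"`.
#' @param params [APSFParams-class].
#' @param seg [TissueSegmentation-class] (TD mode).
#' @param density density [VoxelGrid-class] (TDSV mode).
#' @param kernelSize odd stencil size.
#' @param boundary out-of-grid density rule.
#' @param sliceIndependent restrict the blur to each axial slice
#'   (quasi-2D slab volumes; axial spread is escape).
#' @param adjoint apply the transpose operator instead.
#' @return A [VoxelGrid-class].
#' @export
prcBlur <- function(image, mode = c("td", "tdsv", "none"), params = NULL,
                    seg = NULL, density = NULL, kernelSize = 41,
                    boundary = "air", sliceIndependent = FALSE,
                    adjoint = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is(image, "VoxelGrid"))
  if (!is.null(seg) && !all(dim(seg@labels) == dim(image)))
    stop("prcBlur: image and segmentation grids do not match")
  if (!is.null(density) && !all(dim(density) == dim(image)))
    stop("prcBlur: image and density grids do not match")
  op <- .makeBlurOperator(mode, params, seg, density, kernelSize,
                          image@voxelSize, boundary, sliceIndependent)
  f <- if (adjoint) op$adjoint else op$forward
  VoxelGrid(f(image@values), image@voxelSize, image@origin, image@kind)
}

#' OSEM reconstruction with optional positron range correction
#'
#' Standard multiplicative OSEM update on interleaved angle subsets
#' (processed in bit-reversed order).  With PRC enabled the blur operator
#' is composed with the projector in both directions, and the subset
#' sensitivity images include the blur adjoint.  Attenuation factors, if
#' given, enter the forward model multiplicatively.  Iteration count is
#' the stopping rule; convergence is never tested.
#'
#' @param proj [ProjectionData-class] of counts.
#' @param grid [VoxelGrid-class] template for the reconstruction.
#' @param config [ReconConfig-class].
#' @param params [APSFParams-class] (PRC modes).
#' @param density density [VoxelGrid-class]; required for TDSV and used
#'   to derive the TD segmentation when `seg` is missing.
#' @param seg optional [TissueSegmentation-class] for TD mode.
#' @param atten optional attenuation factor array (sinogram dims).
#' @param snapshots iteration indices at which to keep volumes (default:
#'   every iteration).
#' @param logLik compute the Poisson log-likelihood after each full
#'   iteration (one extra forward projection per iteration)?
#' @return An [OsemResult-class].
#' @export
osem <- function(proj, grid, config, params = NULL, density = NULL,
                 seg = NULL, atten = NULL, snapshots = NULL,
                 logLik = FALSE) {
  stopifnot(is(proj, "ProjectionData"), is(grid, "VoxelGrid"),
            is(config, "ReconConfig"))
  geom <- proj@geometry
  .checkGridGeom(grid, geom)
  dims <- dim(grid)
  vox <- grid@voxelSize
  nAngles <- length(geom@angles)
  subsets <- .makeSubsets(nAngles, config@subsets)
  order <- .bitReverse(length(subsets))

  if (config@prcMode == "td" && is.null(seg)) {
    stopifnot(!is.null(density))
    seg <- segmentDensity(density, config@tdLevels)
  }
  op <- .makeBlurOperator(config@prcMode, params, seg, density,
                          config@kernelSize, vox, config@boundary,
                          config@sliceIndependent)

  y <- proj@values
  if (is.null(atten)) atten <- array(1, dim(y))
  stopifnot(all(dim(atten) == dim(y)))

  # per-subset sensitivity: blur-adjoint(backproject(attenuation))
  sens <- lapply(subsets, function(s) {
    bp <- .bproj(atten[, s, , drop = FALSE], dims, vox, geom, s)
    op$adjoint(bp)
  })
  masked <- Reduce(`+`, sens) <= 0
  if (any(masked))
    warning(sprintf("osem: %d voxels with zero sensitivity masked out",
                    sum(masked)))

  if (is.null(snapshots)) snapshots <- seq_len(config@iterations)
  snapshots <- sort(unique(as.integer(snapshots)))
  stopifnot(all(snapshots >= 1), all(snapshots <= config@iterations))

  x <- array(1, dims)
  x[masked] <- 0
  eps <- 1e-12
  volumes <- list()
  ll <- if (logLik) numeric(config@iterations) else numeric(0)

  for (it in seq_len(config@iterations)) {
    for (s in order) {
      idx <- subsets[[s]]
      fp <- atten[, idx, , drop = FALSE] *
        .fproj(op$forward(x), vox, geom, idx)
      ratio <- y[, idx, , drop = FALSE] / pmax(fp, eps)
      bp <- .bproj(atten[, idx, , drop = FALSE] * ratio, dims, vox, geom,
                   idx)
      upd <- op$adjoint(bp)
      pos <- sens[[s]] > 0
      x[pos] <- x[pos] * upd[pos] / sens[[s]][pos]
    }
    if (logLik) {
      lam <- atten * .fproj(op$forward(x), vox, geom)
      ll[it] <- sum(y[lam > 0] * log(lam[lam > 0])) - sum(lam)
    }
    if (it %in% snapshots)
      volumes[[sprintf("iter%03d", it)]] <-
        VoxelGrid(x, vox, grid@origin, "activity")
  }
  new("OsemResult", volumes = volumes, iterations = snapshots,
      logLik = ll, config = config)
}
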