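#' @name accessors
#' @title Accessors for prcpet classes
#' @param x an object.
#' @param object an object (for `show`).
#' @description Slot accessors; user code should prefer these over `@`.
NULL

#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("gridKind", function(x) standardGeneric("gridKind"))
#' @rdname accessors
#' @export
setGeneric("kernelWeights", function(x) standardGeneric("kernelWeights"))
#' @rdname accessors
#' @export
setGeneric("kernelSize", function(x) standardGeneric("kernelSize"))
#' @rdname accessors
#' @export
setGeneric("projValues", function(x) standardGeneric("projValues"))
#' @rdname accessors
#' @export
setGeneric("projGeometry", function(x) standardGeneric("projGeometry"))
#' @rdname accessors
#' @export
setGeneric("projSubsets", function(x) standardGeneric("projSubsets"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("totalDuration", function(x) standardGeneric("totalDuration"))
#' @rdname accessors
#' @export
setGeneric("reconVolumes", function(x) standardGeneric("reconVolumes"))

#' @rdname accessors
#' @export
setMethod("gridValues", "VoxelGrid", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("voxelSize", "VoxelGrid", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("gridOrigin", "VoxelGrid", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("gridKind", "VoxelGrid", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("dim", "VoxelGrid", function(x) dim(x@values))

#' @rdname accessors
#' @export
setMethod("kernelWeights", "DiscreteKernel", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("kernelSize", "DiscreteKernel", function(x) x@size)

#' @rdname accessors
#' @export
setMethod("projValues", "ProjectionData", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("projGeometry", "ProjectionData", function(x) x@geometry)
#' @rdname accessors
#' @export
setMethod("projSubsets", "ProjectionData", function(x) x@subsets)

#' @rdname accessors
#' @export
setMethod("nFrames", "FrameSchedule", function(x) sum(x@counts))
#' @rdname accessors
#' @export
setMethod("totalDuration", "FrameSchedule",
          function(x) sum(x@counts * x@durations))

#' @rdname accessors
#' @export
setMethod("reconVolumes", "OsemResult", function(x) x@volumes)

#' @rdname accessors
#' @export
setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelGrid [%s]: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              object@kind, d[1], d[2], d[3], object@voxelSize[1],
              object@voxelSize[2], object@voxelSize[3]))
  cat(sprintf("  origin (mm): %.2f %.2f %.2f; range: [%.4g, %.4g]\n",
              object@origin[1], object@origin[2], object@origin[3],
              min(object@values), max(object@values)))
})

#' @rdname accessors
#' @export
setMethod("show", "APSFParams", function(object) {
  cat(sprintf(
    "APSFParams: C=%.4g a=%.4g n=%.4g epsilon=%.4g r0=%.4g mm (rhoRef=%g)\n",
    object@C, object@a, object@n, object@epsilon, object@r0, object@rhoRef))
})

#' @rdname accessors
#' @export
setMethod("show", "DiscreteKernel", function(object) {
  ctx <- if (is.na(object@contextDensity)) "spatially variant"
         else sprintf("density %.4g g/cm^3", object@contextDensity)
  cat(sprintf("DiscreteKernel: %d^3 stencil, %s, sum %.6f\n",
              object@size, ctx, sum(object@weights)))
})

#' @rdname accessors
#' @export
setMethod("show", "ProjectionData", function(object) {
  g <- object@geometry
  cat(sprintf(
    "ProjectionData: %d radial x %d angles x %d slices (%d subsets), total %.4g\n",
    g@nRadial, length(g@angles), g@nSlices, length(object@subsets),
    sum(object@values)))
})

#' @rdname accessors
#' @export
setMethod("show", "OsemResult", function(object) {
  cat(sprintf("OsemResult: %d snapshot(s) at iteration(s) %s; prcMode=%s\n",
              length(object@volumes),
              paste(range(object@iterations), collapse = "-"),
              object@config@prcMode))
})

#' @rdname accessors
#' @export
setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, %g s total (+%g s discarded)\n",
              sum(object@counts), sum(object@counts * object@durations),
              object@discard))
})
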