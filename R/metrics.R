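# NEMA NU-4 style evaluation metrics, line profiles and the Butterworth
# post-filter.  Standard deviations are population SDs (divide by N),
# the NEMA convention.

.popSD <- function(x) sqrt(mean((x - mean(x))^2))

.roiMask <- function(vol, roi) {
  m <- if (is(roi, "VoxelGrid")) roi@values else roi
  if (is.logical(m)) {
    stopifnot(all(dim(m) == dim(vol)))
    m
  } else stop("roi must be a logical array or label VoxelGrid")
}

#' Percent standard deviation in a uniform region
#'
#' NEMA NU-4 noise metric: population SD divided by the mean over the
#' ROI.  Invariant to global intensity scaling.
#'
#' @param vol a [VoxelGrid-class].
#' @param roi logical array marking the uniform ROI.
#' @return %SD as a fraction (0.1 = 10%).
#' @export
percentSD <- function(vol, roi) {
  stopifnot(is(vol, "VoxelGrid"))
  x <- vol@values[.roiMask(vol, roi)]
  if (!length(x)) stop("percentSD: empty ROI")
  m <- mean(x)
  if (m == 0) stop("percentSD: zero mean in ROI")
  .popSD(x) / m
}

#' Spillover ratio into a cold region
#'
#' `mean(cold) / mean(uniform)`, with the NEMA-style SD taken as the
#' population SD of the cold ROI divided by the uniform mean.
#'
#' @param vol a [VoxelGrid-class].
#' @param coldRoi,uniformRoi logical ROI arrays.
#' @return list with `ratio` and `sd`.
#' @export
spilloverRatio <- function(vol, coldRoi, uniformRoi) {
  stopifnot(is(vol, "VoxelGrid"))
  cold <- vol@values[.roiMask(vol, coldRoi)]
  unif <- vol@values[.roiMask(vol, uniformRoi)]
  if (!length(cold) || !length(unif)) stop("spilloverRatio: empty ROI")
  mu <- mean(unif)
  if (mu == 0) stop("spilloverRatio: zero uniform mean")
  list(ratio = mean(cold) / mu, sd = .popSD(cold) / mu)
}

#' Recovery coefficients for the NEMA rods
#'
#' NEMA NU-4 procedure: for each rod, the maximum value in each
#' transaxial slice of the rod ROI is averaged over slices and divided by
#' the uniform-region mean.  The SD combines the relative variability of
#' the per-slice maxima with the uniform-region %SD in quadrature.
#'
#' @param vol a [VoxelGrid-class].
#' @param rodLabels label array (or label [VoxelGrid-class]) with one
#'   label per rod ROI.
#' @param rodTable data.frame with columns `label` and `diameter` (mm).
#' @param uniformRoi logical array for the uniform region.
#' @return data.frame with `diameter`, `rc` and `sd`, ordered by
#'   diameter.
#' @export
recoveryCoefficients <- function(vol, rodLabels, rodTable, uniformRoi) {
  stopifnot(is(vol, "VoxelGrid"))
  lab <- if (is(rodLabels, "VoxelGrid")) rodLabels@values else rodLabels
  stopifnot(all(dim(lab) == dim(vol)))
  unif <- vol@values[.roiMask(vol, uniformRoi)]
  mu <- mean(unif)
  if (mu == 0) stop("recoveryCoefficients: zero uniform mean")
  pctU <- .popSD(unif) / mu
  res <- lapply(seq_len(nrow(rodTable)), function(i) {
    l <- rodTable$label[i]
    inRod <- lab == l
    if (!any(inRod)) stop(sprintf(
      "recoveryCoefficients: rod label %d not present in the volume", l))
    slices <- which(apply(inRod, 3, any))
    maxs <- vapply(slices, function(z) {
      m <- inRod[, , z]
      max(vol@values[, , z][m])
    }, numeric(1))
    rc <- mean(maxs) / mu
    relMax <- if (length(maxs) > 1 && mean(maxs) > 0)
      .popSD(maxs) / mean(maxs) else 0
    data.frame(diameter = rodTable$diameter[i], rc = rc,
               sd = rc * sqrt(relMax^2 + pctU^2))
  })
  out <- do.call(rbind, res)
  out[order(out$diameter), , drop = FALSE]
}

#' Sample a line profile through a volume
#'
#' Trilinear interpolation at uniform steps along the segment from
#' `start` to `end` (world mm).  Errors if any sample falls outside the
#' voxel-centre hull of the grid.
#'
#' @param vol a [VoxelGrid-class].
#' @param start,end world coordinates, mm (length 3).
#' @param step sampling step, mm.
#' @return A [LineProfile-class]; positions are mm from `start`.
#' @export
lineProfile <- function(vol, start, end, step = 0.1) {
  stopifnot(is(vol, "VoxelGrid"), length(start) == 3, length(end) == 3,
            step > 0)
  len <- sqrt(sum((end - start)^2))
  stopifnot(len > 0)
  pos <- seq(0, len, by = step)
  u <- (end - start) / len
  d <- dim(vol)
  v <- vol@values
  # continuous (1-based) voxel coordinates of the sample points
  ci <- vapply(1:3, function(ax)
    (start[ax] + pos * u[ax] - vol@origin[ax]) / vol@voxelSize[ax] + 1,
    numeric(length(pos)))
  if (length(pos) == 1L) ci <- matrix(ci, nrow = 1)
  tol <- 1e-9
  for (ax in 1:3) {
    if (d[ax] == 1L) {
      if (any(abs(ci[, ax] - 1) > 0.5 + tol))
        stop("lineProfile: segment leaves the volume")
      ci[, ax] <- 1
    } else if (any(ci[, ax] < 1 - tol) || any(ci[, ax] > d[ax] + tol)) {
      stop("lineProfile: segment leaves the volume")
    }
  }
  ci <- pmin(pmax(ci, 1), matrix(rep(d, each = nrow(ci)), nrow = nrow(ci)))
  i0 <- pmin(floor(ci), matrix(rep(d - 1L, each = nrow(ci)),
                               nrow = nrow(ci)))
  i0 <- pmax(i0, 1)
  f <- ci - i0
  val <- numeric(length(pos))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    idx <- cbind(pmin(i0[, 1] + dx, d[1]), pmin(i0[, 2] + dy, d[2]),
                 pmin(i0[, 3] + dz, d[3]))
    val <- val + w * v[idx]
  }
  new("LineProfile", positions = pos, values = val)
}

#' FWHM and FWTM of a profile peak
#'
#' Widths at half and tenth maximum via linear interpolation of the
#' threshold crossings around the designated peak.  By default the
#' thresholds are fractions of the absolute peak value (the convention
#' behind wall-thickness tables, where unresolved spillover widens the
#' measured wall); with `pedestal = "flank"` the larger of the two local
#' minima flanking the peak is subtracted first, isolating the peak from
#' its baseline.
#'
#' @param profile a [LineProfile-class].
#' @param peakRegion optional `c(min, max)` positions (mm) restricting
#'   the peak search.
#' @param pedestal `"none"` (default) or `"flank"`.
#' @return Named numeric `c(fwhm = , fwtm = )` in mm.
#' @export
fwhmFwtm <- function(profile, peakRegion = NULL,
                     pedestal = c("none", "flank")) {
  stopifnot(is(profile, "LineProfile"))
  pedestal <- match.arg(pedestal)
  x <- profile@positions
  y <- profile@values
  sel <- if (is.null(peakRegion)) rep(TRUE, length(x))
         else x >= peakRegion[1] & x <= peakRegion[2]
  if (!any(sel)) stop("fwhmFwtm: empty peak region")
  pk <- which(sel)[which.max(y[sel])]
  if (pk == 1L || pk == length(x))
    stop("fwhmFwtm: peak lies on the profile boundary")
  base <- 0
  if (pedestal == "flank") {
    leftMin <- min(y[1:pk])
    rightMin <- min(y[pk:length(y)])
    base <- max(leftMin, rightMin)
  }
  height <- y[pk] - base
  if (height <= 0) stop("fwhmFwtm: no peak above the pedestal")
  width <- function(frac) {
    thr <- base + frac * height
    iL <- pk
    while (iL > 1 && y[iL] > thr) iL <- iL - 1
    if (y[iL] > thr) stop("fwhmFwtm: profile never crosses the threshold")
    xL <- x[iL] + (thr - y[iL]) / (y[iL + 1] - y[iL]) * (x[iL + 1] - x[iL])
    iR <- pk
    while (iR < length(y) && y[iR] > thr) iR <- iR + 1
    if (y[iR] > thr) stop("fwhmFwtm: profile never crosses the threshold")
    xR <- x[iR] - (thr - y[iR]) / (y[iR - 1] - y[iR]) * (x[iR] - x[iR - 1])
    xR - xL
  }
  c(fwhm = width(0.5), fwtm = width(0.1))
}

#' Isotropic 3D Butterworth post-filter
#'
#' Zero-phase frequency-domain filter with magnitude
#' `1 / sqrt(1 + (f/fc)^(2*order))` on the 3D radial frequency, each axis
#' normalized so its Nyquist frequency is 1.  Order 10 and cutoff 0.2
#' reproduce the clinical post-filter setting.
#'
#' @param vol a [VoxelGrid-class].
#' @param order filter order.
#' @param cutoff cutoff as a fraction of Nyquist, in `(0, 1]`.
#' @return A filtered [VoxelGrid-class].
#' @export
butterworth3d <- function(vol, order = 10, cutoff = 0.2) {
  stopifnot(is(vol, "VoxelGrid"))
  if (cutoff <= 0 || cutoff > 1)
    stop("butterworth3d: cutoff must lie in (0, 1]")
  d <- dim(vol)
  fax <- lapply(d, function(n) {
    f <- (seq_len(n) - 1) / n
    f[f > 0.5] <- f[f > 0.5] - 1
    f / 0.5
  })
  fr2 <- outer(outer(fax[[1]]^2, fax[[2]]^2, "+"), fax[[3]]^2, "+")
  H <- 1 / sqrt(1 + (sqrt(fr2) / cutoff)^(2 * order))
  out <- Re(fft(fft(vol@values) * H, inverse = TRUE)) / prod(d)
  # filtered PET volumes are conventionally clipped at zero (ringing can
  # produce small negative excursions)
  VoxelGrid(pmax(out, 0), vol@voxelSize, vol@origin, vol@kind)
}

#' NEMA metric sweep over reconstruction snapshots
#'
#' One report row per snapshot: %SD, spillover ratios (air and water,
#' with SDs) and the five rod recovery coefficients (with SDs), enabling
#' metric-versus-iteration curves.
#'
#' @param fit an [OsemResult-class] (or list of [VoxelGrid-class]
#'   snapshots with an `iterations` attribute).
#' @param rois the `rois` element returned by [genNemaNu4()] (possibly
#'   cropped to the reconstruction grid).
#' @return data.frame with one row per snapshot.
#' @export
nemaSweep <- function(fit, rois) {
  if (is(fit, "OsemResult")) {
    vols <- fit@volumes
    iters <- fit@iterations
  } else {
    vols <- fit
    iters <- attr(fit, "iterations")
    if (is.null(iters)) iters <- seq_along(vols)
  }
  lab <- rois$labels@values
  present <- unique(as.vector(lab))
  rodTable <- rois$table[!is.na(rois$table$diameter) &
                           rois$table$label %in% present, , drop = FALSE]
  rows <- lapply(seq_along(vols), function(i) {
    v <- vols[[i]]
    unif <- lab == 1L
    out <- data.frame(iteration = iters[i],
                      pct_sd = percentSD(v, unif))
    for (spec in list(c("sor_water", 2L), c("sor_air", 3L))) {
      l <- as.integer(spec[2])
      s <- if (l %in% present) spilloverRatio(v, lab == l, unif)
           else list(ratio = NA_real_, sd = NA_real_)
      out[[spec[1]]] <- s$ratio
      out[[paste0(spec[1], "_sd")]] <- s$sd
    }
    if (nrow(rodTable)) {
      rc <- recoveryCoefficients(v, lab, rodTable, unif)
      for (j in seq_len(nrow(rc))) {
        out[[sprintf("rc_%dmm", rc$diameter[j])]] <- rc$rc[j]
        out[[sprintf("rc_%dmm_sd", rc$diameter[j])]] <- rc$sd[j]
      }
    }
    out
  })
  do.call(rbind, rows)
}
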