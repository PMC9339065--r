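# Digital phantoms.  All phantoms are rasterized deterministically with
# the centre-of-voxel rule: a voxel belongs to a primitive iff its centre
# lies inside.  Grids are centred on the phantom centre (plus an optional
# offset), so a thin axial field of view cuts a slab through any region.

.phantomGrid <- function(voxelSize, fov, center = c(0, 0, 0)) {
  vox <- .asVox3(voxelSize)
  dims <- pmax(round(fov / vox), 1)
  origin <- center - (dims - 1) / 2 * vox
  x <- origin[1] + (seq_len(dims[1]) - 1) * vox[1]
  y <- origin[2] + (seq_len(dims[2]) - 1) * vox[2]
  z <- origin[3] + (seq_len(dims[3]) - 1) * vox[3]
  list(vox = vox, dims = dims, origin = origin, x = x, y = y, z = z,
       X = array(rep(x, times = dims[2] * dims[3]), dims),
       Y = array(rep(rep(y, each = dims[1]), times = dims[3]), dims),
       Z = array(rep(z, each = dims[1] * dims[2]), dims))
}

.cylinderMask <- function(g, cx, cy, radius, z0, z1) {
  (g$X - cx)^2 + (g$Y - cy)^2 <= radius^2 & g$Z >= z0 & g$Z <= z1
}

#' NEMA NU-4 style image-quality phantom
#'
#' A 30 mm diameter, 50 mm long water cylinder in three axial regions:
#' a rod region (five fillable rods of diameter 1-5 mm on a 7 mm radius,
#' 20 mm long, in a cold background), a uniformly filled region (15 mm),
#' and a cold-chamber region (15 mm) with one water-filled and one
#' air-filled 8 mm chamber.  Dimensions follow the NU-4 image-quality
#' standard; activity is 1 (relative) in all filled volumes.
#'
#' The returned ROI label volume defines the analysis regions: 1 =
#' uniform ROI (22.5 mm diameter x 10 mm), 2 = cold water ROI, 3 = cold
#' air ROI (4 mm diameter x 10 mm each), `10 + d` = rod ROI of diameter
#' `2*d` mm around the rod of diameter `d`, over the central 10 mm of the
#' rod region.
#'
#' @param voxelSize voxel edge length(s), mm; in-plane size must be
#'   <= 0.8 mm so the 1 mm rod is resolvable.
#' @param fov field of view, mm (length 3); defaults to the full phantom.
#' @param center grid centre in phantom coordinates, mm (phantom centre
#'   is `c(0, 0, 0)`; rods at z < -5, uniform region -5..10, cold
#'   chambers z > 10).
#' @return list with `activity`, `density` ([VoxelGrid-class]), `rois`
#'   (label [VoxelGrid-class] plus a `table` data.frame).
#' @export
genNemaNu4 <- function(voxelSize, fov = c(38, 38, 54), center = c(0, 0, 0)) {
  vox <- .asVox3(voxelSize)
  if (any(vox[1:2] > 0.8))
    stop("genNemaNu4: in-plane voxel size must be <= 0.8 mm")
  g <- .phantomGrid(vox, fov, center)
  act <- array(0, g$dims)
  den <- array(.airDensity, g$dims)
  lab <- array(0L, g$dims)

  body <- .cylinderMask(g, 0, 0, 15, -25, 25)
  den[body] <- 1.0
  uniformZone <- body & g$Z >= -5 & g$Z < 10
  coldZone <- body & g$Z >= 10
  act[uniformZone] <- 1
  act[coldZone] <- 1

  # cold chambers: one water, one air (8 mm diameter, 15 mm long)
  chamberW <- .cylinderMask(g, -7.5, 0, 4, 10, 25)
  chamberA <- .cylinderMask(g, 7.5, 0, 4, 10, 25)
  act[chamberW] <- 0
  act[chamberA] <- 0
  den[chamberA] <- .airDensity

  # rods (hot, water) in the cold rod region
  rodD <- 1:5
  rodAng <- pi / 2 + (rodD - 1) * 2 * pi / 5
  for (i in seq_along(rodD)) {
    m <- .cylinderMask(g, 7 * cos(rodAng[i]), 7 * sin(rodAng[i]),
                       rodD[i] / 2, -25, -5)
    act[m] <- 1
    den[m] <- 1.0
  }

  lab[.cylinderMask(g, 0, 0, 11.25, -2.5, 7.5)] <- 1L
  lab[.cylinderMask(g, -7.5, 0, 2, 12.5, 22.5)] <- 2L
  lab[.cylinderMask(g, 7.5, 0, 2, 12.5, 22.5)] <- 3L
  for (i in seq_along(rodD)) {
    m <- .cylinderMask(g, 7 * cos(rodAng[i]), 7 * sin(rodAng[i]),
                       rodD[i], -20, -10)
    lab[m] <- 10L + rodD[i]
  }

  roiTable <- data.frame(
    label = c(1L, 2L, 3L, 10L + rodD),
    region = c("uniform", "cold_water", "cold_air",
               paste0("rod_", rodD, "mm")),
    diameter = c(NA, NA, NA, rodD))
  list(activity = VoxelGrid(act, vox, g$origin, "activity"),
       density = VoxelGrid(den, vox, g$origin, "density"),
       rois = list(labels = VoxelGrid(lab, vox, g$origin, "label"),
                   table = roiTable))
}

#' Two-compartment cardiac phantom
#'
#' A left-ventricle analogue (6 mm lumen, 3 mm hot wall) with a
#' right-ventricle analogue (3 mm crescent lumen, 2 mm hot wall wrapped
#' around the +x side), extruded over a 15 mm chamber length and inserted
#' into a 50 mm cylinder of density 0.4 g/cm^3 (lung-like printed
#' material).  Walls are hot (activity 1, water density); lumina are cold
#' water.  Landmarks give the four-chamber profile line (through both
#' ventricles, along x) and the two-chamber line (through the left
#' ventricle only, along y), both at mid-chamber.
#'
#' @param voxelSize voxel edge length(s), mm; in-plane <= 0.5 mm.
#' @param fov field of view, mm; defaults to the full cylinder.
#' @param center grid centre, mm (chamber axis at x = y = 0, mid-chamber
#'   z = 0).
#' @return list with `activity`, `density`, and `landmarks` (named list
#'   of `start`/`end` mm coordinates).
#' @export
genCardiac <- function(voxelSize, fov = c(54, 54, 30), center = c(0, 0, 0)) {
  vox <- .asVox3(voxelSize)
  if (any(vox[1:2] > 0.5))
    stop("genCardiac: in-plane voxel size must be <= 0.5 mm")
  g <- .phantomGrid(vox, fov, center)
  act <- array(0, g$dims)
  den <- array(.airDensity, g$dims)

  den[.cylinderMask(g, 0, 0, 25, -15, 15)] <- 0.4

  inChamber <- abs(g$Z) <= 7.5
  r2 <- g$X^2 + g$Y^2
  theta <- atan2(g$Y, g$X)
  lvLumen <- inChamber & r2 <= 3^2
  lvWall <- inChamber & r2 > 3^2 & r2 <= 6^2
  sector <- abs(theta) <= pi / 3
  rvLumen <- inChamber & sector & r2 > 6^2 & r2 <= 9^2
  rvWall <- inChamber & sector & r2 > 9^2 & r2 <= 11^2

  den[lvLumen | lvWall | rvLumen | rvWall] <- 1.0
  act[lvWall | rvWall] <- 1

  landmarks <- list(
    fourChamber = list(start = c(-14, 0, 0), end = c(14, 0, 0)),
    twoChamber = list(start = c(0, -14, 0), end = c(0, 14, 0)))
  list(activity = VoxelGrid(act, vox, g$origin, "activity"),
       density = VoxelGrid(den, vox, g$origin, "density"),
       landmarks = landmarks)
}

#' Breathing rat-thorax phantom
#'
#' An in vivo surrogate: an ellipsoidal-shell myocardium (hot) with a
#' cold blood pool, lung fields (density 0.3), a spine (density 1.9) and
#' soft tissue (density 1.0), surrounded by air.  The whole heart is
#' translated axially by `2 * sin(2*pi*phase)` mm (rigid respiratory
#' motion, 2 mm amplitude).  With `infarct = TRUE` the activity in an
#' anteroapical wedge (90 degrees azimuth around +y, apical half) of the
#' shell is zeroed; by symmetry the wedge holds exactly 1/8 of the shell
#' volume.
#'
#' @param voxelSize voxel edge length(s), mm.
#' @param phase respiratory phase in `[0, 1)`.
#' @param infarct zero the anteroapical wedge?
#' @param fov field of view, mm.
#' @param center grid centre, mm (heart centred at the origin at phase
#'   0).
#' @return list with `activity` and `density` [VoxelGrid-class]s.
#' @export
genRatThorax <- function(voxelSize, phase = 0, infarct = FALSE,
                         fov = c(48, 48, 40), center = c(0, 0, 0)) {
  if (phase < 0 || phase >= 1)
    stop("genRatThorax: phase must lie in [0, 1)")
  vox <- .asVox3(voxelSize)
  g <- .phantomGrid(vox, fov, center)
  act <- array(0, g$dims)
  den <- array(.airDensity, g$dims)

  body <- (g$X / 22)^2 + (g$Y / 18)^2 <= 1
  den[body] <- 1.0
  act[body] <- 0.05

  for (sx in c(-1, 1)) {
    lung <- ((g$X - sx * 11) / 7)^2 + ((g$Y - 2) / 9)^2 +
      (g$Z / 14)^2 <= 1
    den[lung] <- 0.3
    act[lung] <- 0.02
  }
  spine <- (g$X)^2 + (g$Y + 14)^2 <= 3^2
  den[spine] <- 1.9
  act[spine] <- 0

  shift <- 2 * sin(2 * pi * phase)
  zh <- g$Z - shift
  outer <- (g$X / 6)^2 + (g$Y / 6)^2 + (zh / 8)^2 <= 1
  inner <- (g$X / 4)^2 + (g$Y / 4)^2 + (zh / 6)^2 <= 1
  shell <- outer & !inner
  den[outer] <- 1.0
  act[shell] <- 1
  act[inner] <- 0

  if (infarct) {
    wedge <- shell & g$Y > 0 & abs(g$X) < g$Y & zh < 0
    act[wedge] <- 0
  }
  list(activity = VoxelGrid(act, vox, g$origin, "activity"),
       density = VoxelGrid(den, vox, g$origin, "density"))
}
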