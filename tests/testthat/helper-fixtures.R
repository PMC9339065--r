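# Shared fixtures.  The expensive simulated studies (quasi-2D slab
# experiments at the evaluation problem sizes) are built once per test
# session and reused across files; everything is generated in code from
# fixed seeds.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# calibrated Rb-82 kernel parameters (package-level cache makes repeat
# calls cheap)
rbFix <- function() rb82Params(1e6, seed = 1)

# cardiac slab study: 0.4 mm in-plane voxels, 15 mm slab (= chamber
# length), 5e6 counts, spatially variant truth blur, detector 1.6 mm,
# reconstructed 40 iterations / 16 subsets without PRC and with TDSV-41
cardiacFix <- function() fixture("cardiac", function() {
  params <- rbFix()
  vox <- c(0.4, 0.4, 15)
  ph <- genCardiac(vox, fov = c(38.4, 38.4, 15))
  geom <- defaultGeometry(ph$activity, nAngles = 128)
  proj <- simulateAcquisition(ph$activity, ph$density, params, geom,
                              totalCounts = 5e6, seed = 7,
                              prcTruthMode = "variant", boundary = "clamp",
                              detectorFwhm = 1.6, sliceIndependent = TRUE)
  atten <- attenuationFactors(ph$density, geom)
  fitN <- osem(proj, ph$activity, reconConfig(40, 16, "none"),
               atten = atten, snapshots = 40)
  fitT <- osem(proj, ph$activity,
               reconConfig(40, 16, "tdsv", kernelSize = 41,
                           boundary = "clamp", sliceIndependent = TRUE),
               params = params, density = ph$density, atten = atten,
               snapshots = 40)
  widths <- function(fit) {
    v <- reconVolumes(fit)[[1]]
    lm <- ph$landmarks$twoChamber
    pr <- lineProfile(v, lm$start, lm$end, 0.05)
    fwhmFwtm(pr, peakRegion = c(16, 22)) # lateral wall
  }
  list(ph = ph, geom = geom, proj = proj, atten = atten,
       fitN = fitN, fitT = fitT,
       widthsN = widths(fitN), widthsT = widths(fitT))
})

# NEMA NU-4 slab study: one 15 mm slab per analysed region (rods,
# uniform, cold chambers) stacked into a 3-slice volume sharing a single
# acquisition; 0.5 mm in-plane voxels, 2e7 counts, reconstructed without
# PRC, TD 2 and TDSV-41 at 40 iterations / 16 subsets
nemaFix <- function() fixture("nema", function() {
  params <- rbFix()
  vox <- c(0.5, 0.5, 15)
  slabs <- lapply(c(-15, 2.5, 17.5), function(zc)
    genNemaNu4(vox, fov = c(38, 38, 15), center = c(0, 0, zc)))
  stack <- function(get) {
    arrs <- lapply(slabs, get)
    a <- array(0, c(dim(arrs[[1]])[1:2], 3))
    for (i in 1:3) a[, , i] <- arrs[[i]][, , 1]
    a
  }
  act <- VoxelGrid(stack(function(s) s$activity@values), vox,
                   kind = "activity")
  den <- VoxelGrid(stack(function(s) s$density@values), vox,
                   kind = "density")
  rois <- list(labels = VoxelGrid(stack(function(s) s$rois$labels@values),
                                  vox, kind = "label"),
               table = slabs[[1]]$rois$table)
  geom <- defaultGeometry(act, nAngles = 128)
  proj <- simulateAcquisition(act, den, params, geom, totalCounts = 2e7,
                              seed = 11, prcTruthMode = "variant",
                              boundary = "clamp", detectorFwhm = 1.6,
                              sliceIndependent = TRUE)
  atten <- attenuationFactors(den, geom)
  recon <- function(cfg)
    suppressWarnings(osem(proj, act, cfg, params = params, density = den,
                          atten = atten, snapshots = c(10, 40)))
  fits <- list(
    none = recon(reconConfig(40, 16, "none")),
    td2 = recon(reconConfig(40, 16, "td", tdLevels = 2, kernelSize = 41,
                            sliceIndependent = TRUE)),
    tdsv41 = recon(reconConfig(40, 16, "tdsv", kernelSize = 41,
                               boundary = "clamp",
                               sliceIndependent = TRUE)))
  sweeps <- lapply(fits, nemaSweep, rois = rois)
  list(act = act, den = den, rois = rois, geom = geom, proj = proj,
       atten = atten, fits = fits, sweeps = sweeps)
})

# respiratory-gated rat-thorax study: 1 mm voxels, 2 mm axial motion,
# 4 phase bins, no PRC in the reconstruction (the gating benefit is a
# motion effect)
gatedFix <- function() fixture("gated", function() {
  gen <- function(phase) genRatThorax(1, phase = phase, fov = c(32, 32, 32))
  template <- gen(0)$activity
  geom <- defaultGeometry(template, nAngles = 48)
  cfg <- reconConfig(24, 16, "none")
  scheme <- simulateGated(gen, 4, geom, counts = 4e6, seed = 3,
                          detectorFwhm = 1.6, attenuate = FALSE)
  gated <- reconstructGated(scheme, template, cfg, attenuate = FALSE)
  tot <- Reduce(`+`, lapply(scheme@projections, projValues))
  projU <- new("ProjectionData", values = tot, geometry = geom,
               subsets = scheme@projections[[1]]@subsets, meta = list())
  ungated <- osem(projU, template, cfg, snapshots = 24)
  list(gen = gen, template = template, geom = geom, cfg = cfg,
       scheme = scheme, gated = gated,
       ungated = reconVolumes(ungated)[[1]])
})

# axial profile through the apical myocardial wall
thoraxZProfile <- function(vol) lineProfile(vol, c(0, 0, -14), c(0, 0, 14), 0.1)
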