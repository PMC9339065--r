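# Segmentation, PRC blur operators and OSEM.

test_that("density segmentation produces the configured class sets", {
  ph <- genNemaNu4(0.6)
  seg2 <- segmentDensity(ph$density, 2)
  expect_identical(sort(unique(as.vector(seg2@labels))), 1:2)
  expect_true(all((seg2@labels == 1L) == (ph$density@values < 0.5)))
  # homogeneous water collapses to a single effective class
  unif <- VoxelGrid(array(1, c(8, 8, 8)), 1, kind = "density")
  for (lv in 1:3)
    expect_identical(unique(as.vector(segmentDensity(unif, lv)@labels)),
                     unique(segmentDensity(unif, lv)@classes$label))
  expect_error(segmentDensity(unif, 4), "levels")
})

test_that("three-level segmentation recovers the thorax tissue masks", {
  ph <- genRatThorax(1)
  seg <- segmentDensity(ph$density, 3)
  den <- ph$density@values
  expect_true(all((seg@labels == 3L) == (den == 1.9)))         # bone
  expect_true(all((seg@labels == 2L) == (den == 1.0)))         # water
  expect_true(all((seg@labels == 1L) == (den < 0.6)))          # lung + air
})

test_that("TD blur of a delta source reproduces the water kernel", {
  params <- rbFix()
  v <- array(0, c(25, 25, 25)); v[13, 13, 13] <- 1
  img <- VoxelGrid(v, 1)
  den <- VoxelGrid(array(1, c(25, 25, 25)), 1, kind = "density")
  out <- prcBlur(img, "td", params, seg = segmentDensity(den, 1),
                 kernelSize = 21)
  k <- kernelWeights(buildUniformKernel(params, 1, 21, 1))
  expect_equal(gridValues(out)[3:23, 3:23, 3:23], k, tolerance = 1e-12)
  # interior source: total activity preserved
  expect_equal(sum(gridValues(out)), 1, tolerance = 1e-9)
})

test_that("TD and TDSV blur agree on a homogeneous volume", {
  params <- rbFix()
  set.seed(5)
  v <- array(runif(15^3), c(15, 15, 15))
  img <- VoxelGrid(v, 1)
  den <- VoxelGrid(array(1, c(15, 15, 15)), 1, kind = "density")
  td <- prcBlur(img, "td", params, seg = segmentDensity(den, 1),
                kernelSize = 11)
  tdsv <- prcBlur(img, "tdsv", params, density = den, kernelSize = 11,
                  boundary = "clamp")
  expect_lt(max(abs(gridValues(td) - gridValues(tdsv))), 1e-7)
})

test_that("blur forward and adjoint are transposes in both modes", {
  params <- rbFix()
  den <- VoxelGrid(array(rep(c(1, 0.3), each = 5 * 10 * 10), c(10, 10, 10)),
                   1, kind = "density")
  set.seed(8)
  x <- array(runif(1000), c(10, 10, 10))
  y <- array(runif(1000), c(10, 10, 10))
  for (mode in c("td", "tdsv")) {
    gx <- VoxelGrid(x, 1)
    gy <- VoxelGrid(y, 1)
    seg <- if (mode == "td") segmentDensity(den, 3) else NULL
    f <- gridValues(prcBlur(gx, mode, params, seg = seg, density = den,
                            kernelSize = 9))
    a <- gridValues(prcBlur(gy, mode, params, seg = seg, density = den,
                            kernelSize = 9, adjoint = TRUE))
    expect_equal(sum(f * y), sum(x * a), tolerance = 1e-10)
  }
})

test_that("one MLEM iteration matches the explicit-matrix oracle", {
  geom <- projectionGeometry(4, 7, 1, 1)
  dims <- c(2L, 2L, 1L)
  # extract the system matrix column by column
  A <- sapply(1:4, function(i) {
    e <- array(0, dims); e[[i]] <- 1
    as.vector(prcpet:::.fproj(e, c(1, 1, 1), geom))
  })
  set.seed(3)
  xTrue <- runif(4, 0.5, 2)
  y <- as.vector(A %*% xTrue)
  x0 <- rep(1, 4)
  fp <- as.vector(A %*% x0)
  ratio <- ifelse(fp > 0, y / fp, 0)
  oracle <- x0 * as.vector(t(A) %*% ratio) /
    as.vector(t(A) %*% rep(1, nrow(A)))
  proj <- new("ProjectionData", values = array(y, c(7, 4, 1)),
              geometry = geom, subsets = list(1:4), meta = list())
  grid <- VoxelGrid(array(1, dims), 1)
  fit <- osem(proj, grid, reconConfig(1, 1, "none"), snapshots = 1)
  got <- as.vector(gridValues(reconVolumes(fit)[[1]]))
  sens <- as.vector(t(A) %*% rep(1, nrow(A)))
  expect_equal(got[sens > 0], oracle[sens > 0], tolerance = 1e-12)
})

test_that("one-subset EM never decreases the Poisson log-likelihood", {
  n <- 24
  xy <- (seq_len(n) - (n + 1) / 2)
  act <- array(1.0 * (outer(xy^2, xy^2, "+") <= 8^2), c(n, n, 1))
  grid <- VoxelGrid(act, 1)
  geom <- defaultGeometry(grid, nAngles = 16)
  proj <- simulateAcquisition(grid, geom = geom, totalCounts = 2e4,
                              seed = 6, detectorFwhm = 0,
                              attenuate = FALSE, subsets = 1)
  fit <- osem(proj, grid, reconConfig(30, 1, "none"), snapshots = 30,
              logLik = TRUE)
  expect_true(all(diff(fit@logLik) > -1e-7 * abs(fit@logLik[-1])))
})

test_that("an all-zero sinogram reconstructs to zero", {
  geom <- projectionGeometry(8, 31, 1, 1)
  proj <- new("ProjectionData", values = array(0, c(31, 8, 1)),
              geometry = geom, subsets = prcpet:::.makeSubsets(8, 4),
              meta = list())
  grid <- VoxelGrid(array(1, c(20, 20, 1)), 1)
  fit <- osem(proj, grid, reconConfig(1, 4, "none"), snapshots = 1)
  expect_true(all(gridValues(reconVolumes(fit)[[1]]) == 0))
})

test_that("matched-model reconstruction recovers the 3 mm wall", {
  # noiseless inverse crime: uniform-water truth blur, TD 1 model
  params <- rbFix()
  ph <- genCardiac(c(0.5, 0.5, 15), fov = c(32, 32, 15))
  geom <- defaultGeometry(ph$activity, nAngles = 64)
  proj <- simulateAcquisition(ph$activity, ph$density, params, geom,
                              totalCounts = 1e7, seed = 1,
                              prcTruthMode = "uniform", detectorFwhm = 0,
                              attenuate = FALSE, poisson = FALSE,
                              sliceIndependent = TRUE)
  fT1 <- osem(proj, ph$activity,
              reconConfig(60, 16, "td", tdLevels = 1, kernelSize = 41,
                          sliceIndependent = TRUE),
              params = params, density = ph$density, snapshots = 60)
  fN <- osem(proj, ph$activity, reconConfig(60, 16, "none"), snapshots = 60)
  w <- function(f) fwhmFwtm(lineProfile(reconVolumes(f)[[1]],
                                        c(0, -14, 0), c(0, 14, 0), 0.05),
                            peakRegion = c(16, 21))["fwhm"]
  fwhmT1 <- w(fT1)
  fwhmN <- w(fN)
  expect_lt(abs(fwhmT1 - 3), 1.3)  # 3 mm + voxel quantization
  expect_gt(fwhmN, fwhmT1 + 1)     # the uncorrected image stays blurred
})

test_that("range correction raises the 3 mm rod recovery", {
  fx <- nemaFix()
  rc <- function(mode) fx$sweeps[[mode]]$rc_3mm[2] # iteration 40
  expect_gt(rc("td2"), rc("none"))
  expect_gt(rc("tdsv41"), rc("none"))
})

test_that("spatially variant correction produces an edge halo", {
  # Gibbs-style overshoot at the hot/cold boundary, absent without PRC
  fx <- nemaFix()
  d <- dim(fx$act)
  cx <- (d[1] + 1) / 2
  r <- sqrt(outer((seq_len(d[1]) - cx)^2, (seq_len(d[2]) - cx)^2, "+")) * 0.5
  edge <- r >= 12 & r <= 15.5
  hot <- r < 8 & fx$act@values[, , 2] > 0 # uniform slab
  overshoot <- function(mode) {
    v <- reconVolumes(fx$fits[[mode]])[[2]]@values[, , 2]
    max(v[edge]) / mean(v[hot])
  }
  expect_gt(overshoot("tdsv41"), overshoot("none"))
  expect_gt(overshoot("tdsv41"), 1.2)
})
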