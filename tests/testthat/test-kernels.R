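# Annihilation profile model, fitting, density scaling and discrete
# kernels.

test_that("apsfRadial evaluates the functional form with clamping", {
  # pure 1/r^2 case: a = 0, n = 0, eps = 0 collapses to C / r^2
  p <- apsfParams(C = 1, a = 0, n = 0, epsilon = 0, r0 = 10)
  expect_equal(apsfRadial(p, 2), 1 / 4)
  # zero beyond the maximum range
  expect_identical(apsfRadial(p, 11), 0)
  # negative bracket clamps to zero (epsilon core)
  pc <- apsfParams(C = 1, a = 0, n = 2, epsilon = 0.5, r0 = 10)
  expect_identical(apsfRadial(pc, 0.1), 0)
  # singularity is a domain error
  expect_error(apsfRadial(p, 0), "domain")
  expect_error(apsfRadial(p, c(1, -2)), "domain")
})

test_that("fitted Rb-82 profile decreases along the tail", {
  params <- rbFix()
  expect_gt(apsfRadial(params, 1), apsfRadial(params, 5))
})

test_that("equivalentDistance scales by relative density", {
  expect_equal(equivalentDistance(2, 0.4), 0.8)
  expect_equal(equivalentDistance(5, 1.0), 5)
  expect_equal(equivalentDistance(0, 0.3), 0)
  expect_error(equivalentDistance(-1, 1), "r must be")
  expect_error(equivalentDistance(1, 0), "densities")
})

test_that("mean range scales exactly as 1/density", {
  params <- rbFix()
  base <- meanRange(params, 1) * 1
  for (rho in c(0.3, 0.4, 1.9))
    expect_equal(meanRange(params, rho) * rho, base, tolerance = 1e-6)
  expect_error(meanRange(params, 0), "domain")
  expect_error(meanRange(params, -1), "domain")
})

test_that("fitAPSF recovers a noise-free self-generated profile", {
  truth <- apsfParams(C = 0.01, a = 0.5, n = 2, epsilon = 0.01, r0 = 15)
  r <- seq(0.1, 14.9, by = 0.1)
  ref <- radialProfile(r, apsfRadial(truth, r))
  fit <- fitAPSF(ref)
  expect_lt(attr(fit, "relRMS"), 1e-3)
  # the fitted profile (normalized) reproduces the reference shape
  m0 <- 4 * pi * r^2 * apsfRadial(truth, r)
  m1 <- 4 * pi * r^2 * apsfRadial(fit, r)
  scale <- sum(m0 * m1) / sum(m1^2)
  expect_lt(sqrt(mean((m0 - scale * m1)^2)) / sqrt(mean(m0^2)), 1e-3)
})

test_that("fitAPSF rejects degenerate references", {
  r <- seq(0.5, 10, by = 0.5)
  expect_error(fitAPSF(radialProfile(r, rep(0, length(r)))), "degenerate")
  expect_error(fitAPSF(radialProfile(c(1, 2, 3), c(1, 1, 1))),
               "at least 10 points")
})

test_that("beta-transport reference profile is reproducible and anchored", {
  p1 <- rbAnnihilationProfile(5e4, seed = 4)
  p2 <- rbAnnihilationProfile(5e4, seed = 4)
  expect_identical(p1@values, p2@values)
  # sample mean displacement sits at the calibration anchor scale
  expect_gt(attr(p1, "meanRange3d"), 6)
  expect_lt(attr(p1, "meanRange3d"), 8.5)
})

test_that("uniform kernels are normalized and narrow with density", {
  params <- rbFix()
  ks <- lapply(c(lung = 0.4, water = 1.0, bone = 1.9), function(rho)
    buildUniformKernel(params, rho, 41, 0.8))
  for (k in ks) {
    expect_identical(dim(kernelWeights(k)), rep(41L, 3))
    expect_equal(sum(kernelWeights(k)), 1, tolerance = 1e-9)
    expect_true(all(kernelWeights(k) >= 0))
  }
  # spatial extent orders inversely with density: bone < water < lung
  rmsRadius <- function(k) {
    w <- kernelWeights(k)
    off <- ((1:41) - 21) * 0.8
    r2 <- outer(outer(off^2, off^2, "+"), off^2, "+")
    sqrt(sum(w * r2))
  }
  expect_lt(rmsRadius(ks$bone), rmsRadius(ks$water))
  expect_lt(rmsRadius(ks$water), rmsRadius(ks$lung))
})

test_that("a range shorter than the half voxel gives a delta kernel", {
  p <- apsfParams(C = 1, a = 0, n = 1, epsilon = 0, r0 = 0.3)
  k <- buildUniformKernel(p, 1.0, 5, 0.8)
  w <- kernelWeights(k)
  expect_equal(w[3, 3, 3], 1)
  expect_equal(sum(w) - w[3, 3, 3], 0)
})

test_that("even kernel sizes are rejected", {
  params <- rbFix()
  expect_error(buildUniformKernel(params, 1, 40, 0.5), "odd")
  den <- VoxelGrid(array(1, c(5, 5, 5)), 1, kind = "density")
  expect_error(buildTDSVKernel(params, den, c(3, 3, 3), 4), "odd")
})

test_that("ray-mean density matches exact traversal accounting", {
  # uniform density: any offset returns the constant
  den <- VoxelGrid(array(0.7, c(9, 9, 9)), 1, kind = "density")
  expect_equal(rayMeanDensity(den, c(5, 5, 5), c(3, -2, 1)), 0.7)
  # degenerate offset: density at the centre voxel
  v <- array(1, c(7, 7, 7)); v[4, 4, 4] <- 1.9
  den2 <- VoxelGrid(v, 1, kind = "density")
  expect_equal(rayMeanDensity(den2, c(4, 4, 4), c(0, 0, 0)), 1.9)
  # axis-aligned segment crossing three water then two air voxels:
  # length weights are (0.5, 1, 1, 1, 0.5) voxels over a length of 4
  v <- array(1, c(7, 7, 7)); v[5:7, , ] <- 0.0012
  den3 <- VoxelGrid(v, 1, kind = "density")
  expected <- (0.5 * 1 + 1 + 1 + 0.0012 + 0.5 * 0.0012) / 4
  expect_equal(rayMeanDensity(den3, c(2, 4, 4), c(4, 0, 0)), expected,
               tolerance = 1e-9)
  # oblique segment against a fine-step sampling oracle
  set.seed(42)
  v <- array(runif(11^3, 0.2, 1.9), c(11, 11, 11))
  den4 <- VoxelGrid(v, 1, kind = "density")
  center <- c(4, 5, 3); offset <- c(5, 3, 6)
  n <- 2e5
  t <- (seq_len(n) - 0.5) / n
  idx <- cbind(round(center[1] + t * offset[1]),
               round(center[2] + t * offset[2]),
               round(center[3] + t * offset[3]))
  oracle <- mean(v[idx])
  expect_equal(rayMeanDensity(den4, center, offset), oracle,
               tolerance = 1e-4)
})

test_that("TDSV kernel equals the uniform kernel in homogeneous media", {
  params <- rbFix()
  den <- VoxelGrid(array(1.0, c(9, 9, 9)), 0.8, kind = "density")
  kt <- buildTDSVKernel(params, den, c(5, 5, 5), 21, boundary = "clamp")
  ku <- buildUniformKernel(params, 1.0, 21, 0.8)
  expect_lt(max(abs(kernelWeights(kt) - kernelWeights(ku))), 1e-9)
})

test_that("TDSV kernel redirects mass away from an air half-space", {
  # a positron crossing air annihilates beyond it or escapes, so the
  # air side of a water/air interface receives less annihilation mass
  params <- rbFix()
  v <- array(1.0, c(31, 31, 31))
  v[17:31, , ] <- 0.0012
  den <- VoxelGrid(v, 1, kind = "density")
  k <- buildTDSVKernel(params, den, c(16, 16, 16), 21, boundary = "clamp")
  w <- kernelWeights(k)
  waterSide <- sum(w[1:10, , ])
  airSide <- sum(w[12:21, , ])
  expect_lt(airSide, waterSide)
})

test_that("the 21 stencil is the renormalized core of the 41 stencil", {
  params <- rbFix()
  k41 <- buildUniformKernel(params, 1.0, 41, 0.8)
  k21 <- buildUniformKernel(params, 1.0, 21, 0.8)
  core <- kernelWeights(k41)[11:31, 11:31, 11:31]
  expect_lt(sum(core), 1) # the larger stencil holds strictly more mass
  expect_equal(core / sum(core), kernelWeights(k21), tolerance = 1e-9)
})

test_that("kernel parameters round-trip through YAML", {
  params <- rbFix()
  f <- tempfile(fileext = ".yaml")
  writeAPSFParams(params, f)
  back <- readAPSFParams(f)
  expect_equal(back@C, params@C, tolerance = 1e-9)
  expect_equal(back@r0, params@r0, tolerance = 1e-9)
  expect_equal(back@epsilon, params@epsilon, tolerance = 1e-9)
})
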