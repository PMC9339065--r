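# NEMA metrics, line profiles, width measures and the Butterworth
# post-filter.

test_that("percent SD is the population SD over the mean", {
  v <- VoxelGrid(array(2, c(4, 4, 1)), 1)
  roi <- array(TRUE, c(4, 4, 1))
  expect_equal(percentSD(v, roi), 0)
  v2 <- VoxelGrid(array(c(1, 3), c(2, 1, 1)), 1)
  expect_equal(percentSD(v2, array(TRUE, c(2, 1, 1))), 0.5) # pop SD 1, mean 2
  v3 <- VoxelGrid(7 * gridValues(v2), 1)
  expect_equal(percentSD(v3, array(TRUE, c(2, 1, 1))), 0.5) # scale invariant
  expect_error(percentSD(VoxelGrid(array(0, c(2, 1, 1)), 1),
                         array(TRUE, c(2, 1, 1))), "zero mean")
})

test_that("spillover ratio divides cold by uniform means", {
  v <- array(2, c(4, 4, 1)); v[1:2, 1, 1] <- c(0.1, 0.3)
  g <- VoxelGrid(v, 1)
  cold <- array(FALSE, c(4, 4, 1)); cold[1:2, 1, 1] <- TRUE
  unif <- !cold
  s <- spilloverRatio(g, cold, unif)
  expect_equal(s$ratio, 0.1)
  expect_equal(s$sd, 0.1 / 2)
  zero <- g; zero@values[cold] <- 0
  expect_equal(spilloverRatio(zero, cold, unif)$ratio, 0)
  # invariant under global scaling
  s7 <- spilloverRatio(VoxelGrid(7 * v, 1), cold, unif)
  expect_equal(s7$ratio, s$ratio)
})

test_that("recovery coefficients are one on the perfect phantom", {
  ph <- genNemaNu4(0.5)
  lab <- ph$rois$labels@values
  rodTable <- ph$rois$table[!is.na(ph$rois$table$diameter), ]
  rc <- recoveryCoefficients(ph$activity, lab, rodTable, lab == 1L)
  expect_equal(rc$rc, rep(1, 5))
  expect_identical(rc$diameter, 1:5)
  # scale invariance
  rc7 <- recoveryCoefficients(VoxelGrid(7 * ph$activity@values,
                                        ph$activity@voxelSize),
                              lab, rodTable, lab == 1L)
  expect_equal(rc7$rc, rc$rc)
})

test_that("RC of a Gaussian-blurred rod matches the closed form", {
  # disk of radius R blurred by an isotropic Gaussian: centre value
  # 1 - exp(-R^2 / (2 sigma^2))
  R <- 1.5; sigma <- 1; step <- 0.1
  n <- 81
  xy <- (seq_len(n) - (n + 1) / 2) * step
  disk <- outer(xy^2, xy^2, "+") <= R^2
  gk <- exp(-xy^2 / (2 * sigma^2))
  kern <- outer(gk, gk) # separable Gaussian kernel on the same grid
  kern <- kern / sum(kern)
  m <- (n - 1) / 2
  kern <- kern[c((m + 1):n, 1:m), c((m + 1):n, 1:m)] # centre -> index 1
  img <- Re(fft(fft(disk * 1) * fft(kern), inverse = TRUE)) / n^2
  img <- pmax(array(c(img), c(n, n, 1)), 0)
  # uniform reference region at value 1 alongside the rod
  vol <- array(1, c(n, n, 2)); vol[, , 1] <- img[, , 1]
  lab <- array(0L, c(n, n, 2))
  lab[outer(xy^2, xy^2, "+") <= (2 * R)^2] <- 1L # rod ROI, slice 1 only
  lab[, , 2] <- 0L
  rodLab <- lab; rodLab[, , 2] <- 0L
  unif <- array(FALSE, c(n, n, 2)); unif[, , 2] <- TRUE
  rc <- recoveryCoefficients(VoxelGrid(vol, step), rodLab,
                             data.frame(label = 1L, diameter = 3), unif)
  expect_equal(rc$rc, 1 - exp(-R^2 / (2 * sigma^2)), tolerance = 0.02)
})

test_that("line profiles interpolate trilinearly", {
  v <- array(5, c(10, 10, 3))
  g <- VoxelGrid(v, 1)
  pr <- lineProfile(g, c(-3, -3, 0), c(3, 3, 0), 0.25)
  expect_equal(pr@values, rep(5, length(pr@positions)), tolerance = 1e-12)
  # a linear ramp is reproduced exactly
  ramp <- array(rep(1:10, times = 100), c(10, 10, 10))
  gr <- VoxelGrid(ramp, 1)
  pr2 <- lineProfile(gr, c(-4, 0, 0), c(4, 0, 0), 0.2)
  # voxel i holds value i; world x = i - 5.5, so value = position + 1.5
  expect_equal(pr2@values, pr2@positions + 1.5, tolerance = 1e-12)
  expect_error(lineProfile(g, c(0, 0, 0), c(50, 0, 0)), "leaves")
})

test_that("widths of analytic peaks match their closed forms", {
  x <- seq(-15, 15, by = 0.05)
  gauss <- new("LineProfile", positions = x + 15,
               values = exp(-x^2 / (2 * 2^2)))
  w <- fwhmFwtm(gauss)
  expect_equal(unname(w["fwhm"]), 2 * sqrt(2 * log(2)) * 2, tolerance = 0.06)
  expect_equal(unname(w["fwtm"]), 2 * sqrt(2 * log(10)) * 2, tolerance = 0.06)
  tri <- new("LineProfile", positions = x + 15,
             values = pmax(1 - abs(x) / 4, 0))
  expect_equal(unname(fwhmFwtm(tri)["fwhm"]), 4, tolerance = 0.06)
  flat <- new("LineProfile", positions = x + 15,
              values = rep(1, length(x)) + 0.001 * dnorm(x))
  expect_error(fwhmFwtm(flat), "crosses")
})

test_that("FWTM never falls below FWHM on random unimodal profiles", {
  x <- seq(0, 30, by = 0.1)
  for (s in 1:10) {
    set.seed(s)
    centre <- runif(1, 10, 20)
    width <- runif(1, 1, 4)
    shape <- runif(1, 1, 3)
    y <- exp(-abs((x - centre) / width)^shape)
    w <- fwhmFwtm(new("LineProfile", positions = x, values = y))
    expect_gte(w["fwtm"], w["fwhm"])
    # dense-resampling brute-force oracle within one step
    xf <- seq(0, 30, by = 0.002)
    yf <- exp(-abs((xf - centre) / width)^shape)
    expect_lt(abs(w["fwhm"] - 0.002 * sum(yf > max(yf) / 2)), 0.1)
  }
})

test_that("the pedestal option isolates a peak from its baseline", {
  # a wall peak next to a spillover shelf: the tenth-maximum level is
  # undefined without pedestal subtraction (the shelf never drops below
  # it) but well defined once the flanking-minimum baseline is removed
  x <- seq(0, 25, by = 0.05)
  y <- exp(-(x - 12)^2 / 2) + 0.45 / (1 + exp(2 * (x - 10)))
  pr <- new("LineProfile", positions = x, values = y)
  expect_error(fwhmFwtm(pr, pedestal = "none"), "crosses")
  ped <- fwhmFwtm(pr, pedestal = "flank")
  # a finite, peak-localized width (the raised threshold makes it
  # narrower than the pure-Gaussian 2.35)
  expect_gt(unname(ped["fwhm"]), 1)
  expect_lt(unname(ped["fwhm"]), 2.5)
  expect_gte(ped["fwtm"], ped["fwhm"])
})

test_that("the Butterworth filter has the textbook frequency response", {
  # a constant volume passes unchanged (unit DC gain)
  const <- VoxelGrid(array(3, c(16, 16, 4)), 1)
  expect_equal(gridValues(butterworth3d(const)), gridValues(const),
               tolerance = 1e-9)
  # gain 1/sqrt(2) at the cutoff frequency
  n <- 50
  f <- 0.2 * 0.5 # cycles per sample at 0.2 x Nyquist
  wave <- 2 + cos(2 * pi * f * (0:(n - 1)))
  vol <- VoxelGrid(array(rep(wave, times = n), c(n, n, 1)), 1)
  out <- gridValues(butterworth3d(vol, order = 10, cutoff = 0.2))
  amp <- (max(out) - min(out)) / 2
  expect_equal(amp, 1 / sqrt(2), tolerance = 0.02)
  # a Nyquist checkerboard is crushed by far more than 10x
  cb <- 2 + outer(outer((-1)^(1:16), (-1)^(1:16)), (-1)^(1:4))
  vcb <- VoxelGrid(array(cb, c(16, 16, 4)), 1)
  outCb <- gridValues(butterworth3d(vcb, order = 10, cutoff = 0.2))
  expect_lt(sd(outCb), sd(cb) / 10)
  expect_error(butterworth3d(const, cutoff = 0), "cutoff")
})

test_that("the NEMA sweep reports one ordered row per snapshot", {
  fx <- nemaFix()
  sw <- fx$sweeps$td2
  expect_identical(nrow(sw), 2L)
  expect_identical(sw$iteration, c(10L, 40L))
  expect_true(all(c("pct_sd", "sor_air", "sor_water", "rc_3mm",
                    "rc_3mm_sd") %in% names(sw)))
  # PRC noise grows with iterations (the %SD curve keeps increasing)
  expect_gt(sw$pct_sd[2], sw$pct_sd[1])
})
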