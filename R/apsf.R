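#' Evaluate the radial annihilation point-spread function
#'
#' `aPSF(r) = C * ((a*r + 1) * (1 - r/r0)^n - epsilon/r^n) / r^2` for
#' `0 < r <= r0`, zero beyond the maximum range `r0`, and clamped at zero
#' where the bracketed term is negative (the fitted core/tail term can
#' undershoot; annihilation densities are non-negative).
#'
#' The `1/r^2` singularity at the origin is integrable in 3D (the radial
#' mass `4*pi*r^2*aPSF(r)` is bounded); kernel construction absorbs it by
#' integrating over the half-voxel sphere, see [buildUniformKernel()].
#'
#' @param params an [APSFParams-class].
#' @param r distance(s) from the decay site in mm; must be > 0.
#' @return Annihilation density per unit volume (relative units).
#' @export
apsfRadial <- function(params, r) {
  stopifnot(is(params, "APSFParams"))
  if (any(r <= 0)) stop("apsfRadial: r must be > 0 (domain error)")
  out <- numeric(length(r))
  inside <- r <= params@r0
  ri <- r[inside]
  if (length(ri)) {
    bracket <- (params@a * ri + 1) * (1 - ri / params@r0)^params@n -
      params@epsilon / ri^params@n
    out[inside] <- params@C * pmax(bracket, 0) / ri^2
  }
  out
}

# radial mass density r^2 * aPSF(r); bounded on [0, r0], used for
# quadrature and kernel lookup tables.  Vectorized; 0 outside [0, r0).
apsfRadialMass <- function(params, r) {
  out <- numeric(length(r))
  inside <- r >= 0 & r < params@r0
  ri <- r[inside]
  if (length(ri)) {
    eps_term <- ifelse(ri == 0,
                       if (params@epsilon > 0) Inf else 0,
                       params@epsilon / ri^params@n)
    bracket <- (params@a * ri + 1) * (1 - ri / params@r0)^params@n - eps_term
    out[inside] <- params@C * pmax(bracket, 0)
  }
  out
}

# lookup tables for the C++ kernel builders: B(u) = u^2 aPSF(u) and its
# cumulative integral M(t) on a uniform grid over [0, r0]
apsfLut <- function(params, n = 8192L) {
  u <- seq(0, params@r0, length.out = n)
  B <- apsfRadialMass(params, u)
  du <- u[2] - u[1]
  M <- c(0, cumsum((B[-1] + B[-n]) / 2 * du))
  list(u = u, B = B, M = M, r0 = params@r0)
}

#' Water-equivalent distance
#'
#' Scales a physical distance to the reference medium:
#' `r_eq = r * rho / rhoRef`.  Densities are expressed relative to water,
#' so `r_eq` is in water-equivalent mm.
#'
#' @param r physical distance(s), mm; must be >= 0.
#' @param rho local tissue density, g/cm^3; must be > 0.
#' @param rhoRef reference density (default water, 1 g/cm^3).
#' @return Equivalent distance(s) in mm.
#' @export
equivalentDistance <- function(r, rho, rhoRef = 1) {
  if (any(r < 0)) stop("equivalentDistance: r must be >= 0")
  if (any(rho <= 0) || rhoRef <= 0)
    stop("equivalentDistance: densities must be > 0")
  r * rho / rhoRef
}

#' Mean 3D positron range implied by an annihilation profile
#'
#' The mean decay-to-annihilation distance in a homogeneous medium of
#' density `rho`: the mean of `r` under the radial distribution
#' `p(r) proportional to 4*pi*r^2 * aPSF(r * rho / rhoRef)`, computed by
#' quadrature.  Scales exactly as `1/rho` (the equivalent-distance law).
#'
#' @param params an [APSFParams-class].
#' @param rho medium density, g/cm^3; must be > 0.
#' @return Mean range in mm.
#' @export
meanRange <- function(params, rho = 1) {
  stopifnot(is(params, "APSFParams"))
  if (rho <= 0) stop("meanRange: rho must be > 0 (domain error)")
  s <- rho / params@rhoRef
  upper <- params@r0 / s
  m <- function(r) apsfRadialMass(params, r * s)
  num <- integrate(function(r) r * m(r), 0, upper, rel.tol = 1e-9,
                   subdivisions = 500L)$value
  den <- integrate(m, 0, upper, rel.tol = 1e-9, subdivisions = 500L)$value
  if (den <= 0) stop("meanRange: profile has zero mass")
  num / den
}

# ---- Rb-82 beta-transport reference profile --------------------------------

# Berger-Seltzer collision stopping power for positrons in water,
# MeV cm^2/g (Z/A = 0.55509, I = 75 eV, no density-effect correction,
# negligible below a few MeV), plus a rough radiative term.
.positronStoppingPower <- function(T) {
  me <- 0.510999
  ZA <- 0.55509
  I <- 75e-6
  tau <- T / me
  beta2 <- 1 - 1 / (1 + tau)^2
  Fp <- 2 * log(2) - (beta2 / 12) *
    (23 + 14 / (tau + 2) + 10 / (tau + 2)^2 + 4 / (tau + 2)^3)
  col <- 0.153536 / beta2 * ZA *
    (log(tau^2 * (tau + 2) / (2 * (I / me)^2)) + Fp)
  rad <- col * T * 7.42 / 700 # effective Z of water
  col + rad
}

# CSDA range (g/cm^2 == cm in water) on an energy grid, by integrating the
# inverse stopping power; the sub-10-keV remainder is a straight-line term.
.csdaRangeTable <- function(Tmax, n = 2048L) {
  T0 <- 0.01
  Tg <- seq(T0, Tmax, length.out = n)
  inv <- 1 / .positronStoppingPower(Tg)
  dT <- Tg[2] - Tg[1]
  R <- T0 / .positronStoppingPower(T0) +
    c(0, cumsum((inv[-1] + inv[-n]) / 2 * dT))
  list(T = Tg, R = R)
}

# Fermi-corrected allowed beta+ spectrum shape for a branch of endpoint Q
# (MeV); daughter Z = 36 (Kr-82).  Coulomb repulsion suppresses slow
# positrons, which matters for the mean range.
.betaSpectrumShape <- function(T, Q, Z = 36) {
  me <- 0.510999
  W <- T + me
  p <- sqrt(pmax(W^2 - me^2, 1e-12))
  s <- p * W * (Q - T)^2
  eta <- -(1 / 137.036) * Z * W / p
  x <- 2 * pi * eta
  s * x / (1 - exp(-x))
}

#' Simulate the Rb-82 annihilation radial profile in water
#'
#' Simplified beta-transport Monte Carlo: positron kinetic energies are
#' sampled from the Fermi-corrected allowed spectrum of the two main Rb-82
#' beta+ branches (endpoints 3.378 and 2.601 MeV, 81.8% / 13.1%), each
#' energy is converted to a water range by integrating the Berger-Seltzer
#' positron stopping power (CSDA), and the positron is assumed to travel
#' that distance in a straight line in an isotropic direction, so the 3D
#' decay-to-annihilation displacement equals the CSDA range.  Tortuosity,
#' energy straggling and annihilation in flight are neglected.
#'
#' @param nDecays number of simulated decays.
#' @param seed RNG seed (the profile is fully reproducible from it).
#' @param binWidth histogram bin width in mm.
#' @return A [RadialProfile-class]; the annihilation density per unit
#'   volume (normalized to unit integral over 3D).  The attribute
#'   `meanRange3d` carries the sample mean displacement in mm.
#' @export
rbAnnihilationProfile <- function(nDecays = 1e6, seed = 1, binWidth = 0.1) {
  set.seed(seed)
  branchQ <- c(3.378, 2.601)
  branchF <- c(0.818, 0.131)
  branchF <- branchF / sum(branchF)
  csda <- .csdaRangeTable(max(branchQ))

  n <- as.integer(nDecays)
  b <- sample.int(2L, n, replace = TRUE, prob = branchF)
  T <- numeric(n)
  for (i in 1:2) {
    idx <- which(b == i)
    if (!length(idx)) next
    Tg <- seq(1e-4, branchQ[i] - 1e-6, length.out = 4096L)
    pdf <- .betaSpectrumShape(Tg, branchQ[i])
    cdf <- cumsum(pdf)
    cdf <- cdf / cdf[length(cdf)]
    T[idx] <- approx(cdf, Tg, xout = runif(length(idx)), rule = 2)$y
  }
  # straight-line displacement = CSDA range, in mm (water, rho = 1)
  r <- 10 * approx(csda$T, csda$R, xout = T, rule = 2)$y

  nBins <- ceiling(max(r) / binWidth)
  counts <- tabulate(pmin(floor(r / binWidth) + 1L, nBins), nBins)
  mids <- (seq_len(nBins) - 0.5) * binWidth
  dens <- counts / (n * 4 * pi * mids^2 * binWidth)
  out <- radialProfile(mids, dens)
  attr(out, "meanRange3d") <- mean(r)
  out
}

#' Fit the annihilation point-spread function to a radial profile
#'
#' Least-squares fit of the five-parameter aPSF functional form (see
#' [apsfRadial()]) to a sampled radial annihilation density.  The fit is
#' performed on the radial mass `4*pi*r^2*p(r)` (bounded at the origin),
#' with Levenberg-Marquardt and box constraints keeping all parameters in
#' their physical ranges.  The returned parameters are normalized so the
#' profile integrates to 1 over the 3D ball of radius `r0`.
#'
#' @param reference a [RadialProfile-class] with at least 10 points.
#' @param init optional [APSFParams-class] starting point.
#' @return A fitted, normalized [APSFParams-class] with attributes
#'   `relRMS` (relative root-mean-square residual on the radial mass) and
#'   `deviance` (residual sum of squares).
#' @export
fitAPSF <- function(reference, init = NULL) {
  stopifnot(is(reference, "RadialProfile"))
  r <- reference@radii
  y <- 4 * pi * r^2 * reference@values
  if (length(r) < 10L)
    stop("fitAPSF: reference needs at least 10 points")
  if (all(y == 0))
    stop("fitAPSF: degenerate fit, reference profile is identically zero")
  rmax <- max(r)
  if (is.null(init))
    init <- apsfParams(C = max(y) / (4 * pi), a = 0.5, n = 2,
                       epsilon = 1e-3, r0 = rmax * 1.02)
  par0 <- c(C = init@C, a = init@a, n = init@n, eps = init@epsilon,
            r0 = max(init@r0, rmax * 1.001))
  model <- function(p, r) {
    prm <- apsfParams(C = p[["C"]], a = p[["a"]], n = p[["n"]],
                      epsilon = p[["eps"]], r0 = p[["r0"]])
    4 * pi * apsfRadialMass(prm, r)
  }
  fit <- minpack.lm::nls.lm(
    par = par0,
    fn = function(p) model(p, r) - y,
    lower = c(C = 1e-12, a = 0, n = 0.05, eps = 0, r0 = rmax * 1.0005),
    upper = c(C = Inf, a = 100, n = 25, eps = 1, r0 = 4 * rmax),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12))
  if (!fit$info %in% 1:4)
    stop(sprintf(
      "fitAPSF: no convergence (info %d, best residual %.4g): %s",
      fit$info, fit$deviance, fit$message))
  p <- fit$par
  prm <- apsfParams(C = p[["C"]], a = p[["a"]], n = p[["n"]],
                    epsilon = p[["eps"]], r0 = p[["r0"]])
  # normalize the 3D integral to 1
  mass <- integrate(function(u) 4 * pi * apsfRadialMass(prm, u), 0, prm@r0,
                    rel.tol = 1e-10, subdivisions = 500L)$value
  if (mass <= 0) stop("fitAPSF: fitted profile has zero mass")
  prm@C <- prm@C / mass
  relRMS <- sqrt(mean((model(p, r) - y)^2)) / sqrt(mean(y^2))
  attr(prm, "relRMS") <- relRMS
  attr(prm, "deviance") <- fit$deviance
  prm
}

#' Calibrated Rb-82 kernel parameters
#'
#' Convenience wrapper: simulate the water reference profile with
#' [rbAnnihilationProfile()] and fit it with [fitAPSF()].  Results are
#' cached per (nDecays, seed) within the session.
#'
#' @inheritParams rbAnnihilationProfile
#' @return A fitted [APSFParams-class].
#' @export
rb82Params <- local({
  cache <- new.env(parent = emptyenv())
  function(nDecays = 1e6, seed = 1) {
    key <- sprintf("n%g_s%d", nDecays, as.integer(seed))
    if (is.null(cache[[key]]))
      cache[[key]] <- fitAPSF(rbAnnihilationProfile(nDecays, seed))
    cache[[key]]
  }
})

#' Read/write aPSF parameters as YAML
#'
#' @param params an [APSFParams-class].
#' @param path file path.
#' @return `readAPSFParams` returns an [APSFParams-class];
#'   `writeAPSFParams` returns `path` invisibly.
#' @export
writeAPSFParams <- function(params, path) {
  stopifnot(is(params, "APSFParams"))
  yaml::write_yaml(list(C = params@C, a = params@a, n = params@n,
                        epsilon = params@epsilon, r0 = params@r0,
                        rho_ref = params@rhoRef), path, precision = 15L)
  invisible(path)
}

#' @rdname writeAPSFParams
#' @export
readAPSFParams <- function(path) {
  p <- yaml::read_yaml(path)
  apsfParams(C = p$C, a = p$a, n = p$n, epsilon = p$epsilon, r0 = p$r0,
             rhoRef = p$rho_ref)
}
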