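---
title: "Positron range correction for Rb-82 PET: model, kernels and evaluation"
author: "prcpet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positron range correction for Rb-82 PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Rb-82 is attractive for myocardial perfusion PET (76 s half-life,
generator-produced), but its positron is emitted at up to 3.4 MeV and
travels a mean of about 7.5 mm in water before annihilating.  PET
localizes the *annihilation*, not the decay, so the reconstructed image
is the tracer distribution blurred by the annihilation point-spread
function (aPSF).  In a human heart this hardly matters; in a rat heart
(3 mm left-ventricular wall) it destroys the separation between
myocardium and blood pool.  Positron range correction (PRC) puts a model
of the aPSF *inside* the reconstruction so that iterative updates
deconvolve the range blur.

`prcpet` implements the two established kernel models:

* **TD** (tissue dependent): the density volume is segmented into 1-3
  classes (water; air/water; lung/water/bone) and each class is blurred
  with the uniform kernel of its representative density.  "TD 2" means
  two segmentation levels.
* **TDSV** (tissue dependent, spatially variant): every voxel gets its
  own kernel; the weight toward each neighbour is evaluated at the
  *equivalent distance* computed from the mean density along the
  straight ray to that neighbour, so kernels adapt across tissue
  borders.  "TDSV 41" means a 41-voxel stencil.

## The annihilation profile model

The radial profile is the five-parameter form

aPSF(r) = C [ (a r + 1) (1 - r/r0)^n - eps / r^n ] / r^2,

clamped at zero where the bracket is negative and zero beyond the
maximum range `r0`.  Density scaling uses the water-equivalent distance
`r_eq = r * rho / rhoRef`, so a medium of half density doubles every
annihilation distance (and `meanRange()` scales exactly as `1/rho`).

No published parameter values exist for the Rb-82 profile, so the
package calibrates them itself with a deliberately simple beta-transport
Monte Carlo (`rbAnnihilationProfile()`):

1. sample the positron kinetic energy from the Fermi-corrected allowed
   spectra of the two main branches (endpoints 3.378 / 2.601 MeV,
   81.8% / 13.1%);
2. convert energy to a water range by integrating the Berger-Seltzer
   positron collision stopping power (CSDA; validated against standard
   tabulations to about 1.5%);
3. take the 3D displacement as that range along an isotropic straight
   line.

The fitted profile (`fitAPSF()`, Levenberg-Marquardt on the radial mass
`4 pi r^2 aPSF`, box-constrained, normalized to unit 3D integral) has a
mean range in water of about 7.1 mm, inside the published
7.5 +/- 0.5 mm window.  Two properties of this *simplified* transport
matter for everything downstream:

* **No short-displacement core.**  Real positron paths are tortuous and
  backscatter, concentrating a large fraction of annihilations within
  1-2 mm of the decay.  The straight-line model has almost no mass
  there (the Fermi-corrected spectrum has little low-energy weight), so
  the simulated uncorrected blur is substantially *worse* than a real
  scanner's, and deconvolution has to work harder.  This is the main
  reason the absolute uncorrected FWHM and the convergence speed of the
  corrected reconstructions differ from scanner measurements (see
  "What the tests do and do not show").
* **A clamped core.**  The fitted `eps > 0` makes the profile exactly
  zero below ~0.03 water-equivalent mm, which is faithful to the
  Monte Carlo reference (in this model a positron never annihilates at
  its birthplace).

## Discrete kernels

Kernel weights integrate the probability-conserving annihilation
density of the straight-line model,

p(r) = B(r_eq) * rho_local / r^2,  with B(u) = u^2 aPSF(u),

over each stencil cell: the physical `r^2` is the solid-angle Jacobian
and `rho_local` (the *target* voxel's density) the annihilation rate.
In homogeneous media both factors are constant or cancel under
normalization, so this reduces to the published equivalent-distance
rule; in heterogeneous media it is the reading of that (unit-ambiguous)
rule that conserves probability - the bare substitution `aPSF(r_eq)`
assigns air cavities more annihilations than emissions.  A positron
crossing the NEMA air chamber therefore annihilates in the far wall or
escapes, never "in air", which reproduces the published behaviour of the
cold-air spillover under PRC.

Numerical choices:

* the `1/r^2` singularity at the source is absorbed by integrating the
  radial mass over the half-voxel sphere (radius = half the shortest
  voxel edge);
* cells are integrated by midpoint sub-cell quadrature that refines any
  axis whose voxel edge is much longer than the shortest one, so
  thick-slab voxels (below) receive the axially marginalized kernel
  rather than a central-plane cut;
* weights outside the size^3 stencil (21 or 41) are discarded and the
  stencil renormalized - the published fixed kernel sizes do the same.
  At 0.4 mm voxels a 41 stencil spans only +/-8.2 mm, a small fraction
  of the range in lung-like material, so truncation visibly fattens the
  in-plane tails;
* sources whose annihilation yield inside the stencil is below 0.1%
  (air) degrade to delta kernels: they would otherwise be
  near-unobservable spreaders that make the reconstruction
  ill-conditioned;
* ray-mean densities use exact voxel traversal (Amanatides-Woo);
  out-of-grid voxels count as air by default, or as the nearest edge
  voxel (`boundary = "clamp"`) for volumes that are crops of extruded
  objects.

## Projection model and simulator

The scanner model is a stacked-2D parallel-beam geometry: a pixel-driven
projector with linear radial interpolation whose back projector is the
exact transpose (the adjoint test passes at rounding error).  The
simulator applies the range blur in image space (decay to annihilation),
forward projects, attenuates (`exp(-mu * integral rho dl)`,
`mu = 0.0096`/mm at 511 keV), blurs radially with a Gaussian detector
response (default 1.6 mm FWHM, a small-animal-scanner value), scales to
the requested expected counts and draws Poisson counts from a single
seed.  The reconstruction models PRC and attenuation but, like the
reference implementations, not the detector response.

OSEM uses interleaved angle subsets in bit-reversed order, a uniform
positive start image, matched blur/projector pairs in both directions
(including the subset sensitivity images), and the iteration count as
the only stopping rule.  The TDSV adjoint is the exact transpose of the
spatially variant spreading operator.

## Quasi-2D slab studies

Full 3D TDSV-41 OSEM at sub-millimetre voxels is a GPU-scale
computation (each of the 640 subset updates applies two spatially
variant blurs of cost `N * 41^3`).  The package's evaluation studies
therefore use *thick-slab* volumes: one transaxial slab per analysed
region, with the slab thickness equal to the region's axial extent
(15 mm for the cardiac chamber and each NEMA region).  Kernels
marginalize over the slab column (the exact in-plane reduction for an
object extruded over the slab), `sliceIndependent = TRUE` treats axial
spread beyond the slab as escape, and several regions can share one
acquisition as independent slices of a single stack.  Problem sizes
used by the test suite: 96 x 96 x 1 at 0.4 mm (cardiac, 5e6 counts) and
76 x 76 x 3 at 0.5 mm (NEMA, 2e7 counts), 40 iterations x 16 subsets.

## What the tests do and do not show

The simulated studies reproduce the *directional* findings of the
scanner study: PRC sharpens the ventricular wall (TDSV-41 wall FWHM
lands within the published band around 3.26 mm for a 3 mm wall),
more than doubles the 3 mm rod recovery, cuts the water spillover, and
TD noise grows with iterations beyond the uncorrected level.  A
spatially variant correction also produces the published edge halo
(Gibbs overshoot) at hot/cold boundaries.

They do **not** reproduce every absolute value, for reasons the
implementation makes explicit:

* the uncorrected wall FWHM is much larger than the scanner's 6.73 mm
  because the simplified transport lacks the short-displacement core
  and the truncated 41-stencil folds the lung-material tails inward;
* the corrected lumen clears more slowly: the tenth-maximum width
  reaches the published regime at about 80 iterations rather than 40;
* the TDSV %SD-versus-iterations curve crosses the uncorrected curve
  later than in the scanner study, and the TDSV value in the cold *air*
  chamber stays ill-determined at 40 iterations (an air column that
  annihilates only in the surrounding wall is nearly unidentifiable
  from projections - the published method sidesteps this because a real
  aPSF keeps air sources quasi-local);
* in this heavy-tail regime TD develops a stronger border artefact than
  TDSV (the scanner study saw the reverse ordering of halo strength).
  The halo property is therefore asserted against the uncorrected
  reconstruction.

The gated studies freeze the phantom at each bin's midpoint phase
(quasi-static binning).  Summing per-bin reconstructions restores the
full motion blur by construction - the resolution benefit of gating is
demonstrated on a single gated frame, the standard per-frame sharpness
argument; the summed image is what the published workflow inspects for
myocardial homogeneity.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `kernelSize` | 41 voxels | stencil edge; 21 and 41 are the published sizes |
| `tdLevels` | 1 | TD segmentation classes (1 = water everywhere) |
| `iterations`, `subsets` | 40, 16 | OSEM schedule of the published protocol |
| `detectorFwhm` | 1.6 mm | intrinsic resolution in the simulator |
| `muWater` | 0.0096 /mm | 511 keV narrow-beam attenuation of water |
| `boundary` | `"air"` (0.0012 g/cm^3) | out-of-grid density for ray tracing |
| Butterworth | order 10, cutoff 0.2 x Nyquist | clinical post-filter setting |

Segmentation thresholds: 0.5 g/cm^3 (air/water) for two levels;
0.6 and 1.4 g/cm^3 for lung/water/bone, with sub-0.15 voxels assigned
lung (outside-animal air is masked by sensitivity anyway).

The FWHM/FWTM measure takes thresholds as fractions of the absolute
peak by default - wall-thickness tables are defined that way, and with
unresolved spillover the half-maximum level deliberately sits below the
lumen baseline.  `pedestal = "flank"` subtracts the larger flanking
minimum first for peak-intrinsic widths.

## Known limitations

* The transport model is the spec of a feasibility study, not a particle
  code: no tortuosity, straggling, annihilation in flight, or magnetic
  field effects; only Rb-82 is built in (other isotopes enter through
  fitted parameters).
* The scanner model is parallel-beam and slice-stacked; no scatter,
  randoms, prompt gamma, dead time or depth of interaction.
* TDSV kernel banks store per-voxel in-volume weights; memory grows as
  `N * size^3`, so spatially variant reconstructions are intended for
  the slab-scale volumes above, not full scanner grids.
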