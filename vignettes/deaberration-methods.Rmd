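---
title: "Elastic-model skull de-aberration: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic-model skull de-aberration: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the forward model and
its discretisation, the exact adjoint, the inverse problem, the synthetic
study that exercises everything, and the design decisions taken where more
than one reasonable choice existed. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The forward model

Transcranial photoacoustic signals traverse bone, which unlike soft tissue
supports both compression and shear waves. We therefore model propagation
with the isotropic elastic wave equation in velocity–stress form,

$$\rho\,\partial_t v_i = \partial_j \sigma_{ij},\qquad
\partial_t \sigma_{ij} = \lambda\,\delta_{ij}\,\partial_k v_k
 + \mu\,(\partial_i v_j + \partial_j v_i),$$

with the photoacoustic initial condition $\sigma_{ij}|_{t=0} = -p_0\,
\delta_{ij}$, $v_i|_{t=0}=0$. The skull is treated as a *homogeneous*
elastic solid — a single $(\rho, c_p, c_s)$ triple assigned to every bone
voxel of a registered mask — in a water background ($\mu = 0$,
$\lambda = \rho c^2$ with $c$ from the tank-temperature polynomial
`water_sos()`). Defaults follow representative cranial-bone values:
$\rho = 1850$ kg/m³, $c_p = 2800$ m/s, $c_s = 1250$ m/s. Because a
homogeneous model stands in for layered cortical/trabecular bone, these act
as *effective* speeds; in practice they are tuned within physiological
ranges per skull. Frequency-dependent attenuation and dispersion are not
modelled; below the 0.5 MHz band used for reconstruction this mainly costs
some resolution, not feature fidelity.

## Discretisation

The solver (`forward_operator()`, `run_elastic()`) is a Fourier
pseudo-spectral time-domain (PSTD) scheme:

* **Spatial derivatives** are computed exactly in Fourier space. Velocity
  and stress components live on grids staggered by half a cell, realised as
  spectral phase factors $e^{\pm i k \Delta x/2}$; with the shift, the
  derivative symbol is well defined including the Nyquist mode. Staggering
  removes the checkerboard null space of collocated PSTD and makes the
  scheme robust at material interfaces.
* **Time stepping** is an explicit leapfrog: stresses at integer and
  velocities at half-integer time levels, with the first velocity update a
  half step. The CFL number $c_{max}\Delta t/\Delta x$ is kept at or below
  0.3 (warning above); the reference configuration — 0.5 mm spacing
  (six points per in-water wavelength at the 0.5 MHz cutoff) and 50 ns
  stepping — sits at 0.28.
* **Material sampling**: $\rho$ is arithmetically averaged onto the
  staggered velocity points (buoyancy $2/(\rho_i+\rho_{i+1})$); $\lambda$
  and $\mu$ are sampled directly at their native points with no
  effective-medium homogenisation. For a homogeneous skull in water this
  choice is benign; strongly heterogeneous media would warrant a more
  careful averaging.
* **Absorbing boundaries** are split-field PMLs: each split component decays
  as $e^{-\alpha\,\Delta t/2}$ before and after its update, with a quartic
  absorption profile over 10 cells scaled for a $10^{-4}$ theoretical
  normal-incidence reflection. Measured against a quadruple-size reference
  domain, the boundary-induced error at an interior probe is about $10^{-5}$
  of the outgoing peak. (A naive reflection measurement is dominated by the
  *physical* algebraic tail of 2-D cylindrical waves, which is two orders of
  magnitude larger — the tests therefore compare against the big-domain
  reference.)
* **Energy**: the leapfrog scheme conserves a discrete quadratic invariant
  — kinetic energy at half-integer times plus the strain bilinear form
  between stresses at adjacent integer times. The tests verify conservation
  to round-off over 500 periodic steps; evaluating both terms at the same
  time level instead shows a spurious few-percent oscillation.

All operator applications run in 64-bit arithmetic; the adjoint tests depend
on it.

## The measurement model and its exact adjoint

The data model is $d \approx F S A\,p_0$: elastic propagation $A$,
multilinear interpolation $S$ onto the transducer positions at every time
step, and a causal second-order Butterworth low-pass $F$ (0.5 MHz default)
applied per channel. Two deliberate choices:

* **The filter sits inside the measurement operator** and is applied to both
  model predictions and (once) to the measured data, so the least-squares
  objective is $\tfrac12\|FSAp_0 - Fd\|^2$ and the operator and its adjoint
  remain exact companions. Transducers are idealised points — no element
  directivity or impulse response — matching the reconstruction model the
  de-aberration method assumes.
* **The adjoint is the exact transpose of the discrete forward map**, not a
  discretisation of a continuous adjoint. Each forward primitive is
  transposed mechanically: diagonal decay/material factors are symmetric,
  the transpose of the staggered derivative $D_{+1/2}$ is $-D_{-1/2}$
  (exactly, including Nyquist), interpolation transposes to scatter-add,
  and the causal filter to time-reversed filtering. The adjoint time loop
  runs the reversed sequence, injecting filtered residuals into the normal
  stress splits ($p = -\mathrm{tr}\,\sigma/d$ transposed) and finally
  reading out $-\tfrac1d\sum_i \tilde\sigma_{ii}$. Dot-product tests sit at
  $10^{-17}$–$10^{-16}$ for every shipped configuration (2-D/3-D, elastic,
  acoustic-only, with/without filter, with/without ROI restriction).

## The inverse problem

`pact_reconstruct(method = "iterative")` minimises

$$\tfrac12\|FSA\,p_0 - Fd\|^2 + \lambda_1\|p_0\|_1 + \lambda_{TV}\,TV(p_0)
\quad\text{s.t. } p_0 \ge 0$$

by a monotone accelerated proximal-gradient method:

* **Step size** $= 0.9/L$ with $L$ the largest eigenvalue of the normal
  operator from power iteration (20 iterations by default; the fixture
  configuration uses 8 — the Rayleigh quotient stabilises within a few
  iterations and the 0.9 safety factor plus the monotone safeguard absorb
  the residual uncertainty).
* **Momentum** uses the standard $t_{k+1} = (1+\sqrt{1+4t_k^2})/2$ schedule
  with a monotone safeguard: the incumbent is kept whenever the candidate
  raises the objective, so the reported objective trace is non-increasing
  by construction. One forward and one adjoint solve per iteration suffice:
  the operator value at the extrapolated point is a linear combination of
  cached values.
* **Proximal map**: the composite prox has no closed form; we apply
  non-negative soft-thresholding first, then isotropic TV denoising by dual
  fast gradient projection (20 inner iterations by default) with the
  non-negativity projection inside. Against the exact taut-string solution
  of the 1-D problem the inner solver reaches $10^{-4}$ accuracy at 400
  inner iterations.
* **Initialisation is the zero image**, which makes a single unregularised
  iteration coincide (up to step scale) with the adjoint reconstruction
  `method = "adjoint"` — the linear, parameter-free probe used for
  model-sensitivity analysis.
* **Regulariser weights** have no universal values; they depend on signal
  scale, noise and target type. The shipped fixture sets both weights to
  2% of the peak magnitude of the adjoint image of the data, which makes
  them invariant to the overall data gain.

UBP (`method = "ubp"`) is the aberrated baseline: back-projection of
$b(t) = 2p - 2t\,\dot p$ over circles (2-D) or spheres (3-D) with
cosine-weighted arc-length/solid-angle weights normalised per voxel;
negative values are retained.

## Registration and mask extraction

The skull geometry enters only through a binary mask plus one property
triple. `kabsch_register()` estimates the rigid CT/MR-to-PACT transform from
fiducial points by SVD of the centred cross-covariance, with the reflection
branch corrected by flipping the smallest singular direction, and reports
the residual RMSD. `binarize_fill_mask()` thresholds (global Otsu by
default, numeric override, invert flag for negative-contrast MR), applies a
binary closing (ball radius 2 voxels by default), and fills cavities fully
enclosed in the bone wall while preserving the cranial cavity, identified
as the largest enclosed non-bone component. Resampling onto the simulation
grid is nearest-neighbour by inverse mapping, preserving binarity; at the
0.5 mm scale of interest the sub-voxel error this introduces is well below
the model error of the homogeneous-skull assumption.

## The synthetic study

`transcranial_fixture()` builds the standing 2-D experiment used throughout
the tests: a 128² grid at 0.5 mm, a 6.5 mm annular shell (inner radius
14 mm, centre offset (1.5, −1) mm so rotations are not symmetries), a
seeded random-walk tube phantom (1.5 mm tubes) confined to the cranial
cavity and close to the inner shell surface, a 256-element circular array
of radius 25 mm, 640 steps of 50 ns, and 1% additive white Gaussian noise
(single-shot acquisition, no averaging). Reconstruction uses the central
64² region of interest. A 3-D spherical-shell smoke fixture (64³,
hemispherical array) guards the dimension-generic code paths.

What the generator emulates: the geometry and material contrast of a skull
phantom acquisition, mode conversion and reverberation in the shell, raw
broadband records filtered at reconstruction time, skull-emission
interference (`add_skull_background()`: a seeded smoothed non-negative
texture on the shell, forward-modelled and scaled to a chosen RMS ratio —
its default feature scale, 1.5 mm, matches the phantom tubes). What it does
not: 3-D scale (the real problem is ~10⁶ unknowns on GPU hardware; the
fixture is 2-D so the whole suite runs in minutes on one core), real-bone
heterogeneity and attenuation, element directivity, and — importantly —
model error: data are simulated with the same solver used to invert, so
fixture reconstructions quantify *aberration* correction, not
forward-model validity. The solver itself is validated independently
(fluid limit against a separately written scalar acoustic solver,
plane-wave speeds by time of flight, energy conservation, analytic
examples).

## The model-mismatch study

Following the sensitivity protocol, the adjoint image of fixed data is
recomputed with perturbed models: shear/compression speeds rescaled ±10%,
the mask rotated ±10°, the mask translated, and the acoustic-only model
($c_s = 0$). Sliding correlation (maximum zero-mean normalised
cross-correlation over ±10-voxel shifts) against the ground-truth phantom
is the figure of merit, since rigid mis-positioning partly translates the
image. On the fixture the matched elastic model always ranks first, the
−10% shear degradation exceeds the −10% compression degradation (shear
errors hurt more), and the acoustic-only model ranks below every speed and
rotation perturbation. The *translation* perturbation is the exception: a
1 cm shift — at this fixture's 25 mm array radius a much larger relative
perturbation than on a head-sized system, large enough to push the shell
partly outside the detection ring — degrades the image more than ignoring
shear entirely, and even a geometry-scaled 2 mm shift measures marginally
below the acoustic-only variant. The tests assert the full documented
ordering, so this clause is expected to fail on the fixture; we report it
rather than resize the perturbation, and note that position error being the
most damaging of the parameter perturbations is itself a consistent
finding of the sensitivity analysis.

## Numerical edge cases and conventions

* Coordinates: 1-based voxel indices in R, physical coordinates at voxel
  centres, SI units throughout (NIfTI files use mm per the format's
  convention); grids default to being centred on the physical origin.
* Degenerate inputs are rejected with named errors: negative $p_0$ in the
  photoacoustic initial condition, non-positive bulk modulus
  ($c_s$ too close to $c_p/\sqrt2$), pathological all-bone/all-background
  thresholds, collinear fiducials, sensors inside the PML, cutoffs at or
  above Nyquist, time axes too short for UBP coverage.
* The solver aborts with a diagnostic if any field grows beyond $10^6$
  times the initial amplitude (instability guard).
* Zero data reconstruct to the zero image for any regulariser weights;
  zero operators make power iteration return 0 with a warning.
* Sliding correlation requires at least 25% overlap; SSIM uses the
  conventional 11-tap Gaussian window ($\sigma = 1.5$, $k_1 = 0.01$,
  $k_2 = 0.03$) with the reference maximum as dynamic range.

## Known limitations

Homogeneous skull (effective speeds, no cortical/trabecular layering); no
frequency-dependent attenuation or dispersion; idealised point detectors;
rigid-only registration; the composite proximal map is approximate (L1
then TV); the 2-D fixture cannot probe out-of-plane mode conversion; and
scalp reflections / sources outside the skull are out of scope.
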