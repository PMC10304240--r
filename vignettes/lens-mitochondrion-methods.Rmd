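---
title: "Methods: polarized ray transport through a sphere-confined gyroid membrane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polarized ray transport through a sphere-confined gyroid membrane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical model

Tree-shrew cone inner segments contain enlarged "lens" mitochondria: spheres
of roughly 1 µm radius whose cristae form a multilayer cubic membrane of the
gyroid type. `mitolens` simulates monochromatic, polarized light transport
through such an organelle to ask what it does optically: focus, filter,
guide, or some mixture.

The geometry is the standard gyroid level-set approximant

$$g(u,v,w) = \sin u \cos v + \sin v \cos w + \sin w \cos u, \qquad
u = 2\pi x / a, \dots$$

evaluated in rotated, phase-shifted lattice coordinates and clipped to a
sphere of radius $R$. The zero level set divides the interior into two
interpenetrating labyrinths: compartment A ($g > 0$, cytosol-like,
$n_A = 1.33$) and compartment B ($g < 0$, the dense compartment, default
$n_B = 1.48$). Defaults are $R = 1000$ nm and $a = 400$ nm, i.e. a diameter
of five lattice cells.

The membrane wall separating the compartments is a stack of 12 lipid
bilayers ($n = 1.70$, 1.8 nm each) alternating with 11 cytosolic gaps
($n = 1.38$, 10 nm), 131.6 nm of finite layers bounded by the adjacent
compartments — 25 media in total. Two simplifications make ray transport
tractable:

* **Center approximation.** Collisions are detected against the single
  $g = 0$ mid-surface; the wall has no geometric thickness. Its full optical
  effect (reflection, transmission, polarization change, phase) enters
  through the stratified-media amplitudes applied at each crossing.
* **Local flatness.** Each crossing is treated as a plane-parallel
  stratified medium at the local incidence angle, valid because the
  individual layers are much thinner than the wavelength.

## Stratified-media optics

Each layer contributes a characteristic 2×2 matrix
$M = \begin{pmatrix}\cos(k_0 h) & i \sin(k_0 h)/\gamma\\ i\gamma\sin(k_0 h)
& \cos(k_0 h)\end{pmatrix}$ with apparent thickness $h = n d \cos\theta$ and
admittance $\gamma_s = n\cos\theta$, $\gamma_p = n/\cos\theta$ (the vacuum
admittance cancels in every ratio and is set to 1). The stack matrix is the
ordered product; reflection and transmission amplitudes follow from the
boundary conditions of the bounding media. Conventions that matter:

* $r_s = (n_0 - n_s)/(n_0 + n_s)$ at a bare normal-incidence interface
  (so $r = -0.2$ for 1.0 → 1.5); for p polarization the opposite sign is
  used together with right-handed $(\hat s, \hat p, \hat k)$ triads per ray,
  which makes the reflected field continuous through normal incidence and
  reproduces the Brewster null.
* Transmittance is $T = \mathrm{Re}(\gamma_s)/\gamma_0\,|t|^2$ (tangential
  amplitudes), which conserves $R + T = 1$ exactly for lossless stacks and
  yields $T = 0$ under total internal reflection (TIR).
* Evanescent *internal* layers are carried with complex cosines (frustrated
  TIR supported); TIR is declared only at the substrate. At TIR the stack's
  complex reflection amplitude (modulus 1, physical phase shift) is used.
* 90° incidence is evaluated as the one-sided limit $90° - 10^{-6}$ rad.

Indices are real (no absorption) and dispersionless: the bulk values are
known only at the Fraunhofer D line, so every chromatic effect in the
simulator is interferential, not material.

## Monte Carlo transport with photon splitting

Rays are launched from a half-spacing-offset square grid in the y–z plane,
restricted to the circle of radius $R$ so every ray meets the sphere, all
with direction $+x$, equal phase, and a common Jones vector. Each packet
carries complex s/p amplitudes in its own transverse basis, an accumulated
propagation phase $2\pi n \ell/\lambda$, and an energy weight
$|A_s|^2 + |A_p|^2$ (transmitted amplitudes are flux-normalised so this
identity survives refraction).

At every mid-surface or sphere crossing the packet is re-expressed in the
local s/p basis (at normal incidence the previous basis is kept — the
minimal-rotation choice avoids spurious geometric phase), split by the stack
amplitudes, and the children continue: transmitted along the Snell
direction, reflected along the mirror direction. Splitting strategies:

* **i** — Russian roulette: one unbiased survivor per event, chosen with
  probability proportional to branch energy, amplitudes rescaled by
  $1/\sqrt{p}$. Counter-based per-ray RNG streams make the result
  independent of scheduling.
* **ii** (default) — both branches pursued depth-first, weaker first;
  branches below $\varepsilon$ (default $10^{-9}$ of the per-ray input
  energy) are discarded into an exact ledger. Fully deterministic.
* **iii** — as ii, with each transmitted membrane branch fanned into a
  symmetric 3-ray kernel (weights ¼, ½, ¼, tilt $\lambda/(\pi s)$ within
  the plane of incidence) emulating small-scale diffraction. Off by
  default: geometric propagation is the primary mode.

The ledger (input = forward + backward + discarded, closed to $10^{-9}$
relative) is the primary energy observable; back-scattered light is
accounted separately and never silently dropped. A depth cap of 60
generations guards against trapped TIR orbits; energy removed there is
ledgered and warned about.

Ray–surface intersections are found by marching at steps of $a/50$ and
bisecting the bracketed sign change to 0.1 nm (far below the smallest layer
thickness); degenerate-gradient roots are stepped past by 0.5 nm and
re-searched. Index-matched sphere crossings are treated as pass-throughs:
at grazing incidence the admittance ratio of two *equal* media is otherwise
numerically unstable.

## Near-field integration and its sampling limits

Exit records are turned into image-plane maps two ways. The first-order
model propagates each record geometrically to the plane, adds its complex
transverse field at the landing pixel, and convolves the complex map with an
Airy point-spread function. The surface-patch model first bins records onto
~100 nm spherical patches (each record phase-referenced to its patch center
along its own direction) and re-emits Rayleigh–Sommerfeld wavelets with an
obliquity factor about the patch's mean direction.

Normalisation follows the sampled-field-density convention: a record of
amplitude $A$ represents a beamlet of area $s^2$ ($s$ the source spacing),
so its pixel contribution is scaled by $s/\mathrm{px}$ and the PSF kernel
has unit DC gain. Extended coherent fields are then power-correct — the
null model reconstructs a unit flat field — and interference (4× peaks for
in-phase pairs, nulls for opposed pairs) is preserved.

One genuine limitation shapes several design choices. The gyroid's local
curvature radius is $\sim a/2\pi \approx 64$ nm, smaller than any practical
ray spacing, so the exit-ray map is chaotic below the sampling scale:
neighbouring rays decorrelate in phase after a few crossings. Consequences:

* Coherent pixel sums underestimate absolute power for the membraned model
  (they sit near the white-noise floor) while still carrying the
  interference structure. Focus detection therefore uses raw coherent peaks
  compared against the analytic free-propagation background level, with a
  three-plane rolling mean to de-jitter the argmax.
* Disk-scale flux is computed from the geometric energy transport (the
  summed energy of records crossing the plane inside the disk), which is
  exact for smooth fields and robust to sub-pixel phase chaos. The
  `renormalize` option of `accumulate_first_order()` rescales a coherent
  map to the geometric landing energy when an absolute scale is needed.
* The focus-map pixel default is $\lambda/8$ ($\lambda/4$ for general
  maps): arrival angles span most of the hemisphere, and coarser pixels
  visibly decohere the focal ridge.
* The PSF default is the wave-resolution floor $NA = n_{ext}$
  ($\lambda/2n$): the coherent ray sum already carries the aperture
  geometry, and an aperture-limited kernel
  ($NA = n_{ext} R/\sqrt{R^2+x^2}$, available as `psf_na = "aperture"`)
  spans ~1 µm at the focal planes and erases exactly the structure the
  focus analysis measures.

The patch model's reconstruction of a truncated plane wave necessarily
shows Fresnel edge ringing (intensity sd/mean ≈ 0.4 across the shadow,
independent of patch size 40–100 nm) — the physical near-field of a large
circular aperture, not a quadrature artifact. The two models agree in
near-sphere disk power to ~15%.

## The equivalent closed bilayer

The 25-medium wall is condensed into a four-parameter "closed bilayer"
$X = \{n_a, n_b, d_a, d_b\}$ by minimising
$\sum_{i,j} |R_\perp - \hat R_\perp| + |R_\parallel - \hat R_\parallel|$
over 400–800 nm (5 nm steps) × 0–90° (1° steps). The bilayer topology is
the closed-membrane sandwich $[n_a,d_a][n_b,d_b][n_a,d_a]$ by default (a
membrane has two leaflets); the minimal two-layer reading is available as
`variant = "two_layer"` and the variant used is recorded in run manifests.
The optimiser is the bound-constrained PORT quasi-Newton routine
(`nlminb`), multi-started from 8 Halton points because a single
interior-point start is initialisation-sensitive. Bounds keep
$n \in [1.33, 2]$: no membrane component is less polarisable than cytosol.
The fit lands at $n_a \approx 1.551$, $n_b = 1.330$ (at its bound),
$d_a \approx 30.4$ nm, $d_b \approx 44.6$ nm, with thickness-weighted mean
index 1.458 against the wall's 1.433 — the wall behaves like a single
moderately-dense slab pair nested in cytosol.

## Fixtures: what the generated inputs do and do not emulate

All test inputs are generated in code. `null_sphere` (all indices 1.33,
membranes disabled) is the optically empty control: any spectral or spatial
structure it shows is integrator artefact. `ball_lens` (homogeneous sphere
at the wall-weighted mean index 1.43, membranes disabled) provides the
classical paraxial oracle $f = m R / (2(m-1))$, $m = n/n_{ext}$; its test
restricts the aperture to $0.35R$ because the full-aperture ball lens is
dominated by spherical aberration. `flat_wall`/`reference_wall` expose the
Table-style stack as an infinite slab for spectral checks. None of these
emulate organelle irregularity: real cristae are neither perfectly
periodic nor sharp-indexed, so passing tests certify the transport
machinery, not biological fidelity.

## Problem sizes

The test-suite and acceptance runs use ray grids of 2000–4000 rays
(spacing 28–40 nm), image planes every 0.1 µm, and single wavelengths per
trace; the bilayer fit uses the full 81 × 91 grid per objective call.
These sizes hold the strategy-ii event count around $2\text{–}3\times10^6$
per trace. Convergence was checked against 8000- and 22000-ray runs: total
transmitted energy moves by <1%, focal-plane selection by ±0.3 µm (the
speckle-realisation jitter discussed above).

## Known limitations

* No material dispersion or absorption; all chromatic structure is
  interferential.
* The chromatic (quasi-dispersion) shift of the focus is weak in this
  implementation: 350 nm and 600 nm light focus at
  essentially the same plane (~3.2–3.6 µm behind the rear pole), while
  the long-wavelength loss of focus at 800 nm does reproduce.
* The energy-weighted exit split slightly *disfavours* the high-index
  compartment's channel mouths (enhancement ≈ 0.93): Fresnel and TIR
  losses at the dense-compartment exit outweigh capture into its channels.
* UV flux reduction through the mitochondrion-diameter disk reaches ~70%
  at 6 µm planes, dominated by geometric dispersal of the beam rather than
  by interference rejection; close behind the sphere (1–2 µm) it is
  35–50%.
* The volume-fraction diagnostic saturates: the nominal 131.6 nm wall
  around the mid-surface would overfill the 400 nm cell, so wall/compartment
  splits are reported from a bounded distance-band estimate.
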