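# mitolens

Polarized Monte Carlo ray-optics simulation of the tree-shrew **lens
mitochondrion** — a ~1 µm spherical organelle in cone photoreceptors whose
cristae form a 12-bilayer gyroid cubic membrane. The package asks what such
an organelle does to the light passing through it: where it focuses, how
strongly it filters short wavelengths, how robust its transmission is to
orientation, and whether its high-index channels guide light.

It is intended for computational biophysicists and photonics researchers
studying sub-wavelength-structured biological optics, where full-wave (FDTD)
solvers are too expensive at organelle scale and plain ray tracing discards
the interference that produces the phenomena of interest.

## The model

The cubic membrane is the gyroid level set
`g(u,v,w) = sin u cos v + sin v cos w + sin w cos u = 0` (lattice constant
`a = 400` nm, rotated/phase-shifted at will) clipped to a sphere of radius
`R = 1000` nm. The two labyrinths it separates are cytosol-like compartment
A (`n_A = 1.33`) and the dense compartment B (`n_B = 1.48` by default). The
wall between them — 12 lipid bilayers (n = 1.70, 1.8 nm) alternating with 11
cytosolic gaps (n = 1.38, 10 nm) — is collapsed onto the mid-surface for
collision detection (*center approximation*) while its full optics enter
through the stratified-media characteristic matrices

```
M = | cos(k0 h)      i sin(k0 h)/γ |        h = n d cosθ,
    | i γ sin(k0 h)  cos(k0 h)     |        γ_s = n cosθ,  γ_p = n / cosθ
```

multiplied over the 25 media and closed with the bounding-media boundary
conditions to give complex r and t for s and p polarization at every
crossing angle (with exact `R + T = 1` for these lossless stacks and TIR
handled as unit-modulus reflection).

Transport is a splitting Monte Carlo: polarized ray packets (complex s/p
Jones amplitudes, accumulated optical phase, energy weight) are fired on a
y–z grid, split at every membrane/sphere crossing, and pursued weaker-branch
first until they exit or fall below `ε = 1e-9` of their input energy, with
an exact energy ledger. Exit records are integrated coherently onto image
planes (accumulator maps + Airy PSF, or Huygens surface patches) to yield
focus positions, flux-ratio spectra, rotation sweeps and waveguide
diagnostics. An equivalent-bilayer optimizer condenses the 25-medium wall
into the four-parameter closed bilayer that best matches its polarized
reflectance over 400–800 nm × 0–90°.

## Worked example

```r
library(mitolens)

m <- build_mitochondrion()      # defaults: R = 1 um, a = 400 nm, n_B = 1.48
m
#> <mitochondrion_model>
#>   radius: 1000 nm  lattice a: 400 nm  (diameter = 5.00 cells)
#>   n_A = 1.33, n_B = 1.48, n_exterior = 1.33
#>   wall: 23 layers, 131.6 nm total

src <- source_grid(spacing = 28, radius = 1000, wavelength = 550)
tr <- trace(m, src, seed = 1, record_floor = 1e-10)
tr
#> <trace_result>
#>   4020 rays at 550 nm, strategy ii | 543979 exit records
#>   energy: input 4020, forward 3858 (95.96%), backward 162.4 (4.04%),
#>           discarded 0.001189 (0.000%)
```

96% of the incident energy crosses the organelle forward, 4% is
back-scattered by the membrane stacks, and the splitting cutoff loses well
under the 1% bookkeeping budget. Scanning image planes behind the sphere
locates the interference focus:

```r
find_focus(m, 600, spacing = 28, seed = 1)
#> <focus_result> 600 nm: focus 3.30 um behind rear pole, peak 0.868,
#>                offset 53 nm (centered)
```

i.e. green-orange light concentrates ~3.3 µm downstream of the rear pole —
several times closer than the ~6 µm a homogeneous sphere of the same mean
index would give, a purely interferential effect. At 800 nm (twice the
lattice constant) the same call reports `no definitive focus` and an
off-center maximum. The equivalent-bilayer condensation of the wall:

```r
fit <- fit_bilayer(reference_wall())
fit$params[c("na", "nb", "da", "db")]
#> $na 1.5513   $nb 1.33   $da 30.44   $db 44.64
```

— the 25-medium wall behaves like a ~30 nm n≈1.55 leaflet pair around a
cytosol-index core.

A thin command-line interface over the same functions ships in
`inst/cli/mitolens` (subcommands `simulate`, `spectrum`, `fit-bilayer`,
`sweep`, `focus`, `fixtures`), each run writing a JSON manifest from which
it can be replayed.

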