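Package: mitolens
Title: Polarized Ray-Optics Simulation of the Tree-Shrew Lens Mitochondrion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulator for light transport through a
    sphere-confined multilayer gyroid membrane, the "lens mitochondrion"
    found in tree-shrew cone photoreceptors. Implements exact stratified-media
    (characteristic-matrix) thin-film optics for s and p polarization,
    polarized ray tracing with photon splitting and an exact energy ledger,
    an equivalent-bilayer optimizer for the 25-medium membrane wall, and
    coherent near-field integration onto image planes yielding focus
    position, quasi-dispersion, waveguide, rotation-robustness and
    UV-filtering diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
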