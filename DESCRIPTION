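Package: mrdose
Title: Desk-Scale Monte Carlo Dose Engine for a 0.35 T MR-Linac Photon Beam
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A voxelized Monte Carlo photon-electron dose engine for a 6 MV
    flattening-filter-free beam in a uniform 0.35 T transverse magnetic field,
    modelled on the 0.35 T MR-guided linac class of machines. Photons are
    transported with Woodcock delta-tracking (Compton, photoelectric, pair
    production) and charged particles with condensed-history steps on exact
    helices in the magnetic field. The package bundles the beam-commissioning
    workflow (staged grid search over incident electron-beam energy, focal
    spot size and energy spread against reference scans), the standard
    dose-comparison metrics (gamma index, distance to agreement, penumbra and
    depth-dose statistics), and a canned experiment suite (output factors,
    oblique beams, off-axis apertures, heterogeneous slab phantoms, and
    electron-return-effect quantification at lung-water interfaces).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
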