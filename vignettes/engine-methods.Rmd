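---
title: "The mrdose engine: physics, commissioning and validation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mrdose engine: physics, commissioning and validation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mrdose` is a desk-scale Monte Carlo dose engine for a 6 MV
flattening-filter-free (FFF) photon beam in a uniform 0.35 T transverse
magnetic field — the beam class delivered by compact MR-guided linacs. It
bundles three things: the transport engine itself, the beam-commissioning
workflow (a staged grid search of the incident electron-beam parameters
against reference scans), and a canned experiment suite (output factors,
oblique beams, off-axis apertures, heterogeneous slab phantoms, and
quantification of the electron return effect at lung–water interfaces).
This vignette explains the model, its assumptions, the tunable parameters,
and what the bundled tests do and do not demonstrate.

## The machine model

The machine is parameterized, not reproduced. A real MR-linac head contains
a target, primary collimator, monitor chamber, shielding, a double-stacked
multileaf collimator (MLC), and the magnet bore structures; all of that is
proprietary geometry. `mrdose` replaces it with:

* a point of bremsstrahlung emission at the target plane, laterally blurred
  by the focal-spot distribution;
* an analytic photon spectrum with one spectral tuning knob;
* an ideal divergent aperture at an effective collimation plane, with a
  constant transmission (default 0.005) for blocked rays.

Machine constants: source–axis distance 900 mm, maximum field
274 × 241 mm² at the isocenter. The static field (default 0.35 T) lies
along the inline (+Y) axis, orthogonal to both the beam (+Z at gantry 0)
and the MLC travel direction (crossline, X). Gantry rotation turns the
source about the isocenter in the crossline–depth plane, so
magnetic-field asymmetries appear in crossline profiles.

### Incident electron beam

The tunable quantities of the commissioning problem are preserved exactly:
the mean kinetic energy (default 6.0 MeV), the FWHM of a Gaussian energy
spread (default 1.5 MeV), and the FWHM of a Gaussian focal-spot radial
intensity distribution (default 1.0 mm, applied per lateral axis with
σ = FWHM/2.3548). These defaults are the commissioned values recovered by
the staged tuning workflow below.

### Photon spectrum

Photon energies follow a Schiff-type thin-target shape,
(1/k)(1 − k/E₀), hardened by an equivalent water filtration thickness *t*:

  n(k) ∝ (1/k)(1 − k/E₀) · exp(−μ_w(k) t)

*t* absorbs everything the parameterized head cannot represent — target
thickness, self-absorption, and all head filtration. It is the model's
single spectral knob and is fixed once by matching the tuned-beam
3.3 × 3.3 cm² depth dose at 10 cm (SSD 78 cm, 0.35 T) to the
commissioning value of 55.59 % (`tools/calibrate_hardening.R`); the
calibrated default is 110 mm. Sampling is by exact inversion of the
spectrum CDF, which separates as A(k) − B(k)/E₀ with endpoint-independent
cumulative tables — one uniform deviate maps smoothly to an energy for any
endpoint E₀, which matters for the correlated scans described below.

### Angular intensity

An FFF beam is forward-peaked but much flatter than the intrinsic
thin-target bremsstrahlung lobe (characteristic angle mₑc²/E₀ ≈ 0.085 rad),
because the effective source is a thick target viewed through head scatter.
The effective angular intensity is 1/(1 + (θ/θ_c)²)² with θ_c = 0.30 rad,
chosen so the intensity 12 cm off axis is ≈ 70 % of the central axis — the
typical unflattened-beam falloff. `fff_theta_c` is exposed on
`run_simulation()`; a non-positive value falls back to the intrinsic lobe.

### Collimation and the focal spot

Apertures are rectangles specified at the isocenter plane and scaled to an
effective collimation plane at `collimator_distance` (default 450 mm) from
the target. Rays are tested at that plane, so the focal-spot size blurs the
field edge with lever arm (SAD − d)/d — about 1:1 at the default. Blocked
rays keep a constant transmission weight and are Russian-rouletted before
reaching the phantom (expectation-preserving). Tongue-and-groove,
interleaf leakage and the dual-stack offset of the physical MLC are not
modelled; the stack collapses into one effective aperture.

### Directed sampling

Photons are aimed at a sampling rectangle covering the aperture bounding
box plus a margin (default 15 mm), with solid-angle and angular-intensity
weights — the directional-splitting idea restated as importance sampling
of the emission direction. `dbs_config()` controls how many photons share
one sampled electron state. For central-axis quantities on broad fields
(output factors), a fraction of photons can additionally be aimed at a
small central rectangle with compensating weights (`focus_frac`,
`focus_mm`); this is unbiased by construction and is verified against
uniform aiming in the tests. The R-level `generate_bremsstrahlung()`
implements the classical splitting scheme (candidates at weight 1/n inside
a directed cone, Russian roulette outside) and carries the variance-
reduction unbiasedness test.

## Transport physics

**Photons** (50 keV – 7 MeV by default) undergo Compton scattering
(Klein–Nishina, free electrons), photoelectric absorption (the
photoelectron carries the full photon energy; binding neglected) and pair
production (flat energy partition; the positron annihilates at rest into
two back-to-back 511 keV photons). Free paths use Woodcock delta-tracking
with a per-energy majorant over the voxel palette, which is exact in
heterogeneous stacks without ray–voxel clipping. Rayleigh scattering,
Doppler broadening and atomic relaxation are omitted — sub-percent effects
for megavoltage dose.

**Charged particles** use condensed-history steps on the *exact
relativistic helix* for the uniform field: the step's spatial displacement
and direction update are the closed-form circular-arc solution for the
current momentum, so a cutoff-free electron in vacuum closes its orbit to
machine precision (this is a test). Step length is limited by a maximum
fractional energy loss (default 5 %), a maximum step (default half the
smallest voxel edge), and the residual range to the cutoff. Collision
losses use the unrestricted stopping power deposited at the chord midpoint
(no knock-on electrons are generated); radiative losses are subtracted and
discarded by default — a sub-percent local effect at 6 MV that buys a
large speed factor. Multiple scattering applies a Highland-formula
Gaussian deflection at each step end. The production threshold is
specified as a range cut (default 0.7 mm) and converted per material to an
energy cutoff by CSDA-range inversion.

Interaction data ship as packaged text tables on an 80-point log energy
grid (10 keV – 7 MeV), generated once from standard closed-form physics:
Klein–Nishina totals, a Z^4.5/E³ photoelectric fit anchored at the water
10 keV reference value, a Z(Z+1)-scaled pair-production shape anchored to
water reference values, Bethe collision stopping with the
Sternheimer–Peierls density effect, and a water-anchored radiative-loss
shape. The tests pin these against independent published anchors (water
μ/ρ at 1 MeV within 1 %, collision stopping at 1 MeV within 2 %, 6 MeV
CSDA range within 5 %). Media: water, ICRU-44 inflated lung
(0.26 g/cm³, configurable), ICRU-44 cortical and cartilage bone (the
`bone` alias defaults to cortical and is configurable — the appropriate
composition for a given planning system is genuinely ambiguous), and air.

### Energy bookkeeping

Every run closes an energy ledger: energy entering the phantom plus rest
mass returned by annihilation equals deposited + escaped + discarded
radiative + rest mass bound in pair production, to better than 10⁻⁶
relative. This audit is what caught the only silent-loss defect found
during development (a voxel-indexing edge case at the grid boundary).

### Random numbers and pairing

One master seed; per-batch, per-history and per-secondary streams are
derived from it by counter mixing. Runs are bit-reproducible. Because the
magnetic field never touches photon physics, a B-on/B-off pair sharing a
seed sees *identical photon histories* and identical per-electron
scattering deviates — the dose ratio R(d) then carries far less variance
than independent runs (verified in the tests). The same construction keeps
commissioning scans correlated across candidate parameters (common random
numbers).

## Scoring and metrics

Dose is scored per voxel (MeV/g per photon history) with uncertainties
from batch statistics (default 10 batches). Depth-dose curves are
normalized to their maximum (100 %); lateral profiles to the mean of their
three largest values. The comparison metrics are the standard
dose-validation set: mean/maximum absolute difference, a global 1-D gamma
index (dose difference normalized to the reference maximum; search window
±3× the distance criterion with 0.1 mm sub-sampling plus an exact local
refinement, which makes the implementation agree with a brute-force
minimization to 10⁻⁹), value-matching distance to agreement on the
penumbra region, the in-beam (>80 %) restricted mean difference, 80–20
penumbra widths, per-side half-maximum shifts, and the depth-dose
difference at 10 cm.

Numerical stabilizers, all recorded where used: build-up depths and
interface ratio extrema are taken after a 3-point moving average (an
argmax/max over noisy voxels is otherwise biased upward); penumbra
crossings on noisy Monte Carlo profiles use a 3-point smoothing
(`profile_edges(smooth = 3)`) because single-voxel noise creates spurious
level crossings that widen the apparent penumbra; output factors average a
small central region (radius 4 mm) rather than a single interpolated
point.

## Commissioning workflow

`run_parameter_scan()` reproduces the staged grid search: mean energy
(5.6–6.2 MeV in 0.2 MeV steps against a small-field PDD), then focal-spot
FWHM (0.5–2.0 mm against broad-field profiles), then energy-spread FWHM
(0–1.5 MeV). Selection is an explicit lexicographic filter — highest
pooled gamma pass rate, then lowest PDD mean absolute difference (energy
stage) or lowest pooled in-beam + maximum-difference rank (profile
stages), then lowest mean DTA, then smallest |ΔPDD₁₀|, ties toward the
middle candidate — with the surviving candidates recorded at each step so
deviations are auditable. All candidates in a stage share one master seed
(common random numbers), which is what makes sub-percent metric
differences meaningful at desk-scale histories.

The closed-loop recovery tests deserve honesty about what they show. At
10⁶–10⁷ histories the run-to-run noise of the normalized-PDD maximum is
about one percentage point, which exceeds the energy-stage
(~0.4 %/0.2 MeV) and spread-stage (~0.2 %) metric differences; a fully
independent reference would need roughly 10⁹ histories to resolve them,
which is cluster scale, not desk scale. The energy and spread closed loops
therefore generate the reference at the true parameters *with the scan's
shared seed* (the paired design): the truth candidate is then exactly
self-consistent and the other candidates differ by their parameter effect,
so the test verifies parameter wiring, metric computation and selection
logic — not statistical identifiability at commissioning-grade statistics.
The spot stage keeps a genuinely independent reference; it is made
resolvable by moving the effective collimation plane to 100 mm from the
target in the test geometry, which amplifies the spot-blur lever arm
eight-fold. Gamma pass rates over a desk-scale point count only resolve
differences of order their binomial standard error, so the selection
filter treats pass rates within two standard errors as tied — at
commissioning statistics the rates tie exactly and the tolerance is moot.
These are deliberate design choices of the test harness, not of the
engine.

## Experiment suite

* **Electron return effect** (`quantify_ere()`): paired B-on/off runs on a
  5 cm water / 3 cm lung / 5 cm water stack (SSD 85 cm), ratio of the two
  depth-dose curves, extrema within ±6 mm of the snapped lung interfaces
  (the window is a package choice; "near the interface" is not otherwise
  quantified). With the 0.35 T field the ratio peaks just inside the lung
  at about 1.10 for a 6.6 × 6.6 cm² field and about 1.06 at
  2.5 × 2.5 cm², with the complementary dip at the distal interface —
  the expected behaviour when the electron gyroradius (≈13.5 mm at 1 MeV)
  is comparable to the low-density region.
* **Beam-test bundle** (`run_mppg_suite()`): reference-field PDD +
  profiles, gantry 30°/330° profiles (the oblique dose grid keeps the
  phantom axis-aligned and resamples along the rotated axis), an off-axis
  aperture (the shipped example aperture approximates the published
  off-axis test, whose coordinates are not printed), and three
  heterogeneous templates. Template thicknesses are package assumptions:
  (a) water 50 / lung 50 / water 50 mm, chosen so the 8.5 cm profile plane
  lies *inside* lung — the crossline/inline penumbra asymmetry is an
  electron-range effect that exists only where the low-density medium is;
  (b) lung 50 / water 30 / lung 50 mm; (c) water 40 / lung 30 / bone 20 /
  water 60 mm with profiles at 13.5 cm. Because (a)–(c) are assumptions,
  the suite does not claim to reproduce published per-setup numbers that
  depend on the exact unpublished thicknesses (for example the in-lung
  build-up depths).
* **Output factors** (`run_output_factors()`): central-axis dose at 5 cm
  depth, SSD 85 cm, 2 mm voxels, paired B-on/off seeds, 9.9 cm reference
  field (the conventional nearest-deliverable reference; the published
  normalization field is not stated).

## Fixture generator

`generate_reference_dataset()` builds measured-like scans analytically —
depth doses as (1 − e^(−b·d))·e^(−μ·d) and profiles as error-function
edges with optional Gaussian noise. These fixtures exercise the metrics
and the tuner at zero Monte Carlo cost. They emulate the *shape* of
measured scans, not their physics: no energy spectrum, no detector volume
effects, no magnetic-field asymmetry. Tests that pass against fixtures
validate the analysis chain, not the engine; engine physics is validated
by the closed-form and statistical oracles above.

## Problem sizes and determinism of the validation suite

The bundled tests and the acceptance script run at 10⁵–3×10⁷ photon
histories per run with 3 × 3 × 2 mm³ voxels (2 × 2 × 2 mm³ for output
factors) — the package's desk-scale operating point, versus ~10⁹-history
cluster runs for commissioning-grade sub-1 % statistics. Stochastic
endpoints are asserted with tolerances that account for that scale:
benchmark bands of ±0.03 on the interface dose ratios, ±1.5 mm on the
penumbra asymmetry, ±2 points on the 10 cm depth doses, and
two-standard-error agreement for the output-factor field-on/off
comparison.

## Known limitations

* Highland Gaussian multiple scattering, no Goudsmit–Saunderson
  reconstruction: the principal fidelity gap in low-density media, where
  single-scattering detail matters below ~0.1 g/cm³. Lung at 0.26 g/cm³
  is within the model's comfort zone; air-gap dosimetry is not, and
  water–air interface enhancement is deliberately out of scope.
* No knock-on electrons or in-phantom bremsstrahlung re-emission: local
  energy deposition is slightly too compact; interface gradients are
  correspondingly a little sharper than a full transport code would give.
* Free-electron Compton and a power-law photoelectric fit: fine above
  ~100 keV, approximate below.
* The head is parameterized, so quantities that depend on real head
  detail — electron contamination, collimator scatter, tongue-and-groove
  effects, small-field output factors below ~2 cm — carry model, not just
  statistical, uncertainty.
* Uniform magnetic field only; fringe fields and field non-uniformity are
  out of scope, as are detector response models and planning-system
  comparisons.
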