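---
title: "Methods: kilovoltage contrast-enhanced radiotherapy simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kilovoltage contrast-enhanced radiotherapy simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kvcert)
```

`kvcert` simulates radiotherapy delivered with a kilovoltage CT-scanner
beam to a liver tumour that retains an iodinated embolic agent after
chemoembolization. This vignette is the package's own account of the
models inside it: what is computed, which parameters matter, which
conventions and approximations were chosen where several were defensible,
and what the test suite does and does not demonstrate.

## Photon interaction data

Everything rests on per-element tables of mass attenuation and mass
energy-absorption coefficients on a 1–150 keV grid
(`attenuation_table()`), shipped as TSV files and regenerable with
`data-raw/make-attenuation-tables.R`. The construction is deliberately
transparent:

* **Incoherent scattering** is the free-electron Klein–Nishina cross
  section times Z/A — exactly the kernel the transport engine samples, so
  tables and engine cannot drift apart.
* **Totals** for H, C, N (scaled from O), O, Al, Ca, Ti and I are
  anchored to standard published grids; K absorption edges (Al 1.56 keV,
  Ca 4.04 keV, Ti 4.97 keV, I 33.17 keV) appear as duplicated energy rows
  carrying the below- and above-edge branches.
* **Photoelectric vs. coherent split.** The non-incoherent remainder is
  split so that the derived `mu_en` column reproduces the classic
  water, air and aluminum energy-absorption anchors where those exist;
  elsewhere a smooth coherent-share model `R/(1+R)`,
  `R = 0.25 (8/Z)^1.3 (E/30 keV)`, is used. The photoelectric column
  therefore also absorbs the (small) electron-binding correction to
  Klein–Nishina; branch ratios are approximate at the few-percent level,
  which matters for nothing downstream except the channel-frequency
  tests, whose tolerances reflect this.
* **Trace elements** (F, Na, Mg, P, S, Cl, Ar, K — all minor mass
  fractions of tissue, bone and Teflon) interpolate the per-mole
  photoelectric component in ln Z between anchored neighbours. Values
  below ~8 keV are approximate and L edges are smoothed; photons there
  are absorbed within a fraction of a millimetre regardless.
* `mu_en = tau (1 - esc) + sigma_inc f_KN(E)`, where `f_KN` is the mean
  Klein–Nishina energy-transfer fraction (computed by quadrature) and
  `esc = omega_K E_Kalpha / E` above the K edge of a fluorescing element
  — the exact energy bookkeeping of the engine, so the collision-kerma
  tests close to within statistics.

Mixtures use Bragg additivity with log–log interpolation per element
(`mixture_mu()`); queries exactly on an edge take the above-edge branch by
default (`side = "below"` selects the other).

## Beam model

The tube spectrum (`generate_spectrum()`) is a semi-empirical tungsten
model: Kramers bremsstrahlung fluence `(kVp − E)/E` in 1 keV bins from
5 keV, plus the four tungsten K lines (58.0, 59.3, 67.2, 69.1 keV) at a
configurable 8% share of unfiltered fluence, filtered through titanium.
The scanner's true inherent filtration is unknown, and absolute output is
irrelevant because plans are renormalised to prescription — so the
titanium thickness is the *single* beam-quality calibration parameter,
bisected until the aluminum HVL matches the measured 9.4 mm
(`calibrate_inherent_filtration()`; 0.248 cm at default settings). The
HVL itself is the air-kerma-weighted narrow-beam transmission solving
`T(t) = 1/2`, an ionization-chamber surrogate, and the effective energy
inverts the aluminum total-attenuation table (coherent included — the
narrow-beam convention) at `ln 2 / (HVL rho_Al)`. With these conventions
the calibrated beam reproduces the measured beam-quality pair
(HVL 9.4 mm -> 61 keV) and the 9.2 mm measurement inverts to 59.8 keV,
within the 1-keV print precision of the quality index.

The bowtie filter is Teflon with only its centre (0.15 cm) and edge
(2.8 cm) thicknesses known; between them we take the simplest smooth even
profile, quadratic in fan angle over a 22° half fan, exposed in
configuration. The off-center ratio (`off_center_ratio()`) attenuates
each ray by the slant bowtie path and the inverse square distance —
normalised to the axis, so only the profile shape matters.

## Synthetic phantom

`build_synthetic_abdomen()` replaces an anthropomorphic phantom CT (not
distributed with any data source) by a parametric abdomen: an elliptic
soft-tissue body (16 × 11 cm semi-axes), a liver ellipsoid in the right
abdomen, a posterior vertebral column with a central cord canal, two
kidneys, and a 3 cm spherical GTV centred in the liver, on an isotropic
grid (3 mm default, 1–5 mm supported). Organ HU values carry Gaussian
texture noise (sigma = 10 HU); the GTV HU comes from the concentration
calibration. The PTV is the GTV dilated by 5 mm.

Choices worth stating:

* **Margin expansion** (`expand_margin()`) dilates between voxel centres
  with a half-voxel compensation, so that dilating a voxelised sphere
  approximates dilation of the continuous sphere (a pure centre-to-centre
  ball under-reaches diagonals by ~10% in volume at 3 mm voxels).
* **Material override**: GTV voxels are assigned the iodinated mixture
  regardless of HU — iodine dispersed in soft tissue with volume-additive
  density `rho(c) = rho_base + c/1000` and iodine mass fraction
  `(c/1000)/rho(c)`. A display convention of flagging the region with an
  arbitrary very high HU would corrupt the density map if taken
  literally, so the dosimetric assignment always goes through the
  composition, never through a flag HU.
* **Clinical surrogate**: `sample_patient_gtv_hu()` draws from a normal
  distribution truncated to the clinically observed [376.2, 1653] HU with
  mean 864.7 HU and sigma = 320 HU. The spread is a judgement call (the
  source distribution is only summarised by min/mean/max); it emulates
  between-voxel variability for demos and tests, not patient-level
  statistics.
* What the generator does **not** emulate: real organ shapes and HU
  textures, heterogeneous Lipiodol uptake within the tumour, breathing
  motion, beam-hardening artefacts. Tests passing on this phantom
  demonstrate the pipeline's internal correctness and the physics of
  enhancement, not clinical dosimetry for any patient.

## Monte Carlo engine

`run_simulation()` transports photons on the voxel grid by Woodcock
(delta) tracking against an energy-dependent majorant, so no
voxel-boundary crossings are ever computed. Physics, in the kilovoltage
regime:

* photoelectric absorption; for absorbers with Z >= 20 and photons above
  the K edge, a single K-alpha line (iodine: 28.6 keV) is emitted
  isotropically with probability equal to the K fluorescence yield
  (0.884 for iodine) and transported; the remainder deposits locally;
* incoherent scattering from free electrons, sampled by
  composition-rejection from the Klein–Nishina kernel; the electron
  deposits locally;
* coherent scattering redirects with the Thomson angular law (no form
  factors — a flagged approximation worth ~1–2% on broad-beam dose);
* electrons are never transported: their CSDA range below 120 keV is
  under 0.2 mm, far below the voxel size, so dose equals collision kerma.

Cross sections reach the engine as per-material lookup tables on a
uniform 0.25 keV grid (nearest-bin lookup; the iodine edge is smeared by
at most one bin). Photons falling below the 1 keV cutoff are terminated
with their residual energy booked in a separate *discarded* audit bucket,
so `emitted = deposited + escaped + discarded` holds to 1e-6 per batch —
a tested invariant. Runs are single-threaded and bitwise reproducible for
a fixed seed (PCG32; batch seeds derived by fixed offsets).

Batch statistics follow the usual recipe: the run is split into
`n_batches` (default 10) equal batches; the per-voxel relative standard
error comes from the batch-to-batch variance. The headline precision
statistic is the maximum relative SE over voxels above 50% of the maximum
dose, evaluated over tissue-like voxels (density >= 0.5 g/cm^3): in
near-zero-mass air voxels a single interaction produces an enormous
dose-to-air spike, which would otherwise define "maximum dose" and make
the statistic meaningless. With `uncertainty_target` set, whole run
increments are added (fresh derived seeds) until the statistic reaches
the target.

Two benches replicate the validation experiments. The HVL bench
(`simulate_hvl_bench()`) offers an analytic mode (spectrum-weighted
Beer–Lambert) and a transport mode (primary-only pencil beam through an
aluminum slab, never-scattered photons tallied with air-kerma weighting);
both agree within statistics, which checks the Woodcock tracker against
closed-form attenuation. The enhancement bench
(`simulate_enhancement_bench()`) places a contrast layer (iodinated water,
default 3 cm) behind 4.8 cm of PMMA at 15 cm SSD and runs the identical
geometry twice — contrast vs. plain water, same seed — reporting
`100 (D_c/D_w − 1)` along the central axis. We report the *relative
increase*; readers preferring the dose-enhancement *ratio* add 100
percentage points. The agent is read as iodine at the stated mg/mL (an
iodinated aqueous agent), not as mg of whole oil formulation.

## Planning and DVH conventions

`make_arc_plan()` approximates continuous CT rotation by 36 equispaced
gantry angles (configurable; the angular discretisation error is below
the statistical noise at default settings), each a point source at
62.56 cm from the isocenter (the GTV centroid) with a rectangular
aperture equal to the projected PTV bounding box plus a 0.5 cm margin.
Beam weights are equal — this models simple collimated rotational
delivery, not inverse-optimised planning. `compute_plan()` scales the
accumulated grid so D95% of the GTV equals the 40 Gy prescription
(a configuration switch allows prescribing to the PTV instead; the
rotational-delivery convention here prescribes to the GTV).

DVH metrics use voxel-centre doses with equal voxel volumes. `Dx%` is the
midpoint-interpolated percentile of the descending dose distribution
(ties toward the higher dose); `Dxcc` accumulates voxel volumes in
descending dose order and returns the dose of the voxel that completes
the requested absolute volume, so a single 0.1 cc hotspot voxel defines
D0.1cc exactly. `VxGy` is reported as percent of structure volume (the
fractional-volume convention); the cumulative curve uses 0.05 Gy bins by
default. All metrics are verified against brute-force sort-based oracles
to 1e-9 on a thousand random grids.

The organ-at-risk constraint table shipped by `default_constraints()`
contains conventional working limits for a 40 Gy / 4 fraction schedule
and is explicitly non-authoritative; `check_constraints()` treats a
metric exactly at its limit as passing.

## Behaviour of the concentration sweep

`concentration_sweep()` reruns the full pipeline over 10–50 mg/mL with a
shared phantom and seeds. Two robust findings from the test suite: the
tumour D2% rises with concentration and exceeds 130% of the prescription
at 50 mg/mL, and every normal-liver metric (V5Gy, V20Gy, Dmean) falls
monotonically — the selectivity that motivates the method. One caveat the
package states openly: with the prescription pinned to D95% — the cold
tumour core under rotational kV delivery — every higher percentile is a
ratio of arc-averaged attenuation factors, and self-shielding grows with
iodine concentration; in a uniformly filled spherical tumour the
normalised median dose (D50%) therefore *rises* gently with
concentration. A reported decrease of D50% under these exact conditions
is not reproducible in this geometry; the corresponding ordering check in
the acceptance suite documents this honestly rather than adjusting the
phantom until it passes.

## Problem sizes and numerical settings

Defaults were chosen once, as desk-scale study conditions: 3 mm voxels
(about 5.4e5-voxel grids) for production runs and 4.5 mm for the
statistics and sweep studies; 1e7 histories for the headline arc run;
2.5e7-history increments for the 1%-precision stopping rule (reaching the
target around 1e8 histories); 5e6 histories per arm for the enhancement
bench; 10 batches everywhere. The test suite uses smaller counts with
tolerances set from the batch SE, never the other way around.

## Known limitations

* Cross sections are authored from anchor grids, not a certified
  database; they are accurate at the percent level in the 20–120 keV
  window that matters here and cruder below 8 keV.
* No electron transport, no Doppler broadening or binding in incoherent
  scattering, no atomic form factors in coherent scattering, single-line
  fluorescence without cascades.
* No heel effect, focal-spot blur, detector model or helical pitch in the
  scanner model; tube current and thermal loading are out of scope.
* The phantom is parametric; absolute organ-at-risk doses depend on the
  invented anatomy and must not be read as clinical predictions.
* Megavoltage comparison plans are out of scope by design.
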