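---
title: "Choriocapillaris OCTA under drusen: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choriocapillaris OCTA under drusen: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccocta)
```

## The question the pipeline addresses

OCT angiography (OCTA) detects blood flow by acquiring repeated B-scans at
each location: moving erythrocytes decorrelate the speckle pattern between
repeats, static tissue does not. Because voxels with very low OCT signal
produce large, unreliable decorrelation values, OCTA pipelines zero every
voxel whose OCT signal falls below a threshold. That thresholding creates an
interpretive ambiguity: a dark region on an en face OCTA choriocapillaris
(CC) slab can mean absent flow, absent OCT signal, or both.

Underneath drusen this matters clinically. Drusen and the overlying RPE
attenuate short-wavelength (~840 nm) light much more strongly than
longer-wavelength (~1050 nm) light, and spectrometer-based (spectral-domain,
SD) detection additionally loses sensitivity with depth ("roll-off"),
whereas swept-source (SS) detection does not. A shorter-wavelength SD device
can therefore show OCTA signal loss under a druse that is purely a shadowing
artifact — *false-positive flow impairment* — while a longer-wavelength SS
device imaging the same eye shows intact flow.

`ccocta` rebuilds this comparison end to end on synthetic data: a digital
macular phantom, a physics-level simulation of both device classes,
decorrelation angiography with OCT-signal thresholding, en face CC slab
projection referenced to Bruch's membrane (BM), and an automated version of
the clinical grading (none / ambiguous / unambiguous signal loss, with
cross-device false-positive flags).

## The phantom

The phantom is a 3 × 3 mm macular field sampled on a 192 × 192 lateral grid
with 320 axial samples at 3 µm pitch, depth increasing away from the
instrument (zero-delay at the top of the frame, as under the vitreoretinal
protocol). Layers, top to bottom: vitreous, retina, RPE, (druse), CC,
choroid. BM is a flat plane; each druse is a parabolic dome
`h(r) = height * max(0, 1 - (2r/diameter)^2)` that lifts the RPE off BM,
with druse material filling the gap — the anatomy of soft drusen, which sit
between the RPE and BM. A Gaussian dome is available via the config.

Geometry defaults (all configurable): ILM at 540 µm, BM at 760 µm, RPE
15 µm thick, CC layer 60 µm thick directly below BM so that the standard
30–60 µm sub-BM slab window lies inside it. The default drusen are three
analysis-eligible soft drusen (diameters 300/250/220 µm, heights
120/105/90 µm) plus one 160 µm druse that falls below the ≥ 165 µm
eligibility criterion used for grading. Heights in the 90–120 µm range are
typical of large soft drusen; lateral size, not height, defines
eligibility.

Flow lives only in the CC layer as a lateral erythrocyte-speed map,
2 mm/s by default (capillary-range speed). Scenarios: `uniform`,
`voids_under_drusen` (true flow deficits co-located with drusen), and
`voids_elsewhere`.

## Device presets

| | SD840 | SS1050 |
|---|---|---|
| center wavelength | 840 nm | 1050 nm |
| A-scan rate | 70 kHz | 400 kHz |
| repeats per location | 2 | 5 |
| native grid | 304 × 304 | 500 × 500 |
| interscan time Δt | ~5 ms | ~1.5 ms |
| axial resolution | ~5 µm | ~8–9 µm |
| 6-dB roll-off depth | 600 µm | ∞ |

Simulation runs on the phantom grid; the native grids are metadata. The
roll-off model is a Gaussian amplitude sensitivity
`exp(-ln 2 (z/z6)^2)` — 1 at the zero-delay, 1/2 at `z6`. The 600 µm SD
default expresses that spectrometer detection loses several dB over the
depth of the choroid under the vitreoretinal protocol; SS detection is
modeled as roll-off-free over this range. Both values are preset fields.

## Optical model

Per-voxel noise-free mean amplitude is
`reflectivity(tissue) × exp(-2 ∫ µ ds) × sensitivity(z)` — single-scatter
Beer–Lambert with round-trip attenuation, integrated exactly over the
piecewise-constant tissue segments of each A-scan.

Default coefficients (1/mm):

| tissue | reflectivity | µ(840) | µ(1050) |
|---|---|---|---|
| vitreous | 0.0 | 0 | 0 |
| retina | 0.2 | 1.0 | 0.8 |
| RPE | 1.0 | 12.0 | 3.0 |
| druse | 0.4 | 12.0 | 2.0 |
| CC | 0.6 | 2.0 | 1.5 |
| choroid | 0.5 | 2.0 | 1.5 |

The table encodes ordering, not tissue spectroscopy: what matters for the
mechanism is that (i) RPE/druse attenuation at 840 nm is several-fold
higher than at 1050 nm, and (ii) the *excess* round-trip loss that a large
druse adds at 840 nm (≈ 2 × (µ_druse − µ_retina) × height ≈ 2.6 nepers
≈ 23 dB for a 120 µm druse apex, since druse material displaces retina
along the A-scan) is severe enough to push the sub-druse CC signal below
the OCTA threshold, while the corresponding 1050-nm excess (≈ 2.5 dB) is
mild. With weaker druse attenuation the sub-druse CC amplitude at desk
scale stays well above the µ + 2σ threshold and the masking artifact —
which is the observed clinical phenomenon — never occurs; the defaults were
chosen once so that the artifact appears on SD840 and not on SS1050, and
every value is exposed in the config.

## Speckle, flow decorrelation, and noise

Each voxel-repeat amplitude is the modulus of a circular complex Gaussian
field (fully developed speckle), scaled so its expectation equals the mean
amplitude above. Between consecutive repeats the field evolves as an AR(1)
mixture `g' = a g + sqrt(1 - a²) w`. The *amplitude* correlation across one
interscan interval is set to `ρ(v) = exp(-(v Δt / L_c)²)` with
`L_c = 10 µm`: the mixing coefficient `a` is obtained by inverting the
closed-form Rayleigh envelope-correlation relation (a hypergeometric series
in `a²`), so the stated ρ holds on the amplitudes themselves rather than on
the underlying fields — the distinction matters because envelope
correlation ≈ (field correlation)², and tests assert the amplitude-level
value. Static tissue has `a = 1`; with noise off its repeats are
bit-identical.

The noise floor is additive in the complex field, with scale chosen so that
signal-free voxels have Rayleigh-distributed amplitude of scale
`noise_floor` (0.02 by default, in normalized amplitude units). This keeps
the vitreous an exact Rayleigh sample (used both by the threshold
calibration test and as the default noise-estimation region) and
reproduces the real phenomenon that low-SNR voxels decorrelate spuriously —
precisely the voxels the threshold is meant to remove.

At Δt = 5 ms and v = 2 mm/s, `v Δt / L_c = 1`, so the SD repeat-pair
amplitude correlation in flowing CC is `e^-1`; the SS device's shorter
1.5 ms interval gives weaker per-pair decorrelation, traded against five
repeats instead of two.

## Angiography and thresholding

The decorrelation statistic is the unsplit pairwise form

D = 1 − (1/(R−1)) Σₙ AₙAₙ₊₁ / (½(Aₙ² + Aₙ₊₁²)),

applied identically to both devices (the commercial SD device's split-
spectrum processing is proprietary; using one formula for both isolates
the wavelength/roll-off physics, at the cost of not reproducing the SD
device's display processing). A 0/0 pair contributes decorrelation 0 —
empty signal must not fabricate flow.

Noise is estimated as the sample mean and SD of the mean-over-repeats
amplitude in the vitreous (everything at least two axial pixels above the
ILM), and the threshold is `T = mean + 2 SD`. Voxels with mean OCT
amplitude strictly below `T` are zeroed and recorded in a mask; a value
exactly at `T` is retained.

## Slabs and segmentation

En face CC slabs are mean projections of the flattened volume from 30 to
60 µm below BM. Index convention (fixed for bit-reproducibility): BM pixel
index `round(bm/pitch)`, offsets `ceil(offset/pitch)`, half-open window —
exactly 10 samples at 3 µm pitch. Ground-truth BM is the default reference
in tests, removing segmentation error as a confounder. The estimated mode
mimics the clinical automatic segmentation: per A-scan, the brightest peak
(RPE band) is found and BM is placed at the lower edge of the strongest
amplitude drop at or below that peak, then median-filtered laterally
(5-pixel window). Under a druse this follows the elevated RPE bottom rather
than true BM — the same failure mode that forces manual adjustment of
clinical segmentations — and deviations are flagged against ground truth
when available.

## Automated grading

Human readers judged "low signal" qualitatively; the automatic reader makes
that explicit with two parameters: a slab pixel is low when below
`k ×` median of the background (all slab pixels outside every druse
footprint, eroded 2 px), and an ROI is low-signal when at least a fraction
`f` of its pixels are low. Defaults `k = f = 0.5`. Raising `k` is monotone:
it can only add low pixels, never remove them.

Per druse and device: loss = low OCTA; ambiguous = low OCTA with low OCT
(masking cannot be excluded); unambiguous = low OCTA with preserved OCT
(interpretable as true flow alteration). False-positive flow impairment on
one device = ambiguous loss there with *no* OCTA loss on the other device.
Cohort tallies use the printed conventions: loss percentage over all
drusen, class and false-positive percentages over that device's losses,
rounded half-up to one decimal.

The published per-druse grades are not available, only the tallies; the
package ships one synthetic 23-row assignment
(`inst/extdata/drusen_cohort23_synthetic.csv`) consistent with every
printed count simultaneously. Interreader agreement is computed as percent
agreement and Cohen's κ between two reader parameterizations; the clinical
κ of 0.957 cannot be recomputed because its denominator (images, drusen, or
druse × device) is not stated, so it is not asserted anywhere.

## Problem sizes and runtime choices

The default desk-scale grid is 192 × 192 × 320 (3 µm axial pitch), chosen
so a full two-device simulation-to-grading run completes in about a minute;
unit tests use 48–96 pixel lateral grids and the full axial range.
Innovation fields are drawn only for flowing voxels (static speckle carries
over unchanged), which is exact and removes most of the random-number cost.
Monte-Carlo checks (pair correlation, threshold calibration) use 10⁴–10⁵
voxels with tolerances set from their sampling error.

## What the synthetic data does and does not show

The generator reproduces the *mechanism*: wavelength-dependent attenuation,
SD roll-off, speckle decorrelation, thresholding, and their interaction
under dome-shaped drusen. It omits eye motion and motion correction,
projection artifacts from overlying retinal vessels, RPE clumping,
anatomical sublayers, the foveal pit, SSADA spectral splitting, and the
commercial device's display transfer function. Passing tests therefore
demonstrate that the pipeline's physics and grading logic produce the
artifact pattern for the stated reasons — not that the simulation is
calibrated to any particular hardware. The simulated cohort percentages
depend on the invented druse population and reader parameters; the exact
published tallies are reproduced from the grading table, not claimed to
emerge from the simulation.

## Degenerate inputs and numerical conventions

Zero-druse phantoms are valid (flat RPE). Drusen whose footprint leaves the
field, negative geometry, empty noise regions, empty ROIs or backgrounds,
R < 2 repeats, and slab windows leaving the volume all raise errors naming
the problem. All randomness flows from explicit integer seeds;
`run_study()` derives one sub-seed per device from its root seed, and
identical seeds give bit-identical volumes, grades and summaries.
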