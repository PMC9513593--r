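---
title: "Lutetium-background transmission attenuation correction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lutetium-background transmission attenuation correction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

LYSO scintillation crystals contain natural ${}^{176}$Lu, which decays by
$\beta^-$ emission followed by prompt gammas at 307, 202 and 88 keV. The beta
deposits its energy in the host crystal; the 307 keV photon can traverse the
patient and be detected by an opposing crystal. Each such coincidence is a
transmission measurement through the body at 307 keV, available for free and
simultaneously with the PET emission acquisition. On long-axial-FOV scanners
the crystal volume (hence the background flux) and the solid-angle coverage
are large enough that the background becomes a practical transmission source
for estimating the 511 keV attenuation map ($\mu$-map) needed for attenuation
correction (AC) — particularly attractive for ultralow-dose scans where the
CT dose would dominate.

`lutran` implements this measurement chain at desk scale: a parametrized
cylindrical scanner with the maximum-unit-difference (MUD) coincidence
policy, a synthetic voxelized torso phantom, an expected-count Poisson
simulator for blank/transmission/TOF-emission sinograms, penalized MLTR
reconstruction of $\mu$, TOF-OSEM reconstruction of activity, the joint
MLAA-TX estimator, and the quantification metrics used to evaluate them.

## Models

### Scanner geometry and coincidence policy

The scanner is a cylinder of ring diameter $D$ (default 786 mm) with
$N_u$ axial units of length $L_u$ (default 8 × 242.5 mm = 194 cm). A finite
MUD $m$ accepts a coincidence only when the two crystals' units differ by at
most $m$; the most oblique accepted line of response (LOR) then spans
$(m{+}1)L_u$ axially, giving a maximum acceptance angle
$\theta_{\max} = \arctan\!\big((m{+}1)L_u / D\big)$ (57° for MUD 4; 51° and
17° for the unrestricted 4-unit and 1-unit geometries). Sinogram bins are the
unordered FOV-crossing transaxial crystal pairs crossed with (optionally
mashed) ring pairs inside the acceptance window; the bin mapping is exactly
invertible up to mashing.

### System model

Projections use Siddon ray tracing with exact voxel-intersection lengths.
LOR endpoints are the crystal front-face centers pushed radially into the
crystal by the depth-of-interaction (DOI)

$$d(Y) = -\ln\!\big(1 - Y\,(1 - e^{-\eta\mu_{\mathrm{LYSO}} D_c})\big) /
(\eta\mu_{\mathrm{LYSO}}),$$

the inverse-CDF of an exponential interaction profile truncated at the
crystal length $D_c = 18.1$ mm, with $\mu_{\mathrm{LYSO}} = 0.0815$ mm$^{-1}$
and the fixed quantile $Y = 0.6$ (≈7.6 mm at 511 keV, ≈7.0 mm at 307 keV);
per-event random sampling of $Y$ is available but off by default. The
$\mu$-map is stored at 511 keV everywhere; all 307 keV physics goes through
the single energy-scale factor $\eta = 1.2276$
($\mu_{307} = \eta\,\mu_{511}$), a linear tissue fit that is also used by the
transmission system matrix. TOF-resolved projection spreads each voxel's
contribution over time bins with a Gaussian kernel of FWHM equal to the
coincidence timing resolution (430 ps), centered at $t = 2u/c$ for a voxel at
signed arc length $u$ from the LOR midpoint, truncated at ±3σ and
renormalized to unit mass so marginalizing over TOF reproduces the non-TOF
projection. The kernel is tabulated over the fractional bin offset (256
steps, ≈1 ps granularity), which keeps forward and back projection exactly
adjoint.

### Simulator

Instead of photon tracking, the simulator draws Poisson counts from
expected-value models:

* **Blank**: per-LOR rate = beta-trigger rate of one crystal (calibrated
  against 92.2 cps per cc of LYSO) × the 307 keV emission probability ×
  the opposing crystal's solid angle with obliquity × its intrinsic
  absorption and energy-window survival, both orderings summed. A global
  exposure factor scales the physical rate to desk-scale count targets and
  is recorded with every data set.
* **Transmission**: blank expectation × $\exp(-\eta\int\mu\,dl)$ for the
  unscattered category. In single-scatter mode, photons removed from the
  primary beam receive one Klein–Nishina-sampled scatter vertex; the
  scattered energy goes through the Gaussian resolution model
  (fractional FWHM $0.117\sqrt{511/E}$) and the gamma window (250–350 or
  290–350 keV), and survivors are recorded as a separate category. Emission
  contamination of the transmission window carries a body-origin TOF and is
  filtered by the per-LOR threshold (crystal-to-crystal transit time minus
  500 ps). Categories are stored separately so "no scatter" data are exact
  subsets. Randoms are never generated.
* **Emission**: TOF-resolved forward projection of the activity map,
  attenuated at 511 keV, scaled by duration, the time-integrated F-18 decay
  factor and the emission exposure factor.

### Reconstruction

* **MLTR** maximizes the Poisson transmission likelihood with a quadratic
  26-neighbour roughness penalty (inverse-distance weights) using additive
  separable-quadratic-surrogate (SQS) updates. The per-LOR curvature is the
  standard precomputed optimal curvature
  $c = 2\,[h(0) - h(Z) + Z h'(Z)]/Z^2$ of the transmission negative
  log-likelihood (Newton curvature at $Z=0$), floored at a small ε: the
  design contract is the monotone-descent property, which the tests assert,
  not a particular curvature formula. Subset data terms are scaled by the
  subset count so the penalty balance matches the full objective, and every
  update ends with a non-negativity clamp. Initialization is zero.
* **TOF-OSEM** is the classical multiplicative update with the expected
  counts model $a_i n_i\, c\, \sum_j p_{itj}\lambda_j + s_{it}$; the
  calibration $c$ (duration × decay × exposure) makes the reconstruction
  come out directly in kBq/ml. A voxel invisible to a given subset is left
  unchanged by that subset.
* **MLAA-TX** interleaves one OSEM activity pass with several SQS
  attenuation passes whose numerator combines the emission surrogate
  derivative with the $\alpha$- and $\eta$-weighted transmission term;
  initialization is the regularized MLTR map. The emission chain-rule term
  uses the 511 keV system matrix and the transmission term the 307 keV one
  (the printed update collapses both onto the transmission matrix; the two
  differ only in the DOI depth). $\alpha = 0$ degenerates to emission-only
  attenuation updates, and because $\alpha$ scales only the likelihood, the
  large-$\alpha$ limit is the *unpenalized* transmission problem.

### Body-contour masking

The non-negativity clamp makes the reconstructed air around the body carry
one-sided (positive) noise; integrated along lines that traverse a lot of
air — through the neck most of the in-FOV path is air — this inflates the
attenuation correction by several percent. Before a $\mu$-map is used for
AC it is therefore masked to the body contour: smooth (σ = 2 voxels),
threshold at 0.003 mm⁻¹, take the connected body component, seal thin
surface channels by morphological closing, and refill internal
low-attenuation cavities (lungs) by a slice-wise background flood from the
transaxial grid boundary (cavities are ringed by tissue in every transaxial
plane, outside air is not). The mask is a standard element of
transmission-based AC chains; `run_lu_ac_study(mask_support = FALSE)`
disables it.

### Quantification

NRMSE divides the RMSE against ground truth by the evaluated image's own
value range (a configuration switch offers the conventional
ground-truth-range form). SSIM uses unit exponents on the luminance,
contrast and structure terms, a 3D Gaussian window of σ = 1.5 voxels and
constants $C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$, $C_3 = C_2/2$ with $L$ the
ground-truth range; the implementation is pinned against an independent
reference implementation in a unit test. Voxel bias is
$(x - \check{x})/\check{x}$; VOI statistics pool the voxels of each organ
group's spherical VOIs and report boxplot summaries (whiskers at 1.5 IQR),
with the headline number the maximum over organs of the absolute mean.
Lesion SUVmax is the maximum voxel inside the lesion sphere dilated by one
voxel (per image; the location may differ), compared against the
ground-truth map and against the OSEM reconstruction that used the true
$\mu$-map. Water-peak scaling searches a smoothed histogram
(2×10⁻⁴ mm⁻¹ bins) for the soft-tissue mode inside
[0.007, 0.012] mm⁻¹ and rescales the map globally.

## Desk-scale study conditions

All heavyweight studies run on a reduced crystal lattice that preserves the
ring diameter, the unit structure and the MUD semantics: 120 crystals per
ring (transaxial pitch ≈ 20.6 mm) and 8 rings per unit (axial pitch
≈ 30.3 mm), with no axial mashing — the coarse lattice already provides the
effective sampling the full-size scanner reaches after mash-3, scaled by
roughly 2.5×. LORs are restricted to the support cylinder around the phantom
(radius 100 mm), which discards bins that never see the object. The phantom
is 48 × 48 × 180 voxels at 4 mm (the reconstruction voxel size of the
full-scale study).

Count levels are set by one exposure factor per chain, recorded in every
data set: the 20-min blank is scaled to 2×10⁷ expected counts (object
transmission scans then land in the 10⁶–10⁷ range) and the 20-min emission
scan to 1.4×10⁷ counts, which matches the full-scale study's counts per
resolution element (a few hundred to ~10³) so that noise per resolved
feature is comparable even though the absolute count is four orders of
magnitude smaller.

The phantom emulates a torso at organ level: body and neck cylinders, a
skull shell with brain, two lungs, liver, a left-ventricle blood pool inside
a myocardial shell, a spine with marrow core, hip bones with marrow cores
and a hot bladder; 22 activity-only spherical lesions (8–12 mm, contrasts
2.4–24: 5 liver, 3 per lung, 4 pelvic, 4 neck, 3 brain) and 23 spherical
VOIs grouped into the analyzed organs (lungs, liver, LV blood pool,
cerebrum, skull bone, hip bone, hip marrow, bladder, soft tissue).
Compartment sizes are chosen at least ~2.5× the desk-scale sampling
distance — in particular the skull (24 mm thick), the LV blood pool
(24 mm radius) and the hip marrow cores (≥ 24 mm radii, offset inside the
bone so a pure-bone region remains) — so that the ±10% organ-bias bound
under test reflects the attenuation-correction chain rather than partial
volume of sub-resolution structures, mirroring the full-scale study where
analyzed organs are large against that scanner's resolution. Lesions keep
their physical 8–12 mm diameters and are therefore *below* the desk-scale
resolution; their SUVmax statistics carry correspondingly more noise than
the full-scale counterparts (see Limitations).

## What the generator emulates, and what it does not

The simulator reproduces the count statistics, energy-window selection, TOF
discrimination, acceptance-angle/policy geometry and attenuation physics of
the measurement chain, which is what the reconstruction and quantification
methods consume. It does not model inter-crystal scatter or penetration,
detector dead time or pileup, randoms (discarded by construction), multiple
scatter or object fluorescence (the single-scatter model has one
Klein–Nishina vertex per removed photon and keeps the event on its original
LOR), block structure, or anatomical realism beyond organ-level primitives.
Passing tests therefore demonstrate the correctness and the quantitative
behaviour of the algorithms under the stated conditions, not clinical
performance on real data.

## Numerical choices and degenerate inputs

Voxel-center inclusion rasterizes spheres and organs (exactly testable;
no anti-aliasing). Transmission bins with zero blank counts are excluded
with a warning. $H'$ is evaluated as $y\,(\bar{b}/\bar{y}) - \bar{b}$ so it
stays finite when the predicted count underflows; the Newton curvature at
$Z = 0$ guards the $(B+r)^2$ denominator. The curvature floor is
ε = 10⁻⁸. OSEM ratios treat $\bar{y} \le 0$ bins as zero contribution.
The water-peak search returns factor 1 with a warning when no mode lies in
the search window. Subset order is a fixed seeded permutation of the
equidistant-in-angle subsets.

Two desk-scale deviations from idealized behaviour are documented here
because the tests encode them: ordered subsets at this angular sampling
(12 angles per subset) leave a voxelwise limit cycle of order 20% relative
RMS against matched MLEM on noiseless data, while the quantitative readouts
(VOI means, totals) agree to ~1%; and noiseless uniform-cylinder recovery to
1% in a central VOI needs ~50 MLEM-equivalent iterations rather than 30.

## Open design choices

* The acceptance angle uses the ring diameter as the adjacent side
  (reproduces all three printed angles); rounding to integer degrees is a
  reporting convention only.
* The quadratic penalty acts on $\mu$ at 511 keV (not on
  $\mu_{\mathrm{tran}}$); with the fixed $\eta$ the two differ only by a
  constant factor absorbed into $\beta$.
* The DOI formula with uniform $Y$ is read as the inverse-CDF sampler of the
  truncated exponential; $Y = 0.6$ is the fixed quantile used by default.
* MLTR initializes at zero; MLAA-TX at the regularized MLTR map.
* Multi-bed protocols reconstruct jointly with bed-summed sensitivity
  (per-bed reconstruction with overlap-weighted averaging is available as a
  switch); the 24-cm protocol uses abutting beds.
* SSIM is 3D and windowed; boxplot whiskers use the 1.5 IQR convention.

## Known limitations

* Organ-activity recovery at 30 MLEM-equivalent iterations retains
  convergence-dependent bias in low-uptake compartments; the skull, lying
  against the hot brain, carries the largest residual (~−10%) even with
  ground-truth AC.
* Lesion SUVmax at desk scale is a maximum over a noisy, sub-resolution
  neighbourhood: low-contrast 8–10 mm lesions show per-seed SUVmax
  fluctuations of ±10–20% between two reconstructions of the same data, an
  order larger than at full scale. Seed-averaged per-lesion biases are the
  stable readout.
* The crosstalk artifact of joint estimation reproduces in magnitude
  ordering (strongest at low transmission weight and early iterations) but
  its sign under desk conditions is overestimation rather than the
  underestimation seen at full scale.
* The single-scatter model is qualitative: it reproduces the
  scatter-induced underestimation of $\mu$ and the benefit of the 290 keV
  threshold, not quantitative scatter fractions.

## A worked run

```{r}
library(lutran)

ph <- default_phantom(seed = 1)
setup <- desk_setup(ph, "uexplorer")
st <- run_lu_ac_study(ph, setup, seed = 1)

st$mu_report            # NRMSE/SSIM and per-organ mu bias
st$activity_report      # same for the attenuation-corrected activity
st$lesions              # per-lesion SUVmax bias against both references
```

The config-driven sweeps (`run_experiment`) reproduce the acceptance-angle,
scan-duration, geometry, weighting-factor and scatter/threshold studies; the
thin CLI in `inst/cli/lutran.R` drives them from a shell.
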