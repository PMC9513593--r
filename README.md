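# lutran

Desk-scale simulation and reconstruction framework for **lutetium-background
transmission attenuation correction** in long-axial-FOV PET.

LYSO-based PET scanners carry an intrinsic radiation source: ¹⁷⁶Lu in the
crystals decays by β⁻ emission with a prompt 307 keV gamma. The beta tags
the emitting crystal; the gamma traverses the patient and is detected
opposite — a free transmission measurement acquired simultaneously with the
PET scan. On total-body scanners the background flux and solid angle are
large enough to reconstruct the 511 keV attenuation map (μ-map) from this
data alone and use it for attenuation correction (AC) of ultralow-dose
scans, removing the CT from the dose budget.

`lutran` implements the full measurement and estimation chain for
scientists studying this method:

* **Geometry** — parametrized cylindrical scanner with axial units and the
  maximum-unit-difference (MUD) coincidence policy; acceptance-angle math
  (`arctan((MUD+1)·L_unit / D_ring)` → 57°/51°/17° for the 194-cm, 1-m and
  24-cm geometries), invertible sinogram binning with axial mashing, per-LOR
  TOF thresholds, multi-bed protocols.
* **Phantom** — synthetic voxelized torso (organs, 22 spherical lesions of
  8–12 mm at contrasts 2.4–24, 23 spherical VOIs) with ground-truth μ- and
  activity maps; NIfTI import/export.
* **Simulation** — expected-count Poisson models for blank, transmission
  (with optional Klein–Nishina single scatter and TOF-gated 511 keV
  contamination) and TOF emission sinograms; energy-window and timing
  models; component-based normalization.
* **Reconstruction** — penalized MLTR with separable quadratic surrogates
  (SQS) for μ; TOF-OSEM for activity; joint MLAA-TX with a transmission
  weight α. Projectors are on-the-fly Siddon ray tracers (Rcpp) with a
  depth-of-interaction endpoint model and the 307/511 keV energy scale
  η = 1.2276.
* **Quantification** — NRMSE, 3D Gaussian-windowed SSIM, voxel bias, VOI
  boxplot statistics, lesion SUVmax bias against two references, water-peak
  μ rescaling.
* **Experiments** — config-driven drivers for the acceptance-angle,
  scan-duration, scanner-geometry, α and scatter/energy-threshold studies,
  plus a thin CLI (`inst/cli/lutran.R`).

## The core update

The μ-map maximizes the penalized Poisson objective
`L_emis(λ,μ) + α L_tran(ημ) − β U(μ)` (MLTR is the transmission-only case).
With `Z_i = η Σ_j l_ij μ_j`, blank counts `B_i` and transmission counts
`y_i`, each SQS pass updates

```
μ_j ← [ μ_j − ( Σ_i l_ij (h'_i + α η H'_i) + β Σ_k w_jk (μ_j − μ_k) )
              / ( Σ_i l_ij (č_emis + α η² č_tran) L_i + β Σ_k w_jk ) ]₊
```

where `H'_i = y_i B_i e^{−Z_i}/(B_i e^{−Z_i}+r_i) − B_i e^{−Z_i}`, the
curvatures `č` are the standard precomputed optimal curvature bounds,
`L_i = Σ_k l_ik`, and `w` are inverse-distance weights over the 26-voxel
neighbourhood. Activity uses the classical TOF-MLEM/OSEM multiplicative
update with sensitivity `Σ_i p_ij a_i n_i`.

## Worked example

```r
library(lutran)

ph    <- default_phantom(seed = 1)        # 21 MBq torso, 22 lesions, 23 VOIs
setup <- desk_setup(ph, "uexplorer")      # desk-scale lattice, ~2.3M LORs
st    <- run_lu_ac_study(ph, setup, seed = 1)

st$mu_report
#> metrics_report [mu_mltr]: NRMSE 9.08%, SSIM 0.6517, max |organ mean bias| 5.06%
st$activity_report
#> metrics_report [osem_lu_ac]: NRMSE 0.69%, SSIM 0.9478, max |organ mean bias| 22.87%
head(st$lesions[, c("host", "contrast", "bias_vs_ref")], 3)
#>    host contrast bias_vs_ref
#> 1 liver      2.4  -1.0190587
#> 2 liver      4.0   8.0969860
#> 3 liver      8.0  -0.9954236
```

The μ-map report says the penalized-MLTR attenuation map reconstructed from
a 20-min-equivalent lutetium transmission scan recovers every analyzed
organ's mean attenuation within ±5% of ground truth in this replicate. The
activity report evaluates the TOF-OSEM image attenuation-corrected with
that map: in this single replicate the small skull VOI group carries −23%
(64 voxels of a low-uptake shell beside the hot brain — the noisiest organ
readout); all other organs sit within ±6%, and averaged over three
replicate seeds every organ's mean bias stays within ±10%. The lesion table
compares each lesion's SUVmax against the reconstruction that used the true
μ-map, isolating the AC-induced lesion bias.

Sweeps:

```r
cfg <- experiment_config("angle_sweep", angles = c(57, 32, 17), seeds = 1:3)
run_experiment(cfg, outdir = "out/angles")
```

or from a shell: `Rscript inst/cli/lutran.R angle_sweep --seed 1 --outdir out`.

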