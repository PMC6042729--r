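# dtihist

Region-wise **histogram analysis of diffusion-tensor imaging (DTI) index
maps** for detecting neurodegeneration and tracking its progression in
longitudinal two-timepoint MRI studies — the analysis style used for
pontocerebellar degenerations such as spinocerebellar ataxia type 2, where
whole-region histogram metrics sidestep the registration and
multiple-comparison burdens of voxelwise methods.

The package is a complete, tested pipeline:

1. **Tensor estimation** from diffusion-weighted volumes
   (`S = S0 · exp(−b gᵀDg)`): log-linear (LLS), weighted (WLLS), and the
   robust outlier-rejecting **RESTORE** fit, with b-matrix construction and
   reorientation by the rotational (polar) part of a registration affine.
2. **Index maps** from the eigenvalues λ₁ ≥ λ₂ ≥ λ₃: mean diffusivity
   MD = (λ₁+λ₂+λ₃)/3, axial AD = λ₁, radial RD = (λ₂+λ₃)/2, fractional
   anisotropy FA = √(3/2)·‖λ−λ̄‖/‖λ‖ ∈ [0,1], and mode of anisotropy
   MO = 3√6·det(Ã/‖Ã‖_F) ∈ [−1,1] (Ã the deviatoric tensor; −1 planar,
   +1 linear).
3. **Histogram metrics** per region (cerebrum, brainstem–cerebellum) and
   index: median (raw values), peak location, peak height; normalized
   histograms with the published bin widths (0.05×10⁻³ mm²/s for MD/AD/RD,
   0.03 for FA, 0.08 for MO).
4. **Longitudinal statistics**: per-subject rate of change
   (Δvalue/Δyears), exact two-sided Mann–Whitney group comparisons with
   Holm–Bonferroni familywise correction, Pearson correlations of imaging
   rates with clinical scores (CAG repeats, disease duration, IACRS/ICARS
   rates), and the standardised response mean (SRM).
5. A **synthetic two-compartment DWI phantom** (Rician noise, known
   ground-truth tensors, two groups × two timepoints) so that every stage
   has a parameter-recovery surface; presets `paper_like`, `null`, `tiny`.

I/O: NIfTI-1 (`.nii`/`.nii.gz`), FSL-dialect `bval`/`bvec` gradient tables,
CSV manifests/tables, JSON run configs. See `vignettes/dtihist-methods.Rmd`
for the model, conventions and design decisions.

## Worked example

Simulate the full study design (9 patients, 16 controls, two scans 2–4.7
years apart, SNR 20) and run the whole pipeline with the RESTORE fit:

```r
library(dtihist)
study <- make_fixture("paper_like", seed = 42)
res   <- analyze_study(study, fit_method = "restore")

r <- res$analysis$rate                      # rate-of-change comparisons
r[r$significant, c("region", "index", "metric", "median_patient",
                   "median_control", "U", "p")]
```

```
               region index        metric median_patient median_control  U            p
 brainstem_cerebellum    md        median        1.00e-05      -2.95e-06  0 9.789645e-07
 brainstem_cerebellum    md peak_location        1.31e-05      -1.24e-05 12 4.999517e-04
 brainstem_cerebellum    md   peak_height       -4.49e-03       3.15e-03  0 9.789645e-07
 brainstem_cerebellum    ad        median        1.17e-05      -3.96e-06  0 9.789645e-07
 brainstem_cerebellum    ad peak_location        1.61e-05       0.00e+00  8 2.323871e-04
 brainstem_cerebellum    rd        median        9.10e-06      -2.57e-06  0 9.789645e-07
```

Reading the first row: the median MD of the brainstem–cerebellum rises at
+0.0100×10⁻³ mm²/s per year in patients versus −0.0030×10⁻³ in controls —
exactly the ground-truth rates the phantom encodes — and the difference
survives Holm–Bonferroni correction over the 30-test family (exact
Mann–Whitney U = 0, p ≈ 9.8×10⁻⁷, the smallest value the 9-vs-16
enumeration can produce). No cerebrum metric is flagged: the simulated
degeneration is confined to the brainstem–cerebellum, and the analysis
finds it there and only there. Baseline comparisons (in
`res$analysis$baseline`) flag all five indices in the brainstem–cerebellum
(patients' median MD 1.12×10⁻³ vs controls' 0.80×10⁻³ mm²/s; FA 0.19 vs
0.25), and `res$analysis$srm` reports the responsiveness of the clinical
scales and of every passing imaging metric. SRM values of the imaging
metrics are much larger than in vivo because the phantom has no
between-subject biological variance — see the vignette's discussion of what
the phantom does and does not emulate.

The same run from the shell:

```sh
echo '{"preset":"paper_like","fit_method":"restore","seed":42,"out_dir":"out"}' > run.json
Rscript inst/cli/dtihist run-all --config run.json
# out/metrics.csv, out/comparisons.csv, out/correlations.csv, out/srm.csv, out/run_log.txt
```

Stage-by-stage subcommands (`simulate`, `fit`, `indices`, `histo`, `stats`)
operate on the on-disk NIfTI/CSV artifacts; `dtihist_cli()` is the same
entry point from R.

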