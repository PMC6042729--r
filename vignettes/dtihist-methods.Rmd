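---
title: "Methods: region histogram analysis of DTI index maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region histogram analysis of DTI index maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtihist)
```

## The problem and the model

In pontocerebellar degenerations such as spinocerebellar ataxia type 2
(SCA2), microstructural damage alters the diffusion of water in brain
tissue. Diffusion tensor imaging (DTI) models the diffusion-weighted MRI
signal in each voxel with a symmetric positive-semidefinite tensor $D$:

$$ S(b, g) = S_0 \exp(-b\, g^\top D g), $$

where $b$ (s/mm²) is the diffusion weighting and $g$ a unit gradient
direction. With eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$ (mm²/s),
the five rotationally invariant indices are

* **MD** $= (\lambda_1+\lambda_2+\lambda_3)/3$ — overall diffusivity;
* **AD** $= \lambda_1$, **RD** $= (\lambda_2+\lambda_3)/2$ — axial / radial
  diffusivity;
* **FA** $= \sqrt{3/2}\,\lVert\lambda-\bar\lambda\rVert / \lVert\lambda\rVert$
  — the normalized eigenvalue dispersion, 0 (isotropic) to 1;
* **MO** $= 3\sqrt{6}\,\det(\tilde A / \lVert\tilde A\rVert_F)$, with
  $\tilde A = D - \mathrm{MD}\cdot I$ the deviatoric tensor — the *shape*
  of the anisotropy, $-1$ (planar) to $+1$ (linear).

Instead of voxelwise statistics, the pipeline reduces each region (a
"cerebrum" mask and a "brainstem–cerebellum" mask, supplied as inputs) to a
*normalized histogram* of each index and summarizes it by three metrics:
the **median** of the raw voxel values, the **peak location** (modal bin
center) and the **peak height** (maximal normalized frequency).
Normalization by the voxel count removes brain-size dependence, and no
spatial registration across subjects is needed. In a two-timepoint design
the per-subject **rate of change** $(x_{fu} - x_{bl})/\Delta t$ (per year)
of every metric becomes the longitudinal readout, compared between patients
and controls.

## Tensor estimation

The fit is log-linear: $\ln S = \ln S_0 - \mathbf{b}^\top \theta$ with the
design row $b(g_x^2, g_y^2, g_z^2, 2g_xg_y, 2g_xg_z, 2g_yg_z)$ — the
doubled cross-term convention is fixed and unit-tested, being the classic
source of silent error. When a registration affine is supplied, the
gradient directions are reoriented with the *rotational part* of its
$3\times3$ block, obtained by polar decomposition, which is unique and
discards the scaling/shear that eddy-current correction introduces.

Three estimators share this design:

* **LLS** — ordinary least squares on $\ln S$;
* **WLLS** — one reweighting pass with weights equal to the squared
  predicted signals (the standard variance stabilization for
  log-transformed magnitude data);
* **RESTORE** — robust estimation: accept the WLLS fit if all signal-domain
  residuals are within $3\sigma$; otherwise iterate a Geman–McClure
  reweighted fit ($w_i = 1/(r_i^2 + C^2)^2$, $C = 1.4826\,\mathrm{med}|r|$,
  up to 50 iterations, relative weight tolerance $10^{-6}$), flag
  measurements with $|r| > 3\sigma$ as outliers, and refit by WLLS without
  them; if fewer than 7 measurements survive, fall back to the full-data
  WLLS fit and flag the voxel.

The reference description of RESTORE leaves its constants to the
implementation; all of ours ($3\sigma$ threshold, the MAD-based scale, the
iteration cap and tolerance) are explicit and tested. The noise level
$\sigma$ is either supplied or estimated from air voxels with the Rayleigh
moment estimator $\sigma = \sqrt{\mathrm{mean}(S_{bg}^2)/2}$.

Numerical choices worth knowing:

* Non-positive signals (possible at high $b$ under the Rician floor) are
  clamped to half the voxel's smallest positive measurement and counted;
  voxels with fewer than 7 usable measurements are invalid.
* Negative eigenvalues from noisy fits are *kept* — indices are computed
  from raw eigenvalues, and the voxel is excluded from histograms only when
  $\lambda_1 \le 0$ or the FA denominator vanishes. Clamping would bias
  histograms toward zero.
* MO of a numerically isotropic voxel
  ($\lVert\tilde A\rVert_F < 10^{-12}\,\mathrm{MD}$) is an undefined limit;
  it is set to 0 (the symmetric choice) and flagged.
* Eigenvalues are computed with the closed-form trigonometric solution for
  symmetric $3\times3$ matrices, vectorized across voxels; `eigen()` is
  used per voxel only when eigenvectors are requested. The two paths are
  cross-checked in the tests.

## Histograms

Bin widths follow the published figure convention: $0.05\times10^{-3}$
mm²/s for MD/AD/RD on $[0, 4\times10^{-3}]$, 0.03 for FA on $[0,1]$, 0.08
for MO on $[-1,1]$. Bins are anchored at the range minimum, left-closed
right-open with the last bin closed; the anchoring and the tie-break toward
the lowest bin center are unstated in the source design and fixed here for
determinism. The median is computed from the raw voxel values, not from
binned counts — binning would quantize it, and the definition refers to the
data sample. Peak metrics are by definition binned; a sensitivity test
documents that halving the bin width moves the peak location by at most one
original bin. More than 5% of in-mask voxels outside the range is treated
as a misconfiguration error rather than silently dropped.

Peak heights are reported as dimensionless normalized frequencies. (The
emulated study's abstract attaches diffusivity-rate units to peak heights;
that is internally inconsistent with a normalized frequency and is treated
as a typographical artifact.)

## Statistics

Baseline metrics and rates of change are compared between groups with the
two-sided Mann–Whitney test: exact (full enumeration distribution of $U$)
whenever $n_1+n_2 \le 25$ and there are no ties — which covers the
9-vs-16 design — otherwise the normal approximation with midranks, tie
correction and continuity correction. Completely tied samples return
$p = 1$. Holm–Bonferroni correction at $\alpha = 0.05$ is applied *within
each analysis family*: the 30 baseline comparisons (2 regions × 5 indices ×
3 metrics), the 30 rate-of-change comparisons, and the correlation family.
The source design does not state whether baseline and rate families were
corrected jointly; correcting per analysis block is the reading we fixed,
and the family size is reported in every output row. Two-sided tests
throughout, sidedness also being unstated.

Pearson correlations (with the $t$-transform p-value, $n-2$ df) are
computed in patients only, between the rates of metrics that survived the
rate-family correction and four clinical variables: CAG repeat count,
disease duration, and the IACRS/ICARS rates of change. The standardised
response mean, SRM $= \overline{\Delta}/s_\Delta$ with the sample ($n-1$)
SD, is reported for the clinical scales and for passing metrics; the IQRs
in comparison tables use a configurable quantile rule (`iqr_type`, default
R's type 7) since the estimator behind the published tables is unstated.

## The synthetic phantom: what it emulates, and what a green test means

No imaging data accompany the emulated study, so the package generates a
stated-world phantom: two non-overlapping boxes ("cerebrum",
"brainstem–cerebellum") in a 24³ grid of 2 mm voxels, 9 patients and 16
controls scanned twice 2.2–4.0 / 1.9–4.7 years apart (uniform), one $b=0$
plus 15 electrostatically spread directions at $b = 1000$ s/mm² — the
acquisition scheme is held fixed across subjects and replicate studies,
as on a real scanner. Compartment mean eigenvalue triples are calibrated so
the true AD/RD medians reproduce the published region medians: controls'
brainstem–cerebellum $(1.00, 0.70, 0.70)\times10^{-3}$ mm²/s, patients'
$(1.30, 1.03, 1.03)\times10^{-3}$, both groups' cerebrum
$(1.05, 0.69, 0.69)\times10^{-3}$. Each voxel jitters each eigenvalue by a
multiplicative $\pm10\%$ uniform factor (re-sorted) and draws a uniformly
random orientation; signals get Rician noise at SNR $S_0/\sigma = 20$,
typical of 1.5 T echo-planar DWI and chosen to exercise RESTORE.

The longitudinal effect scales patients' brainstem–cerebellum eigenvalues
uniformly so that true MD grows at $0.010\times10^{-3}$ mm²/s/year
(controls: $-0.003\times10^{-3}$), the published rates; uniform scaling
preserves FA and MO, matching the finding that only MD tracked progression.
Cerebrum tensors drift at a common rate (default 0) in both groups, so
cerebrum metrics are exchangeable between groups — the stated world confines
the effect to patients' brainstem–cerebellum. Patients' clinical scores are
drawn from normal distributions matching the published summary statistics
(IACRS $17.2\pm4.3 \to 21.3\pm6.1$; ICARS $39.7\pm14.3 \to 44.3\pm14.5$;
CAG $40.6\pm1.4$, floored at 34; duration $12.8\pm7.3$ years, clipped to
2–23), rounded and clipped to their legal ranges.

What the phantom does *not* emulate: anatomy and partial-volume mixing,
motion/eddy artifacts (only the b-matrix-rotation contract is kept),
between-subject biological variability beyond measurement noise (all
subjects of a group share compartment distributions, so between-subject
variance of the metrics is noise-driven and smaller than in vivo), and any
spatial correlation of noise. A green recovery test therefore establishes
that the *pipeline* is faithful — estimator, indices, histogram and
statistics — not that the phantom is a realistic brain. The published
between-subject IQRs conflate within- and between-subject variance and
cannot be disentangled from the printed tables; this is noted, not
resolved.

Presets: `paper_like` (the design above), `null` (identical group
distributions, zero rates, compact grid — used for familywise
false-positive calibration across replicate seeds) and `tiny` (3 + 4
subjects, minimal grid, for smoke tests). One global seed drives derived
per-subject, per-timepoint substreams, so studies are bit-reproducible.

## Design choices that were genuinely open

* **No NIfTI dependency**: no NIfTI reader exists among the available R
  packages here, so a minimal NIfTI-1 reader/writer (sform affine, float32
  maps, `.nii`/`.nii.gz`) lives in the package behind the I/O contracts,
  round-trip tested.
* **Exact Mann–Whitney machinery**: the exact null distribution of $U$ for
  tie-free samples is the same object full enumeration produces; the
  implementation uses R's exact Wilcoxon distribution and the tests verify
  it against a literal `combn()` enumeration oracle for all
  $n_1+n_2 \le 10$ rank configurations.
* **MO formula**: the source states only the $[-1, 1]$ range; the
  deviatoric-determinant definition used here is the standard mode-of-
  anisotropy measure and is pinned by unit tests at both extremes. If the
  original toolchain normalized differently, intermediate values could
  differ slightly while the extremes still match.
* **Run configs are JSON** (via jsonlite) rather than YAML: equivalent
  structure, one fewer dependency.
* **Replicate-based criteria use the LLS fitter**: the null-calibration and
  effect-recovery suites run hundreds of full studies; the LLS estimator is
  exact on the model family and orders of magnitude faster than per-voxel
  robust iteration, and the statistical behavior under test does not depend
  on the fitter in the uncorrupted regime.

## Known limitations

Single-shell, single-tensor model only; no motion/eddy correction or
skull-stripping (masks and affines are inputs); no kernel density
alternative to histograms; the exact Mann–Whitney switches to the
approximation as soon as ties appear, which for coarse metrics (e.g. peak
locations sitting on the same bin center) is the common case — the
continuity-corrected approximation is then conservative rather than exact.
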