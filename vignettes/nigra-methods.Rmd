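---
title: "Methods: synthetic nigral phantoms, QSM/SMWI reconstruction, and PD classification statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic nigral phantoms, QSM/SMWI reconstruction, and PD classification statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nigra` re-implements a quantitative Parkinson's-disease (PD) classification
analysis built on midbrain MRI — quantitative susceptibility mapping (QSM),
susceptibility-map-weighted imaging (SMWI) and neuromelanin-sensitive (NMS)
contrast — as a reusable pipeline driven entirely by synthetic data. The
patient images behind the original analysis are not publicly deposited, so
every stage here is exercised by a seeded phantom cohort whose summary
statistics are calibrated to the published group tables. This vignette
documents the models, the numerical choices, and what the synthetic data can
and cannot establish.

## The latent degeneration model

Each subject carries one latent severity factor $x \sim N(0,1)$, shifted by a
group offset: $\eta = x + \delta_g$ with defaults $\delta_{PD} = 1.5$,
$\delta_{HC} = -1$. Degeneration is the probit transform $d = \Phi(\eta)$,
so the median control sits at $d \approx 0.16$ and the median patient at
$d \approx 0.93$. The left hemisphere is more affected: the offset
`left_offset` (default 0.125 on the probit scale, roughly +5 percentage
points of degeneration mid-scale) is split symmetrically,
$d_L = \Phi(\eta + \lambda/2)$, $d_R = \Phi(\eta - \lambda/2)$, so the
bilateral mean stays on the calibrated marginal. Published work reports
consistently better left-sided classification without quantifying the
asymmetry, so the magnitude is a configuration knob, not a claim. The
nigrosome-1 is considered intact while $d < 0.5$.

All four quantitative SN measures load on the single factor. For measure $m$
in group $g$, published medians and inter-quartile ranges are converted to a
log-normal by quartile matching,

$$\mu = \log(\text{median}), \qquad
  \sigma = \frac{\log q_3 - \log q_1}{2\, z_{0.75}}, \quad z_{0.75} = 0.6745,$$

which reproduces the median always and both quartiles exactly when
$q_1 q_3 = \text{median}^2$ (log-symmetric IQR). The generator then uses a
common mapping for both groups,

$$\log m = a_m - b_m\,\eta_s + s_m\,\varepsilon_m, \qquad
  \eta_s = \Phi^{-1}(d_s) + \tau\,\xi_s,$$

with $b_m$ chosen so the PD and HC log-medians are hit exactly at the two
group offsets, and $s_m$ topping the within-group log-variance up to the
average of the two fitted $\sigma$'s. Because the group difference flows
*only* through the degeneration term, setting `effect_scale = 0` makes the
groups exchangeable — the basis of the null-calibration test. The shared
factor induces positive cross-measure correlation; its strength is not
published, so the residual split ($b_m$ vs $s_m$) is the package's own
choice, fixed by the variance-matching rule above. Measure noise
$\varepsilon_m$ rides on a dedicated random stream keyed to the cohort seed,
so editing a subject's degeneration and regenerating measures is a
common-random-numbers experiment: measures are monotone non-increasing in
degeneration, which the tests assert.

A log-normal family was chosen because all four measures are strictly
positive and reported right-skewed; it is the simplest family a quartile
triple pins down. Clinical covariates couple to the same factor:
MDS-UPDRS-III for patients is a configured floor (5) plus a log-normal
component rising with severity; H&Y stages are severity bands matched to the
published stage frequencies (6/83/11 %); LEDD and disease duration are
quartile-fitted log-normals with moderate loadings (0.4, 0.3). Controls get
stage 0, small motor scores (median 2), and no LEDD/duration.

## Phantom geometry and the forward model

`render_phantom()` builds, per hemisphere, an SN ellipsoid (semi-axes
4.5 x 2.5 x 4.5 mm at ±7 mm laterality), a red-nucleus (RN) sphere
(r = 2.5 mm) cranial to it, and an N1 ellipsoid in the caudo-dorsolateral
SN, all inside a "head" ellipsoid that carries the MR signal. Susceptibility
(ppb): SN $90 + 60 d$, N1 $10 + 120 d$ (iron-poor while intact, converging
on the SN level as degeneration proceeds), RN 100, background 0, plus
3 ppb Gaussian texture. The N1 additionally shrinks by up to 60 % of its
linear size. NMS signal is generated directly on the same grid — a
medial-to-lateral contrast ramp of 10–25 % over background inside the SN,
scaled by $(1 - 0.75 d)$ — rather than simulated from spin physics: the
analysis consumes NMS only through percentiles and thresholds, so contrast
structure is what must be emulated, not T1 relaxometry. Anisotropic NMS
slices are possible via the grid configuration but default to the GRE grid,
since no resampling scheme between the two native grids is published.

The acquisition model is standard dipole physics. With
$D(k) = 1/3 - k_z^2/|k|^2$, $D(0) \equiv 0$, and B0 along the slice axis,

$$f = \bar\gamma B_0 \cdot 10^{-9}\, \mathcal{F}^{-1}[D \,\mathcal{F}(\chi)]
  \;\text{Hz}, \qquad \bar\gamma = 42.577\ \text{MHz/T},\ B_0 = 3\ \text{T}.$$

Per-echo phase is $2\pi f\,TE$ plus a smooth quadratic background field
(2 Hz peak) and a constant per-channel offset, wrapped to $(-\pi, \pi]$;
magnitude decays as $e^{-TE/50\,\text{ms}}$ with per-channel gains, and
complex Gaussian noise is added per channel. The $D(0)=0$ convention removes
the undefined $k=0$ term and makes the field inside a uniform sphere vanish
(the Lorentz $+\chi/3$ and demagnetizing $-\chi/3$ terms cancel), which the
tests use as a closed-form oracle. All spectral operations zero-pad by a
factor 2 per axis to suppress circular wrap-around.

## QSM and SMWI reconstruction

The named joint unwrapping/background-removal technique of the original
processing chain is not published as equations, so it is decomposed into two
explicitly testable stages:

* **Laplacian unwrapping** solves
  $\nabla^2\phi = \cos\psi\,\nabla^2\sin\psi - \sin\psi\,\nabla^2\cos\psi$
  spectrally with the $k=0$ term zeroed. One numerical subtlety: the padded
  copy of $\cos\psi$ must be continuous at the pad boundary, so
  $\cos\psi - 1$ is padded instead (constants are in the null space of the
  solver). Wrap-free smooth phase is reproduced to ~1e-12 rad; a phase bump
  peaking at $6\pi$ is recovered to < 0.05 rad interior error.
* **Frequency fitting** is per-voxel weighted least squares of unwrapped
  phase against $2\pi TE$ with an intercept absorbing TE-independent
  receiver offsets; default per-echo weights are the echo-mean squared
  magnitude. A single echo requires the explicit intercept-free flag.
* **SMV background removal** applies $(\delta - S_r)$ (spherical-mean kernel,
  default radius 2 mm), restricts to the mask eroded by the kernel radius,
  then deconvolves the filter where its spectrum exceeds 0.05. Harmonic
  (externally generated) fields are annihilated up to a boundary layer;
  constant fields vanish identically.
* **Dipole inversion** starts from truncated k-space division
  ($\text{sign}(D)/\max(|D|, \delta)$, default $\delta = 0.1$) and applies
  `n_iter` (default 30) fixed-point refinements enforcing exact data
  consistency on $\{|D| > \delta\}$ while constraining image-space support
  to the mask — a projection-onto-convex-sets scheme. The output is
  referenced to zero mean over the mask, since susceptibility is only
  defined up to a constant. The exact regularization and iteration counts of
  the original vendor chain are not published; both parameters are exposed
  in the configuration and are claims of structure, not equivalence. A
  100 ppb sphere round-trips through forward simulation and inversion to
  within ±15 % interior mean (measured ~4 % low), and the whole map is
  linear in the field to numerical precision.

Brain extraction is a deliberately simple stand-in for a full skull-stripping
tool: threshold at 20 % of the robust (99th percentile) maximum, largest
6-connected component, morphological closing (1 mm).

SMWI follows the eight published steps: root-sum-of-squares channel
magnitude; channel phase combined circularly after subtracting per-channel
constant offsets estimated over a high-magnitude core (reference = channel
1); RSS echo combination; QSM via the stages above (the susceptibility map
is bit-identical to calling the QSM chain directly — asserted in tests); a
paramagnetic mask $w = \mathrm{clip}((\chi_t - \chi)/\chi_t, 0, 1)^p$
(defaults $\chi_t = 150$ ppb, $p = 4$ — the published description names only
"a paramagnetic threshold value", so the linear-ramp-to-power form is the
minimal standard contract, both constants configurable); and the final
product SMWI = magnitude x w, which is bounded by the magnitude with
equality exactly where $\chi \le 0$.

## SN quantification

Analysis slices follow the radiological rule: scanning cranio-caudally
(caudal = increasing slice index internally), the first slice where the RN
is "barely or no longer visible" — operationalized as a per-slice RN voxel
count below `ceiling(0.1 x max count)`, the fraction being configurable
since the original criterion is visual — plus the two consecutive inferior
slices. Per hemisphere and measure:

* **QSM-based volume**: SN voxels on those slices with $\chi$ *below* a
  threshold (low-susceptibility tissue), times the voxel volume.
* **NMS-based volume**: SN voxels *above* a threshold (high neuromelanin).
* **NMS contrast range**: P90/P10 of NMS signal in the SN mask, using
  linear-interpolation percentiles (pinned because the ratio is meaningless
  without a fixed percentile definition). The same three slices are used as
  for segmentation; the original description implies but does not state
  this.
* **QSM-NMS composite**: the product of the three, lower = more PD-like.
* **N1 volume (SMWI)**: the proprietary deep-learning volumetry tool is out
  of scope; its functional contract — "returns the N1 volume in mm^3" — is
  met by a rule-based stand-in: SN voxels on the analysis slices whose SMWI
  exceeds `rel_threshold` (default 0.15) times the slice-wise median
  background SMWI, i.e. residual hyperintensity inside the hypointense SN.

The thresholds are never published, so "auto" mode is the only faithful
reading of "the threshold which maximized the difference between PD and
control groups": `optimize_threshold()` scans a quantile grid of candidate
thresholds and maximizes the PD-vs-HC AUC of the resulting per-subject
volumes (equivalent to the standardized Mann-Whitney statistic — scale-free
and consistent with the nonparametric testing used throughout), ties broken
toward the smallest threshold. Hemispheres are aggregated by averaging for
continuous measures; binary ratings are Normal only if both sides are
Normal.

## Classification and statistics

ROC curves place one vertex per distinct score (ties grouped), so the
trapezoidal AUC equals the Mann-Whitney $U/(n_1 n_2)$ with half-credit for
ties — asserted exhaustively against a brute-force pairwise oracle. The
orientation convention `lower_is_positive` (score ≤ cutoff called PD)
matches all five markers. Youden's $J = \max(\text{tpr} - \text{fpr})$ with
ties broken toward higher sensitivity, on the principle that a screening
classifier should err toward false positives; the returned cutoff applied
back to the scores reproduces the vertex confusion counts exactly. Binary
raters get the two-point trapezoid AUC,
$(\text{sens} + \text{spec})/200$.

Group comparisons use the tests the published tables name: Mann-Whitney with
midrank ties (exact enumeration when the smaller group has ≤ 8 observations
and no ties, else a tie-corrected normal approximation), pooled-variance
Student's t (accepting summary statistics directly — the published age
summaries reproduce the reported p ≈ 0.656 under the pooled form), and
Pearson chi-square without continuity correction (the published sex-ratio
p = 0.005 is reproduced without the correction; Yates gives ≈ 0.007).
Spearman is Pearson-on-midranks with the t approximation; Kendall tau-b uses
the standard tie terms with a normal-approximation p. Bonferroni control
uses $m$ = the number of correlation tests actually run, overridable to the
published fixed $m = 40$ (the enumeration of those 40 tests is not
published).

## Problem sizes, determinism, limitations

Every stage is deterministic given the configuration and master seed;
per-subject seeds are derived by counters, not execution order, so results
are independent of scheduling. Default test problem sizes are chosen for
desk-scale runtime: spectral tests on 32–48^3 grids, the sphere round trip
on 64^3 (padded to 128^3), calibration checks at 500 per group via the
latent route, and the full-image smoke cohort at 10 + 10 subjects on a
64 x 64 x 32 grid (~13 s per subject on one core); the acquisition matrix of
the original protocol is not published (only voxel size), so the grid is
configuration. The default pipeline grid is 96 x 96 x 32.

What passing tests show — and what they do not: the phantoms are geometric
primitives with Gaussian texture. They contain no realistic anatomy,
relaxometry, motion or pulsation artefacts, through-plane re-slicing, or
scanner variability, all of which drove misclassifications in the real
cohort. Calibration tests therefore establish that the pipeline's
statistical machinery is correct and that the generator hits the published
marginals; they do not validate classification performance on real
patients. The published headline AUCs on the real cohort are not
reproducible from synthetic data by construction; what is reproduced exactly
is every quantity that is arithmetically determined by printed inputs
(confusion-matrix metrics from sensitivities/specificities and group sizes,
binary-rater AUCs, the Bonferroni level).
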