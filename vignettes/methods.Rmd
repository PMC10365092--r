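---
title: "Methods: uncertainty-aware tract segmentation in SH space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty-aware tract segmentation in SH space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

White-matter tracts (corticospinal tract, inferior longitudinal fascicle,
uncinate fascicle, ...) are segmented directly from diffusion MRI by a
convolutional network, and — because surgical planning consumes these maps —
every prediction is accompanied by an uncertainty estimate and a calibrated
volume interval. This vignette documents the modelling choices, the tunable
parameters, what the phantom generator does and does not emulate, and the
numerical conventions.

# Signal representation

A single shell (default b = 2000 s/mm²) is selected from the acquisition,
normalized voxelwise by the mean b0 signal, and projected onto the real,
even-degree spherical-harmonic (SH) basis with `lmax = 4`, i.e. 15
coefficients per voxel. The projection is a plain per-voxel least squares
against the SH design matrix at the shell directions — no diffusion model is
fitted. Even degrees suffice because dMRI signals are antipodally symmetric.
Finally each coefficient channel is clamped to its in-brain [5th, 99th]
percentile band to suppress noise outliers.

Conventions worth recording:

* Basis ordering is `l = 0, 2, 4` with `m = -l..l` inside each degree
  (`sh_index_table()`); the convention identifier is stored in every
  `sh_volume` so mismatches are detectable.
* Percentiles use linear interpolation between order statistics
  (`stats::quantile` type 7) and are computed **per channel** within the
  brain mask: channel scales differ by orders of magnitude, so a global band
  would clamp nothing but the isotropic channel. One consequence of the
  interpolated convention is that clamping is idempotent only up to
  re-interpolation inside one order-statistic gap (a relative shift
  bounded by roughly 1/n); the tests assert idempotence at that tolerance.
* b0 frames are those with b ≤ 50 s/mm²; voxels whose mean b0 is ≤ 1e-6 are
  zeroed and counted rather than propagating division noise.

# Rotation-consistent augmentation

Naive spatial augmentation is wrong for SH images: rotating the voxel grid
without rotating the per-voxel function leaves fiber orientations pointing
the old way. `rotate_volume_and_sh()` applies one rotation to both: the grid
is resampled (trilinear for coefficients, nearest for masks, zero fill
outside) and each voxel's coefficient vector is multiplied by the
block-diagonal SH rotation operator of the same rotation.

The operator is built by least-squares collocation: the degree-l basis is
evaluated at a fixed Fibonacci direction set and at the back-rotated set,
and the block is the exact linear map between them (rotations preserve
degree subspaces, so the overdetermined system is consistent). This is as
accurate as a recursive construction — the conformance test is the
sphere-sampling oracle `synth(rot(c))(u) = synth(c)(R⁻¹u)`, which holds to
~1e-14 — and considerably simpler to audit. Blocks are orthogonal, so
per-degree coefficient norms are invariant (a Parseval check in the tests).

Angles are drawn i.i.d. uniform per axis (extrinsic x, then y, then z) on
[-range, +range]; the training default is 20°. The rotation center is the
grid center; the axis order is recorded in the `rotation_spec` so
augmentation is reproducible.

# Network and training

The segmentation network is a 3D U-Net: `depth` encoder blocks of
2 × (conv 3³, dropout, instance norm, leaky ReLU) followed by 2³ max
pooling, a bottleneck block, and a mirrored decoder using 2× transposed
convolutions and skip connections; a 1×1×1 logistic head emits one
probability per tract. Outputs are independent per-class logistics, not a
softmax: tracts overlap spatially and the loss is per-class binary
cross-entropy. Dropout lives in the encoder blocks only, which is what makes
test-time dropout possible without retraining. The implementation is a
compact, fully-tested R one (im2col + BLAS); its backward pass is verified
against finite differences.

The loss is class-weighted binary cross-entropy with `w_n = max(C)/c_n`,
where `c_n` counts class-n positive voxels over the training set — rare
tracts are upweighted so the largest class has weight 1. `wbce_loss()`
exposes a `voxel_mean` flag: off, the loss is the literal sum over voxels
(classic form); on, it is divided by the voxel count J. The training loop
uses the voxel-mean form so the loss scale — and therefore the learning
rate — does not change when the patch size changes.

Full-scale defaults (all in `train_config()` / `unet_config()`):
400 epochs, initial learning rate 1e-3 halved every 50 epochs, weight decay
1e-6, dropout 0.25, 50 patches of 64³ per subject visit, ±20° augmentation,
depth 4. Per epoch every subject is visited once in random order with a
fresh rotation and fresh patches. The full-scale protocol pins only the rate
schedule and the weight decay, not the optimizer family; `train_config()`
offers momentum SGD and Adam.

Three desk-scale choices deserve justification:

* **Optimizer.** On the desk budget (a few thousand parameter updates)
  momentum SGD at any stable rate leaves the curved tracts half-converged;
  Adam at 5e-3 (halved every 20 epochs) reaches held-out Dice above 0.8 in
  the same budget. The desk profile therefore uses Adam; SGD remains
  available and is the natural choice when reproducing the full-scale
  schedule. Note the learning-rate scale also differs from the full-scale
  value because the training loop uses the voxel-mean loss form, which
  rescales gradients relative to the summed form.
* **Head-bias initialization.** Tract foreground occupies ~1-2% of brain
  voxels. Starting the logistic head at bias 0 (probability 0.5) makes the
  first several hundred updates do nothing but push the background down; on
  a desk budget the Dice stays at 0 long after the loss has collapsed.
  Initializing the head bias to -2.5 (prior probability ≈ 0.076) removes
  that transient. `head_bias = 0` reproduces the plain initialization.
* **Augmentation range.** The desk profile trains with ±15° rotations
  (full-scale default: ±20°); the tiny grid loses proportionally more voxels to
  out-of-bounds zero fill under large rotations.

# Stochastic inference

`predict_volume()` covers a volume with overlapping windows (50% overlap,
uniform averaging — the seams cancel exactly for a constant-output model,
which is a unit test). Three stochastic modes produce a `probability_stack`
of T passes:

* **TTD** — dropout active at inference; epistemic spread.
* **TTA** — per pass, a random rotation of the input (grid + SH together),
  prediction, then the inverse spatial rotation of the probability maps so
  all passes live in subject space. Probabilities are orientation scalars,
  so only the spatial part needs inverting. Without that re-alignment,
  voxelwise statistics across passes would be meaningless; re-alignment is the only reading that
  makes the subsequent per-voxel quantiles well defined.
* **Hybrid** — both in the same pass.

The full-scale setting is T = 20 passes, r = 0.25; the desk profile uses
T = 10. Pass t draws its random stream from a seed derived from (master
seed, t), so stacks are bitwise reproducible and the first T passes of a
longer run equal the shorter run. The final prediction is the voxelwise
mean; the uncertainty map is the voxelwise SD (population convention,
divisor T — the spread of the finite ensemble actually computed).

# Quantile-volume calibration

For each voxel, the T pass probabilities give empirical quantiles ω_k at
levels k ∈ {0, 1/T, ..., 1} (interpolated order statistics; level 0 = min,
1 = max). Summing ω_k over voxels (times the voxel volume, |det A₃ₓ₃| mm³)
yields the quantile-volume curve V_k — a predicted volume distribution for
the tract. V_k is non-decreasing because order statistics are monotone in
the level and summation preserves order.

Calibration asks: at which nominal level does the curve cross the true
volume (`coverage_level()`, piecewise-linear inverse, ties to the lowest
crossing level)? If predictions were perfectly calibrated these coverage
levels would be uniform on [0, 1] across subjects. `fit_calibration()`
therefore maps nominal level q to the empirical quantile of the validation
coverage levels (piecewise-linear empirical-CDF inverse with sorted levels
at plotting positions i/(n+1), anchored at (0,0) and (1,1)); fitting is
one-shot, per tract, on validation subjects only. `apply_calibration()`
re-reads the original curve at the remapped levels, so coverage levels of
new subjects from the validation distribution become uniform — the correct
proportion of true volumes falls inside each nominal interval. The
remapping acts on quantile *levels*, not on per-voxel probabilities; the
level reading is the one that realizes nominal coverage directly, and
per-voxel maps can still be produced by evaluating `voxel_quantiles()` at
remapped levels.

`min_volume_difference()` (smallest |V_k - V_true| over levels) quantifies
how close the predicted volume distribution comes to the truth; calibration
concentrates curve levels where true volumes actually fall, which lowers it
on average.

# Evaluation

Overlap metrics come from voxel confusion counts; Dice is
`2tp/(2tp+fp+fn)` (two empty masks give 1, flagged). Printed definitions of
sensitivity and specificity in parts of this literature divide by the
*predicted* counts (precision / NPV); both conventions are implemented —
`"standard"` (recall, TNR) is the default and every report records which
was used. Surface distances use 6-connectivity boundaries (foreground voxel
with a background face neighbor; grid edges count as background) and
brute-force nearest-boundary Euclidean distances scaled by the voxel
spacing; Hausdorff is the maximum and ASSD the mean over the union of both
directed sets, so HD ≥ ASSD always.

Structure-wise uncertainty is the volume variation coefficient: binarize
each pass at 0.5 (inclusive), take per-pass foreground volumes, and report
σ/μ (population SD; scale-free). Across subjects VVC is expected to rank
with segmentation error 1 - mean-pass-Dice; the association is measured
with Spearman's rank correlation (average ranks on ties; undefined and
reported missing under zero rank variance).

# The phantom generator

`make_phantom_subject()` builds what the pipeline needs and nothing more:
tube-shaped tracts (radius 2.4 voxels) around straight, C- and S-shaped
centerlines in a 32³ grid, a spherical "intracranial" mask guaranteed to
contain them, and a single-shell DWI signal. The three templates occupy
distinct principal-orientation classes — straight inferior-superior
(CST-like, along z), a C curving in the y-z plane (UF-like), an S running
anterior-posterior (ILF-like, along y) — because that is how real bundles
remain locally distinguishable from their diffusion signatures; co-planar
layouts make different tracts locally identical and the multi-label
classification ill-posed. In-tract
voxels follow an axially symmetric single-tensor attenuation
`S0·exp(-b·(λ⊥+(λ∥-λ⊥)(g·d)²))` with d the local centerline tangent,
λ∥/λ⊥ = 1.5e-3/3e-4 mm²/s (ratio 5); background is isotropic with ADC
7e-4; b0 frames are unattenuated. At b = 2000 and S0 = 100 with Gaussian
noise SD 2, the degree-2 SH energy of tract voxels sits orders of magnitude
above the background, so segmentation is learnable at desk scale. Rician
noise (magnitude of complex Gaussian) is available for realism; Gaussian is
the default because it keeps the analytic tests exact. Subjects differ by
±1 voxel control-point jitter; everything is seeded and byte-reproducible.

What the phantoms deliberately lack: crossing fibers, partial-volume
gradients at tissue interfaces, anatomical variability beyond jitter,
multi-shell schemes, and acquisition artifacts. Tests passing on phantoms
demonstrate that the pipeline's machinery is correct and that uncertainty
tracks error when noise is the dominant degradation — they do not
demonstrate clinical-grade accuracy on real brains.

# The desk-scale study

`run_desk_study()` is the package's end-to-end experiment: 6 training
phantoms (seed 7), the tiny network profile (depth 2, base 8 filters, 16³
patches, dropout 0.25), 50 epochs of Adam at 5e-3 halved every 20, ±15°
augmentation, then Hybrid inference (T = 10, window 32) on 2 held-out
phantoms and a noise sweep over 8 phantoms with noise SD 1–40. Reported:
mean Dice of the thresholded mean prediction across held-out tracts, the
Spearman correlation of VVC with 1 - mean-pass-Dice across the sweep, and
quantile-volume curves. Problem sizes were chosen so the full study runs in
minutes on one CPU while still exercising every stage at realistic
signal-to-noise.

# Known limitations

* The network implementation favors clarity over speed; it is adequate for
  32³ phantoms, not for 145³ human acquisitions.
* The greedy electrostatic reordering is a deterministic stand-in for
  global half-sphere optimization; its prefixes are near-optimal, not
  optimal.
* Calibration assumes validation and test subjects are exchangeable; under
  domain shift the fitted map inherits the shift.
* With few validation subjects the empirical-CDF map is a coarse staircase;
  degenerate (all-identical) coverage levels produce a step map and a
  warning.
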