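---
title: "Methods: simulating and evaluating accelerated FLAIR reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating accelerated FLAIR reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models, parameters, and the
design decisions behind them. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## What is being modeled

The package replicates, on synthetic data, an evaluation chain for
accelerated FLAIR brain MRI: a fully sampled acquisition (the *std* arm) is
retrospectively undersampled threefold along the phase encode, reconstructed
by parallel imaging with wavelet regularization (the *acc* arm), and then
denoised by a small convolutional network (the *dlr* arm). The question the
chain answers is quantitative: how close are acc and dlr to std, globally
(whole-image SSIM/NRMSE) and at white-matter hyperintensities (the same
metrics on 25×25-pixel lesion windows)?

Patient raw k-space is not publicly available for this kind of study, so the
cohort is synthetic and the generator is a first-class, tested module — its
defaults *are* the study conditions.

## The phantom generator

`generate_phantom()` builds a 2D axial FLAIR-like slice from concentric
smoothed ellipses: background air, a CSF rim plus two ventricles
(suppressed, dark), a gray-matter ribbon (bright), and a white-matter core
(intermediate). Tissue signal levels are 0 / 0.15 / 0.75 / 0.55 in arbitrary
units, with 2% per-case multiplicative jitter, and each case receives a
smooth random angular deformation of its tissue boundaries so cases differ
in anatomy as well as lesion placement. Lesions are rasterized discs,
3–10 mm in diameter (uniform), restricted to the white-matter label,
non-overlapping, with a 1-pixel smoothed edge and a 1.4× core contrast
relative to white matter. The lesion contrast and texture are free
parameters of the generator (exposed in the configuration): the source
material for this design characterizes lesions only by size range and
hyperintensity, so the default was chosen once as a clearly
supra-threshold, clinically plausible contrast and not revisited.

Defaults: 120×120 grid over a 240×240 mm field of view (2 mm pixels), 30
evaluation cases with 4 lesions each — at least 100 lesions for the regional
analysis. The grid is 120 rather than a power of two because the
phase-encode length must be divisible both by the acceleration factor 3
(per-group SENSE unfolding assumes periodic aliasing) and by `2^3` for the
three-level periodized wavelet transform; 120 = 8·15 satisfies both, a
128-line phase encode does not.

What the phantoms do *not* model: Bloch-equation FLAIR physics (tissue
contrast is painted, not simulated), 3D geometry, motion, susceptibility or
flow artifacts, and anatomical detail beyond four compartments. Passing
tests therefore demonstrate the pipeline's numerical behavior under
controlled contrast and noise, not performance on clinical images.

## Coil maps and the noise regime

`generate_coil_sensitivities()` places one broad Gaussian magnitude lobe per
channel around the object with slowly varying linear phase, then normalizes
so the channel sum of squares is exactly 1 everywhere; coil combination then
has unit gain and the fully sampled reconstruction noise equals the
per-sample k-space noise.

Three generator parameters set the noise regime of the whole study and were
calibrated once, jointly, before freezing:

* `noise_std = 0.002` (complex Gaussian, per real/imaginary component, in
  the same arbitrary units as the phantom signal; white matter is 0.55);
* `lobe_width = 0.7` of the grid extent for 8 channels;
* `phase_range = 0.3` cycles of linear phase per channel across the field
  of view.

The calibration targets two properties of the regime being replicated.
First, the accelerated arm's whole-image SSIM against std lands in the
0.85–0.95 band. Second — and this is the property that actually constrains
the geometry — the accelerated arm's *excess* noise (g-factor amplification
of the R = 3 unfolding) must dominate, and must be *decorrelated* from the
reference arm's own noise. Retrospective undersampling reconstructs the acc
arm from a subset of the same noisy acquisition as std, so with a
well-conditioned coil geometry (narrow lobes or strong phase diversity) the
two arms share most of their noise, SSIM(std, acc) is propped up by that
correlation at or above the ideal-denoiser bound, and no denoiser — not
even one that outputs the noiseless image — can raise whole-image SSIM.
Nearly-parallel sensitivities (wide overlapping lobes, weak phase
gradients) make the R = 3 unfolding genuinely ill-conditioned: the
amplified noise is dominated by cross-terms folded in from distant alias
positions, which the std arm does not contain. That is the regime the
replicated study describes (severe central noise in the accelerated
images, a comparatively clean reference), and the shipped defaults sit
firmly inside it.

## Reconstruction

All transforms are centered and orthonormal (`1/sqrt(N)` both directions),
so Parseval's identity holds exactly and noise variances carry unchanged
between domains. The phase-encode axis is the column axis.

**Reference.** Per-channel inverse FFT, sensitivity-weighted least-squares
combination `m = Σ conj(S_c) x_c / Σ |S_c|²`, magnitude. With simulated maps
the combination uses the ground-truth sensitivities; calibration from
auto-calibration lines is out of scope.

**SENSE.** Masking k-space is a circular convolution in image space; for a
periodic mask the kernel has exactly R taps, so each set of R
pixels spaced `n/R` apart along the phase encode folds onto itself. The
per-(row, group) system stacks all R aliased positions over all channels
(`(R·n_ch) × R`) and is solved by least squares via the normal equations,
with an eigenvalue rank check that reports the offending pixel group when
the geometry cannot unfold ("unresolvable aliasing"). The factorization is
precomputed once per coils/mask pair (`sense_reconstructor()`), which makes
Monte-Carlo noise maps cheap.

**POCS with wavelet soft-thresholding.** The iteration starts from the
unfolded SENSE solution (configurable back to a zero-filled start), which is
already consistent with the measured lines up to noise; a zero-filled start
needs far more alternating-projection iterations than a desk-scale run
allows and leaves a smooth, case-specific aliasing bias in the image that
neither the wavelet shrinkage nor a small CNN can remove. From the SENSE
start the iterations purely reshape noise. Iterate: (1) data consistency —
re-project the current estimate through the coil maps to k-space and replace
sampled lines with the measured data; (2) coil combination; (3) shrinkage of
the detail coefficients of a 3-level periodized Daubechies-4 (4-tap)
decomposition, approximation band untouched. The threshold is
`lambda × sigma_hat`, where `sigma_hat` is a median-absolute-deviation
estimate from the finest diagonal band at the first iteration and
`lambda = 0.25` by default; `lambda = 0` reduces the iteration to pure
alternating projections, under which the sampled-line residual is provably
non-increasing (both steps are projections: the data-consistency set is
affine, and with unit sum-of-squares maps the coil-combination step is an
orthogonal projection onto the range of the coil expansion). Defaults:
30 iterations (`max_iters`), relative-change tolerance `1e-5`;
non-convergence at `max_iters` is flagged in the result metadata, not an
error. The wavelet filters have closed form (`(1±√3)/(4√2)` family), the
transform is orthonormal, and perfect reconstruction is asserted to machine
precision in the tests.

The accelerated arm defaults to the POCS reconstruction
(`acc_method = "pocs"`), with plain SENSE available as a switch; both were
plausible readings of the replicated design and the choice is exposed rather
than hidden.

## The denoiser

Architecture (asserted by test): 9×9 kernels/64 channels, 5×5/32, 5×5/1,
bias everywhere, ReLU after layers 1 and 2, linear output, global skip
connection (`output = input + correction`), final clamp to non-negative
magnitudes at inference; 57,281 parameters. A literal reading of the
source design would put a ReLU on the last layer too, but a residual
correction must be signed, so the output layer is linear — the standard
resolution for residual denoisers.

Convolutions use same-padding with reflect boundaries, implemented as
im2col + BLAS matrix multiplication with the backward scatter precomputed as
a sparse matrix; the analytic gradients match numerical differentiation in
the tests.

Training pairs: the *reference* is the reconstruction of noiseless fully
sampled k-space of a training case; the *noisy* member is the acc-arm
reconstruction of the undersampled noisy acquisition of the same case;
patches are co-located, drawn from brain-mask centers, and both members are
normalized by the noisy image's 1st–99th percentile span. The input-derived
normalization (rather than reference-derived) is deliberate: at inference
only the input exists, so the training-time rule must be computable from the
input alone; the percentile probabilities are stored in the model. Using a
noisy reference instead would make the target share a noise realization
with the input (both arms come from the same retrospective acquisition) and
the MSE-optimal network would be close to the identity.

Optimization: Adam (`lr = 3e-4`, batch 32), MSE loss, seeded shuffling over
a canonical pair order (so the result is invariant to the order pairs are
supplied in), with an 80/20 by-case train/validation split. The default
epoch and patch counts (`epochs`, `n_patches` in `experiment_config()`) are
sized for a single-CPU desk run of the whole experiment in minutes; the
loss and validation curves are recorded in the trained model so the tests
can assert that held-out patch MSE beats the noisy-input baseline.

## Metrics

SSIM uses an 11×11 Gaussian window (σ = 1.5), `k1 = 0.01`, `k2 = 0.03`, and
windows fully inside the image. The dynamic range defaults to the range of
the two images combined rather than the reference's range: the package
asserts symmetry of the measure in its arguments, which a reference-only
range would break; the range is configurable. SSIM values are reported as
computed (they can in principle be negative; no clamping). NRMSE is RMSE
divided by the reference intensity range by default (mean and RMS
normalizers available); the mode is recorded on the result.

Regional metrics extract a 25×25 window centered on each lesion; near
borders the window is shifted just enough to stay inside the grid — a
clamp-shift rather than zero-padding, because padding would inject
artificial structure into similarity scores. The shift depends only on the
center and the image size, so all arms are measured at byte-identical
coordinates. Summary tables report mean ± population SD (a single record
reports SD 0).

## Statistics

The paired Wilcoxon signed-rank test handles zero differences by the Pratt
method (zeros share in the ranking, then drop; `discard` selectable) — the
conservative choice for heavily tied 4-point data. p values are exact by
enumeration over all sign assignments when at most 12 non-zero differences
remain, otherwise a tie-corrected normal approximation with continuity
correction 1 is used (the signed-rank sum moves in steps of ~2). Bonferroni
correction multiplies by the family size and caps at 1; the experiment's
family is the four metric comparisons (whole-image and regional SSIM and
NRMSE).

ICC(2,1) — two-way random effects, absolute agreement, single measure — is
computed from the ANOVA mean squares, with the F-based confidence interval
for that form (the Satterthwaite-style degrees of freedom for the lower
bound). Qualitative labels: below 0.50 poor, 0.50–0.75 moderate, above
0.75 up to 0.90 good, above 0.90 excellent; the shared endpoints 0.75 and
0.90 close the lower band, a documented convention since interval notation
is ambiguous at the boundaries. A table with zero variance everywhere
yields a flagged degenerate result rather than a number.

## Experiment design

`run_experiment()` evaluates all `n_cases = 30` cohort cases against their
own std arm and trains the denoiser on a *disjoint* training cohort
(`n_train_cases = 12`, itself split 80/20 train/validation by case). The
alternative — carving the held-out set out of the 30 — was rejected on
arithmetic grounds: with 6 held-out cases the exact two-sided Wilcoxon floor
is `2/2^6 ≈ 0.031`, which no Bonferroni-corrected comparison can bring under
0.05, so the design could never demonstrate whole-image significance. The
replicated study has the same shape: its network was trained elsewhere
(vendor training data) and all 30 patients were evaluation cases. Every
evaluation case here is likewise held out from training end to end, which
the report manifest records and a test asserts.

Determinism: the master seed derives independent seed streams for cohort
generation, coil maps, noise, patch sampling, and training; a rerun with the
same configuration is bit-identical, and `--seed` in
`scripts/acceptance.R` drives all of them.

Problem sizes used by the shipped runs: 120×120 grid, 30 + 12 cases, 200
Monte-Carlo noise realizations for the noise-uniformity maps, 288 training
patches of 32×32 trained for 18 epochs. These are the package's desk-scale choices; all are
configuration fields.

## Known limitations

* Painted tissue contrast, single slice, no motion or artifact model; the
  degenerate pipeline checks (AF = 1, zero noise) and oracle equivalences
  validate the machinery, not clinical performance.
* Ground-truth coil maps are used for reconstruction; no calibration error.
* The denoiser is small and trained briefly by design; it demonstrates the
  direction of the effect, not state-of-the-art denoising.
* Reader-score simulation in `analysis/05_reader_stats.R` is labeled
  synthetic: it exists to exercise the ordinal statistics layer, not to
  emulate human raters.
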