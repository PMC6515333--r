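---
title: "Detecting the left-ventricle myocardium: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the left-ventricle myocardium: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`myodetect` localizes the left-ventricle (LV) region of interest — the
myocardial annulus plus the blood pool it encloses — in short-axis cardiac MR
slices, reporting one axis-aligned bounding box per slice. This vignette
explains each stage of the model, the tunable parameters and their defaults,
what the synthetic phantoms do and do not emulate, and the numerical and
design decisions taken where more than one reasonable choice existed.

## The detection model

The detector is a two-stage region-proposal pipeline with four learned or
engineered components.

**1. Structural-similarity superpixels.** Candidate regions come from a
SLIC-style over-segmentation in which the usual color/space distance is
replaced by `1 - S`, where `S` is a hybrid similarity composed of five
ratio-form factors:

* a *phase-congruency* factor `s_pm`, comparing the dimensionless local
  structure strength `PC(u)` computed with a log-Gabor quadrature filter
  bank — `PC = sum_j E_j / (sum_{n,j} A_{n,j} + eps)`, the ratio of summed
  orientation energies to total amplitude, which lies in [0, 1] and is
  invariant to image contrast;
* an *intensity* factor `s_im` on patch/region means, a *contrast* factor
  `s_cm` on standard deviations, and a *structure* factor `s_sm` on the
  (absolute) normalized cross-covariance, all of the stabilized SSIM ratio
  form `(2ab + c)/(a^2 + b^2 + c)`;
* a *coordinate* factor `s_dm = exp(-alpha * d^2)` with `alpha = 2K/N` by
  default (K regions over N pixels), which keeps clusters compact.

The product `S = s_pm * s_im * s_cm * s_sm * s_dm` (exponents all 1 by
default) scores pixel-to-region similarity during assignment and
region-to-region similarity during the subsequent bottom-up hierarchical
merging, which repeatedly fuses the most similar adjacent pair until `K`
regions remain. Defaults `M = 500` initial superpixels merged to `K = 100`
regions.

**2. Stacked sparse autoencoder (SSAE) features.** Every candidate box is
cropped (with a 1.5x context window, see below), resized to `tau x tau` and
encoded by a stack of sigmoid autoencoders trained greedily layer by layer on
the objective

```
J = (1/n) sum_i 0.5 * ||y_i - x_i||^2  +  (lambda/2) * sum W^2
    + beta * sum_j KL(rho || rho_hat_j)
```

(mean-square reconstruction, quadratic weight penalty, Kullback–Leibler
sparsity on the batch-mean hidden activations), then fine-tuned end to end
with a two-class softmax head on cross-entropy with balanced mini-batches.
Defaults: `lambda = 1e-2`, `beta = 0.3`, `rho = 0.2`; layer stacks
`{3600, 1600, 750, 350}` for `tau = 60` down to `{576, 400, 300, 200}` for
`tau = 24`.

**3. Within-class neighborhood preserved (WCNP) classification.** Encoded
features are mapped through kernel PCA of the centered Gaussian Gram matrix
(`K_ij = exp(-r ||x_i - x_j||^2)`, `r = 2`), and a within-class t-nearest-
neighbor graph (`t = 7`) defines the scatter matrix
`S_w = W' K (I - A)'(I - A) K W`, which penalizes embeddings that break local
same-class geometry. The geometry transform `S = I + eta/(2N) * S_w`
(`eta = 2`) rescales the KPCA coordinates by `S^{-1/2}`, after which a
standard soft-margin linear C-SVM (`C = 0.5`) is solved in the transformed
space. The kernel-form decision rule
`sum_i alpha_i y_i k_c(x_i,.)' W S^{-1} W' k_c(x,.) + b` is algebraically
identical to the transformed-space linear rule; the package computes both and
tests their agreement to 1e-8 — this identity is the core correctness check
of the S-matrix algebra. At `eta = 0` the model degrades exactly to a plain
Gaussian-kernel C-SVM (verified against an independent solver).

**4. MIMO epsilon-SVR box refinement.** Boxes surviving classification and
non-maximum suppression are refined by a multi-output support vector
regressor on the 4-vector box codec
`z = ((x_p - x_a)/w_a, (y_p - y_a)/h_a, w_p/w_a, h_p/h_a)` (ratios, not
logs), fitted in the same WCNP feature space with the epsilon-insensitive
loss `L(u) = (u - epsilon)^2` on the joint residual norm, by iteratively
reweighted least squares (IRWLS) with quasi-Newton weights
`a_i = 2C(u_i - epsilon)/u_i` and a step-halving line search. Only proposals
overlapping the ground truth with IoU above 0.6 train the regressor.

**Training orchestration.** Proposals are labeled positive above IoU 0.5 and
negative below 0.3 (the band between is ignored); one round of hard-negative
mining re-injects background regions that the classifier confidently
misclassifies while overlapping the truth below IoU 0.1, briefly re-fine-
tunes the SSAE and refits the classifier. At detection time the surviving
positives go through NMS at IoU 0.3 and the top-probability box is reported
(probabilities come from a Platt-style logistic map fitted on training
decision values).

## The phantom generator

Real short-axis data is not required: `make_dataset()` renders multi-subject
stacks of synthetic slices with known ground truth. Each slice contains a
bright blood pool (`~0.82–0.95` after normalization) inside a mid-intensity
myocardial annulus (`~0.38–0.5`), papillary-muscle spots inside the pool, a
right-ventricle crescent hugging the annulus, a low-signal lung ellipse,
background tissue, a low-order polynomial multiplicative bias field
(amplitude 5–15% of range) and Rician noise (sigma 0.01–0.05) — the magnitude
noise model of MR. Per-subject radii shrink monotonically from base to apex
(factor 1 down to 0.5 across the stack), so apical slices carry small,
ill-defined targets; "mid-stack" denotes the basal 60% of a stack.

Two generator choices deserve justification:

* *Relative heart size.* The basal epicardial radius is drawn as a fraction
  0.095–0.155 of the image side (images are 128–192 px square by default),
  spanning 12–40 px absolute. Drawing radius and image size independently
  produces hearts filling ~40% of the field of view, which short-axis
  acquisitions do not show, and which no fixed region budget could cover.
* *What the phantoms do not emulate*: cine motion, long-axis views,
  scanner-specific artifacts, trabeculation texture, pathology, or
  neighboring anatomy beyond the RV and lung. Passing the phantom benchmark
  therefore demonstrates that the pipeline's stages compose correctly and
  that the learned components generalize across subject geometry, intensity,
  bias and noise variation — not clinical performance on real scanners.

## Numerical choices and degenerate inputs

* **Log-Gabor bank.** 4 scales, 6 orientations, smallest wavelength 3 px,
  scale multiplier 2.1, radial log-Gaussian bandwidth ratio 0.55, angular
  sigma `0.6 * pi / n_orientations`; filters are one-sided in orientation so
  the inverse transform yields the even/odd quadrature pair; the DC bin is
  forced to zero.
* **Phase congruency floor and saturation.** The energy/amplitude ratio is
  0/0 on flat regions; a floor of 1e-4 is added to the denominator. Without a
  noise-compensation term the ratio saturates wherever the few active scales
  agree in phase, however weak the response — sharp edges are still the
  per-image maxima, but weak-structure pixels do not score near zero. The
  classical noise-energy compensation is available behind
  `phase_congruency(..., noise_comp = TRUE)` and off by default.
* **Patch statistics** use the `d - 1` denominator and mirror padding at
  borders; images are min-max normalized per slice so the SSIM-style
  constants `c1..c4 = 1e-4` are comparable across scanners. The structure
  factor takes the absolute covariance and clips to [0, 1] (perfect
  anti-correlation counts as structural agreement); in region mode, where
  regions differ in size, it correlates 32-bin intensity histograms instead
  of pixel vectors.
* **Superpixel iteration.** At most 10 assignment sweeps, convergence when
  fewer than 0.1% of pixels change label; stranded fragments are relabeled
  to the dominant adjacent region; merge ties break on the lexicographically
  smallest region-id pair, so the merge sequence is deterministic.
* **KPCA floor.** Components with Gram eigenvalue below 1e-10 of the maximum
  are numerical null space and dropped; coefficients are scaled to unit
  feature-space norm. Centering uses the standard double-centering
  `H K H`; because a soft-margin SVM with bias is translation invariant in
  feature space, centering does not change predictions — which is exactly why
  the eta = 0 degradation to an uncentered-kernel reference SVM holds.
* **Graph symmetrization.** Row normalization of the within-class adjacency
  breaks the symmetry the scatter construction expects; `(A + A')/2`
  restores it with minimal distortion. Duplicate points (zero distance) get
  a guarded denominator.
* **IRWLS.** Convergence at relative objective change below 1e-6 (200
  iterations by default); when the reweighted step is not a descent
  direction the solver falls back to a backtracking gradient step on the
  true objective, so it only stops at stationary points. With all residuals
  inside the epsilon zone and `B = 0` the solution is exact and refinement
  predicts the bias vector.
* **Degenerate detections.** If no proposal clears the probability cutoff
  the result is an empty, flagged detection; decoded boxes are clipped to
  the image frame and size factors floored at a small positive value.

## Design decisions in the open parts

* **Star unions in the proposal stage.** Tight boxes of single regions and
  of unions of adjacent *pairs* cannot span a ring-shaped target once the
  annulus fragments into three or more arcs, which at `K = 100` it regularly
  does. The proposal stage therefore also emits each region's closed
  neighborhood (the region united with all its adjacent regions): the blood
  pool's closed neighborhood is exactly the LV ROI. With pairs only, the
  best-proposal coverage at IoU 0.5 plateaued near 90% on mid-stack phantom
  slices; with star unions it is complete, at the cost of at most `K` extra
  candidates.
* **Context padding of crops.** Crop windows are enlarged 1.5x around each
  candidate box before resizing, so surrounding tissue is visible in the
  corners. Without context, the right-ventricle crescent — a bright pool
  with its own rim — is indistinguishable from the LV at `tau = 24`, and
  papillary-bounded pool fragments mimic a complete small ventricle.
* **Unit-norm features.** SSAE features feeding the Gaussian kernel are
  L2-normalized per sample. Raw 200-dimensional sigmoid features sit at
  squared distances around 4, so `exp(-2 d^2)` collapses the Gram matrix to
  near-identity and the classifier memorizes; on the unit sphere the kernel
  distances fall in an informative range for the default `r = 2`.
* **Selecting epsilon.** The insensitivity zone is dimensionful — it lives
  on the scale of the box-codec residual norm, which for jittered anchors is
  well below 1. A fixed `epsilon = 1.5` exceeds the entire target spread, so
  every residual falls in the dead zone and refinement degenerates to a
  constant shift. The package therefore treats `epsilon = NULL` as "select
  from the candidate grid {0.01, 0.5, 1, 1.5, 2} on a held-out fifth of the
  regression anchors, by the refined-box IoU" (phantom training selects
  0.01); any numeric value fixes it instead.
* **Negative sampling.** Training caps are met by sampling negatives in two
  strata — half from near-misses (IoU >= 0.05 with the truth, including RV
  lookalikes), half from background — for both the SSAE and the classifier
  sets; sampling is deterministic under the training seed.
* **Overlap ratio.** The overlap index is reported in two variants: the
  detection-literature form `2|A n B| / |A u B|` (twice the IoU, clipped at
  1 when reported) and the classical Dice `2|A n B| / (|A| + |B|)`; both
  appear in evaluation reports, and plots should prefer the classical form.
* **AUC units of analysis.** Threshold sweeps are reported at two levels,
  labeled distinctly: per-proposal probabilities against proposal labels
  (`proposal_auc`), and per-slice top-box probability against slice hit/miss
  at IoU 0.5 (`AUC` in `evaluate_detections`, `NA` when all slices agree).

## Problem sizes used in the shipped experiments

The test suite exercises the full pipeline on a 60-subject phantom benchmark
(40 training, 20 held-out subjects, 5 slices each) with the `tau = 24` layer
stack `{576, 400, 300, 200}`, capped at 2000 pretraining crops, 1000
classifier samples before mining and 400 regression anchors; unit and
property tests run on 64–128 px images, toy kernels of 20–100 points and
autoencoder layers of tens of units. `scripts/acceptance.R` trains on 20
subjects x 4 slices and evaluates on 10 held-out subjects, reporting the
detection rate, pixelwise precision/recall/F1, overlap ratios, proposal
coverage, proposal-ranking AUC and the refined-versus-unrefined mean IoU.
These sizes were chosen so a complete run is a workstation-scale experiment;
every reported number is recomputed at run time.

## Known limitations

* The phantom benchmark bounds what the tests can claim about real cardiac
  MR (see above); no claim is made about CAP-scale clinical performance.
* The pipeline is single-object by construction: one box per slice, no
  multi-structure detection and no temporal (cine) modeling.
* The within-class graph requires `t` below the smallest class size, and the
  regressor needs at least ~10 high-IoU anchors; tiny training sets fall
  back to an unrefined detector with a warning.
* Phase congruency as implemented (without noise compensation) is a
  structure detector, not a noise-robust edge detector; on very noisy slices
  the similarity relies more on the intensity/contrast/histogram factors.
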