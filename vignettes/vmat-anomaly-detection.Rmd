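---
title: "Reconstruction-based anomaly detection for VMAT treatment plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction-based anomaly detection for VMAT treatment plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vmatqa)
```

## The problem

Volumetric modulated arc therapy (VMAT) delivers radiation while the gantry
rotates continuously. A plan is specified as arcs of control points (CPs),
each holding the gantry angle, the positions of two opposing banks of
multi-leaf-collimator (MLC) leaves, and a per-CP meterset (MU). Because a
two-arc plan carries thousands of machine parameters, the routine physics
plan review — the manual chart check that catches transcription and
planning errors before treatment — is laborious and rule sets written for
static-field techniques do not transfer well.

`vmatqa` automates this check as one-class (unsupervised) anomaly
detection: a model is trained only on plans that passed review, and a plan
whose reconstruction error is unusually large is flagged. No labelled
anomalies are needed for training; labels enter only through threshold
calibration and evaluation.

## From control point to feature map

Each CP is digitized on a uniform grid over the MLC field. Rows follow the
leaf-index axis (each physical leaf pair is replicated onto
`round(width / resolution)` contiguous rows; no sub-row interpolation),
columns follow the travel axis. A pixel of the aperture map $A_k$ is 1
exactly when its column center lies strictly inside the open interval
between the pair's left and right leaves; a closed pair contributes
nothing. The intensity (fluence) map is $I_k = D_k A_k$ with $D_k$ the
per-CP meterset, so it carries geometry and dosimetry in one image.

At the reference resolution of 0.1 mm a 300 mm-wide field yields 3000 leaf
indices and a 400 mm travel range 4000 position indices — far too large as
a network input. The package therefore rasterizes on a
configurable grid and block-averages down to the network input
(default 64x64): the aperture by open-area fraction binarized at 0.5, the
intensity by the block mean (equal to dose times open-area fraction, so
the map mean is conserved exactly). The default raster pitch is chosen so
the grid is an integer multiple of the target — 1.25 mm for the default
machine (40 pairs of 1.0 cm leaves, 400 mm travel), giving a 320x320 grid
and 5x5 blocks. Semantics are unchanged by the pitch; tests verify the
rasterizer against a per-pixel brute-force oracle and the area
conservation against leaf-interval arithmetic.

## The models

The core model is a multi-task convolutional autoencoder. The encoder maps
$I_k$ through four down-convolution blocks (3x3 stride-2 conv, then 3x3
stride-1 conv, each with batch normalization and ReLU) and one linear
block to a latent vector $h$ (default length 32). Two decoders read $h$:

* an aperture decoder (linear block, four up-convolution blocks of a
  stride-2 transposed conv plus a stride-1 conv, and a 3x3 1-channel head
  with sigmoid output) reconstructing $A_k$ as probabilities $A'_k$;
* a dose decoder (three linear blocks and a scalar head) reconstructing
  the normalized dose $D'_k$.

Training minimizes
$L_R = \lambda\,L_A + L_D$, where $L_A$ is the mean binary cross-entropy
between $A$ and $A'$ (probabilities clipped to $[10^{-7}, 1-10^{-7}]$) and
$L_D$ the mean squared error on the normalized dose, with Adam at learning
rate $10^{-3}$. $\lambda$ defaults to 1. Doses are normalized by the
training-set maximum; the factor is stored in the model and used to
assemble the reconstructed intensity $I' = D' A'$ on the MU scale.

Three classical baselines share the encoder topology with a single
intensity decoder: a vanilla autoencoder (plain MSE), a contractive
autoencoder adding $\gamma\,\lVert \partial h/\partial x \rVert_F^2$, and
a variational autoencoder whose encoder emits $(\mu, \log\sigma^2)$ and
which adds $\beta\,KL(N(\mu,\sigma^2)\,\Vert\,N(0,1))$ with reparameterized
sampling during training (the closed form
$-\tfrac12\sum(1+\log\sigma^2-\mu^2-\sigma^2)$ is used, and the latent
parameters come from a plain linear layer since they must be sign-free).

### Implementation notes

The networks are implemented in the package itself: im2col-based
convolution and transposed-convolution primitives in RcppArmadillo
(single-precision internally — the patch matrices dominate memory traffic
and fp32 is far below the optimization noise floor), batch normalization
kernels, and an R training loop with Adam. All layer gradients are checked
against central finite differences in the development suite, and the
training loop is bit-reproducible under a fixed seed and thread count.

Several numerical choices matter:

* Channel widths default to 4/8/16/32 with a half-width full-resolution
  block — the block widths are free parameters, and these are the
  smallest that pass the single-CP overfit test at 64x64 while training
  the full benchmark on one CPU core.
* Pre-ReLU linear layers are initialized with a small positive bias
  (0.1); with zero bias the narrow latent bottleneck frequently starts
  dead (all-zero ReLU output) and cannot recover.
* The aperture loss is the standard non-negative binary cross-entropy
  (with the conventional leading minus sign), as minimizing a
  reconstruction error requires.
* Batch normalization uses batch statistics in training and running
  averages (momentum 0.9) at inference.
* The contractive penalty's gradient is computed without an autodiff
  framework: a single Rademacher probe gives an unbiased Hutchinson
  estimate of the Jacobian Frobenius norm via a hand-derived tangent
  (JVP) pass, and the backward pass through that tangent treats ReLU
  masks and batch-norm statistics as locally constant (exact almost
  everywhere for ReLU; a standard stop-gradient for the statistics). The
  penalty value itself is verified against a finite-difference Jacobian
  on a small encoder.
* The training sample unit is the control point; plan-level scores are
  aggregated afterwards. An "epoch" is one pass over every CP of the
  training plans.

## Scoring and thresholding

For a plan of $K$ CPs the detector computes three distances between the
original and reconstructed quantities:

* $d_I$: mean squared intensity error, normalized per pixel
  ($\tfrac1{K M N}\sum_k\sum_{ij}(I-I')^2$). A per-CP form that
  normalizes only by $K$ is sometimes used; the per-pixel form is chosen
  so values are comparable across input resolutions and consistent with
  the BCE normalization.
* $d_A$: the BCE form of the aperture loss;
* $d_D$: the MSE of the (denormalized) doses.

Baseline models populate only $d_I$. Aperture probabilities enter $I'$
continuously; no binarization.

The detection threshold $\alpha$ can be calibrated two ways. The
`oracle_fnr0` policy implements the clinical never-miss rule — the
largest observed score value for which no labelled anomaly falls at or
below it (classification is strictly `score > alpha`, so ties are
regular), with a fallback just below the smallest anomaly score when the
classes fully overlap. Because a zero-FNR rule needs anomaly labels that
a training set of regular plans cannot supply, a deployable label-free
`quantile` policy (nearest-rank quantile of regular scores, default
q = 0.99) is provided as well; the evaluation protocol applies
`oracle_fnr0` to the labelled test scores.

## The synthetic cohort

No clinical dataset is distributable, so the package generates one with
the structure the method assumes: two full arcs of 90 CPs (4 degree
spacing), 40 leaf pairs, per-CP metersets from a truncated normal
(default mean 3 MU, CV 0.3), and leaf trajectories built from a per-plan
elliptical aperture envelope (width, vertical extent, and a slow
sinusoidal drift of the aperture center drawn per plan) plus smoothed
Gaussian noise, projected CP-by-CP onto the machine's travel, speed and
gap limits. The projection guarantees that every regular plan passes
`validate_plan()`; a property test sweeps this exhaustively.

Anomalies are injected into otherwise-regular plans as one of six labelled
fault kinds — a leaf pair jumping far beyond the speed limit, crossed
leaves, swapped banks, a meterset spike, a meterset dropout, and a
collapsed aperture. Magnitudes default to gross, human-reviewable faults
(the jump is 5x the per-CP speed limit, the spike 10x the mean dose),
since no clinical severity distribution is available to calibrate against. Each fault affects a
contiguous window of CPs (`span`) confined to one arc; the default window
is the entire arc — the taxonomy models a corrupted arc record — except
for the leaf jump, which switches on mid-arc (half an arc, so the
speed-violating transition is part of the record), and the dose spike,
which is a single-meterset transcription error. A
plan-mean distance dilutes a fault by the fraction of the plan it
touches, so window size, more than magnitude, decides how visible a fault
can ever be to a plan-level score; `span` is exposed for sensitivity
studies. The default desk-scale benchmark is 200 regular plus 20
anomalous plans — the clinical 652:25 imbalance is reachable through
configuration but is not the default.

What the simulator does *not* emulate: optimizer-driven aperture
sequences, anatomy- or dose-distribution realism, delivery-time effects,
or the (unknown) phenotypes of clinical anomalies. Passing the synthetic
benchmark therefore demonstrates that the pipeline can learn the
simulator's regular population and flag gross injected faults — not
clinical performance.

## Evaluation protocol

The regular plans are split into five folds (sizes differ by at most
one). Each fold's model trains on the other four fifths — anomalies never
enter training — and is tested on the held-out regular fifth plus every
anomalous plan — an 80/20 design with the anomalies confined to the
test side.
AUC uses the tie-aware rank (Mann-Whitney) formulation, cross-checked in
tests against an $O(n^2)$ pairwise oracle and against the trapezoidal
integral of the ROC sweep; accuracy, precision, recall, FPR, FNR and F1
follow the textbook formulas with zero-denominator ratios reported as
missing rather than zero. Per-fold metrics are aggregated as the
across-fold mean, which is the headline aggregate. `run_experiment()` drives the whole pipeline from one
config into one artifact directory — plan JSONs, manifest, tensors,
four checkpoints, score tables, the 3-distances-x-1-model and
4-models-x-d_I metric grids, and ROC/box-plot figures — and a rerun with
the same config reproduces every numeric artifact.

Problem sizes used by the packaged tests: the unit suite runs on a 4-pair
toy machine at 16x16 maps; the reference benchmark uses the default
machine at 64x64 with 200+20 plans, two training epochs (the package's
CPU budget; more epochs tighten reconstruction but, see below, do not
change what a one-sided score can detect) and three seeds. These sizes
are the package's chosen desk-scale benchmark conditions.

## Known limitations

* **Reconstruction-error scores are one-sided.** $d_I$ grows when the
  input contains intensity the model cannot reproduce; it *shrinks* when
  the input loses intensity, because an autoencoder reconstructs a
  near-empty map with near-zero error (low-meterset CPs are part of the
  regular population, and the multi-task reconstruction
  $I' = D'A'$ scales with a dose head that regresses on input
  magnitude). Four of the six fault kinds in the simulator — crossed
  leaves, swapped banks, meterset dropout, collapsed apertures — remove
  intensity, and therefore rank *below* the regular plans; training
  longer makes this cleaner, not better. The packaged benchmark
  (`detection_benchmark()`, recomputed by `scripts/acceptance.R`) shows
  this directly: the multi-task AUC under $d_I$ on the uniform fault mix
  sits far below the separability one would infer from the
  energy-*adding* faults (the meterset spike) alone. Detecting removal
  faults needs a two-sided or per-CP-normalized score, which is outside
  the method reimplemented here.
* The plan-level distances are raw means over CPs and pixels, so a plan's
  score scales with its aperture area and meterset; heterogeneous
  populations therefore set a floor on separability that better
  reconstruction cannot remove.
* Geometry faults that violate hard machine limits are already caught by
  `validate_plan()` — deterministic physics checks remain the first line;
  the autoencoder targets what rule checks miss.
* No per-CP anomaly localization or root-cause attribution is attempted.
* DICOM-RT ingestion is out of scope; plans enter through the documented
  JSON interchange format.
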