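---
title: "CEUS liver-lesion classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CEUS liver-lesion classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Contrast-enhanced ultrasound (CEUS) records the transit of a microbubble
bolus through the liver in real time. Radiologists diagnose focal liver
lesions from the enhancement pattern across three phases anchored at bolus
arrival: the arterial phase (AP), the portal-venous phase (PVP) and the late
phase (LP). Malignant lesions typically hyperenhance in the AP and then
*wash out* — fall below the surrounding parenchyma — in the PVP/LP, whereas
most benign lesions enhance and sustain. `ceusdx` implements a complete
computer-aided pipeline around this signal: ROI extraction from clinician
axis markers, time–intensity-curve (TIC) bolus-model fitting, out-of-plane
frame rejection, phase-aware mini-loop sampling, a CNN-LSTM video
classifier with majority-vote case aggregation, and a TIC-feature
gradient-boosted-tree baseline, plus a ground-truthed synthetic cine-loop
generator so everything is testable without clinical data.

## Indicator-dilution TIC models

The lesion TIC is the mean grayscale intensity of the ROI per frame. Five
classical bolus-transit families are fitted, each with a delay `t0`, an
additive baseline and a total area `auc` (`t' = t − t0`; the curve equals
the baseline for `t ≤ t0`):

* **lognormal** — `auc · dlnorm(t'; μ, σ)`; mode `exp(μ − σ²)`, mean
  `exp(μ + σ²/2)`.
* **gamma-variate** — `A t'^α e^{−t'/β}` with
  `A = auc / (β^{α+1} Γ(α+1))`; mode `αβ`, mean `β(α+1)`.
* **LDRW** (local density random walk) —
  `auc/μ · √(λμ/2πt') · e^{λ − (λ/2)(t'/μ + μ/t')}`; mean `μ(1 + 1/λ)`.
* **FPT** (first passage time) — an inverse Gaussian with mean `μ` and
  shape `λμ`.
* **lagged normal** — a Gaussian `(μ_g, σ_g)` convolved with an
  exponential `e^{−t/τ}/τ`, evaluated through the closed-form
  exponentially modified Gaussian; mean `μ_g + τ`.

Fitting is bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) from a coarse multi-start grid seeded by data
heuristics: onset candidates from quantiles of the rising edge, scale from
time-to-peak, plus half/double time-to-peak variants. Among converged
starts the lowest residual sum of squares (RSS) wins; `fit_best_model()`
repeats this for all five families and keeps the overall RSS argmin, with
exact ties resolved in the fixed family order. RSS is used as the
estimation error because it is the native least-squares criterion. The
baseline is a free parameter bounded by `[0, min intensity + 10% of the
dynamic range]`. Intensities are used as stored; no log-decompression is
applied.

Two numerical points deserve note. First, LDRW, FPT and the lagged normal
can reproduce each other's noiseless curves almost perfectly, so the
*label* of the winning family is not identifiable — all curve-level
quantities (AUC, peak, MTT) are, and tests assert those, not labels.
Second, the lagged normal carries its transit delay inside `μ_g`: `t0` and
`μ_g` trade off freely once the Gaussian leading edge clears zero. Its
onset is therefore defined as the identifiable quantity
`t0 + μ_g − 3σ_g` (the effective arrival of the leading edge), and its MTT
is measured from that onset. Fit bounds keep LDRW/FPT in a regime
(`λ ≥ 0.2`, `μ ≤ 2·t_end`) where the extrapolated tail beyond the
observation window stays physically plausible.

The seven derived parameters are: onset time, peak time (closed-form mode
where available, dense grid plus golden-section refinement otherwise),
peak intensity above baseline, AUC (the fitted area parameter), mean
transit time (closed-form first moment), wash-in gradient (chord slope
from onset to peak) and wash-out gradient (least-squares slope of the
fitted curve from the peak to the last observed time; `NA`, imputed 0 for
the classifier, when the peak falls at or beyond the window end). The
wash-in/wash-out definitions are fixed conventions of this package — the
clinical literature names but rarely defines them.

## Preprocessing

* **ROI.** The four axis-marker points bound the lesion; the box is
  expanded 50% about its centre (absorbing respiratory excursion), rounded
  outward and clipped to the contrast panel. Coordinates are 0-based,
  `(x = column, y = row)`, boxes half-open.
* **Frame rejection.** A frame is kept iff
  `|mean intensity − fitted TIC| ≤ 2 · sd(all frame means)`, the threshold
  inclusive. The standard deviation is loop-global — the literal reading of
  the rule — not residual-based. Frames pushed off-plane by respiration
  lose enhancement abruptly and show up as large negative residuals.
* **Phases.** AP `[onset, onset+30 s)`, PVP `[onset+30, onset+120)`,
  LP `[onset+120, end]`, the standard liver CEUS convention (configurable);
  onset is the fitted `t0` of the best bolus model. Loops shorter than
  45 s are excluded outright.
* **Mini-loops.** `F` (default 4) anchors per phase at equal intervals —
  forward from the AP start, *backward* from the PVP and LP ends, because
  the final seconds of those phases carry the washout evidence. Mini-loop
  `j` of `M` (default 3) shifts every anchor by `j·interval/M` into its
  phase and snaps to the nearest kept frame (ties to the earlier frame;
  duplicates resolved by next-nearest substitution). Crops are resized to
  the model input size with bilinear interpolation (`EBImage::resize`).
  The shift scheme is this package's concrete reading of "split into
  multiple mini-loops": it yields `M` deterministic, near-disjoint temporal
  samples per loop.

## The CNN-LSTM classifier

Each of the `3F` crops passes through a convolutional backbone; the
feature sequence is smoothed by temporal adaptive pooling to 3 steps (one
averaged feature per phase, which also damps residual respiratory
jitter), then a two-layer LSTM — first layer bidirectional, hidden size
128; second layer unidirectional over the 256-dim concatenation — followed
by average pooling over the LSTM outputs, a linear layer and a sigmoid.
Training is mini-batch SGD (batch 16, heavy-ball momentum 0.9) on binary
cross-entropy for 6 epochs, learning rate 0.01 for epochs 1–4 and 0.001
thereafter. Pooling LSTM outputs (rather than taking the final hidden
state) is the fixed design choice; layer-2 directionality is
unidirectional.

Two backbones are available. `resnet18_frozen5` denotes a residual network
initialised from externally supplied image-classification pretraining with
its first 5 parameterized layers frozen; the package bundles no pretrained
weights, so selecting it requires a caller-provided weight tree.
`small_cnn` — three 3×3 conv/ReLU/2×2-max-pool blocks (16, 32, 64
channels), global average pooling, feature dimension 64 — is randomly
initialised and trains on a plain CPU; it is the backbone used throughout
the tests and studies. `freeze_prefix_layers` freezes the first *n*
parameterized modules of either backbone in forward order.

All network primitives (im2col convolution, pooling, LSTM cells, layer
normalisation) are implemented natively with hand-written backward passes,
pinned by finite-difference gradient tests. Two parameter-free layer
normalisations — on each pooled phase feature entering the LSTM and on the
pooled LSTM output entering the head — keep activation scales O(1); with a
randomly initialised backbone and only six epochs, training stalls at
chance without them, and momentum-SGD plus input centring to `[−1, 1]`
complete the conditioning. These are architectural choices of this
package, stated here because the short schedule leaves no room for warmup.

Per-case prediction: each mini-loop votes malignant iff its probability
reaches the threshold (default 0.5); the case label is the majority, an
even split resolving by the mean probability; the case-level score used
for ROC analysis is the mean mini-loop probability.

## The TIC baseline

The seven perfusion parameters plus lesion size form an 8-vector fed to
gradient-boosted decision trees (`xgboost`; 200 rounds, depth 3, learning
rate 0.1 — unstated in the source method, fixed here and overridable).
Both classifiers consume the same preprocessing output and identical
stratified case-level folds, so the in-package comparison
(`compare_methods()`) is like for like.

## Evaluation

`sens_spec()` and `roc_auc()` implement the standard definitions; the AUC
is the trapezoidal area over the tie-grouped threshold sweep and equals
the Mann–Whitney statistic (asserted to 1e-12 against a pair-counting
oracle). Cross-validation is stratified *by case*: folds are dealt
round-robin within each class after seeded shuffling, and every mini-loop
inherits its case's fold, which structurally excludes case-level leakage.

## The synthetic generator

`sample_case_spec()` draws class-conditional kinetics:

* **malignant** — lognormal lesion bolus, onset 6–10 s, peak 90–120
  (0–255 grayscale) at 8–14 s post onset, `σ ∈ [0.45, 0.65]`: arterial
  hyperenhancement with washout below parenchyma throughout the LP;
* **benign** — slow gamma-variate (`α ∈ [0.03, 0.08]`,
  `β ∈ [3000, 5000]` s), plateau 55–75: fast early enhancement sustained
  to the end, late-phase slope below 0.02 intensity/s, never dropping
  below parenchyma;
* **parenchyma** (both classes) — the same sustained family at plateau
  30–45, onset 1–3 s after the lesion.

Rendering composes, per frame: lesion-ellipse and background kinetics, a
static multiplicative tissue texture (CV 0.03) that moves with the tissue,
a vertical sinusoidal respiratory translation (1–3 px, 3–5 s period),
temporal multiplicative speckle (mean-1 Gaussian, CV 0.05), whole-panel
intensity dropout on designated out-of-plane frames (retaining 60%), and
8-bit quantisation; the B-mode half is a static texture. The default panel
is 192×256 per side (a scaled-down version of the 960×1280 dual-display
clinical geometry); studies use 96×128 at 0.5–1 Hz for CPU speed. Speckle
is modelled as multiplicative Gaussian rather than Rayleigh and no
acoustic or microbubble physics is simulated — the generator exercises the
pipeline's contracts (kinetic contrast, dropout detectability, motion
jitter, quantisation), not image realism, so passing tests demonstrate
correct mechanics and learnability of kinetic differences, not clinical
performance.

The *dropout phantom* used by the frame-rejection study narrows the spec
to sustained kinetics with onset 3–5 s over 240 s at 0.75 Hz and injects 5
dropout frames sampled after `onset + 20 s`. A stable plateau isolates the
2σ rule from washout dynamics: on a decaying malignant TIC the loop-global
standard deviation is inflated by the bolus itself and a 40% dropout can
hide inside 2σ — a property of the rule as literally specified, not of
this implementation. Dropouts before contrast arrival would have no
enhancement to lose, hence the sampling window.

## Study sizes and reproducibility

The bundled studies use: 5×20 noiseless fits for parameter recovery
(tolerance 1%); 100 phantom loops × 5 dropouts for rejection (≥99%
rejected, ≥95% clean kept); a 60-case cohort (30/30, `small_cnn`, 32×32
crops, F=4, M=3, 6-epoch schedule) for end-to-end learnability with one
stratified fold held out, median AUC over 3 seeds; and a 200-case
TIC-feature cohort (5% label noise) for the boosted baseline with a
shuffled-label null control. Every stochastic element — spec draws,
rendering noise, fold deals, weight init, batch shuffling, booster — is a
pure function of an explicit seed, and dataset generation is
byte-reproducible. These sizes are the package's desk-scale defaults; all
are parameters.

## Known limitations

* No in-plane motion tracking or registration: motion is handled only by
  box expansion and frame rejection, as in the source pipeline.
* The five-family fit extrapolates beyond the observation window when a
  sustained curve is observed; AUC/MTT of such fits describe the fitted
  model, not the (unobserved) full transit.
* The synthetic generator's benign/malignant contrast is deliberately
  clean; real cohorts contain subtypes whose kinetics overlap, so
  synthetic AUCs near 1 say nothing about clinical accuracy.
* `resnet18_frozen5` requires external pretrained weights; the package is
  fully functional without it via `small_cnn`.
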