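---
title: "Methods: transformer-based classification of swallowing fluoroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transformer-based classification of swallowing fluoroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A videofluoroscopic swallowing study (VFSS) records a patient swallowing
radio-opaque boluses under continuous X-ray. Clinicians review these clips
frame by frame for airway invasion — bolus material entering the laryngeal
vestibule or trachea. `vfssvit` implements a fully automated pipeline for
this review: standardized cleaning of the raw fluoroscopy video, a vision
transformer that classifies a whole variable-length clip as normal or
abnormal from a single study-level label, and attention-rollout saliency
maps that show *where* the model looked.

Because clinical VFSS data are private, the package ships a synthetic
phantom generator that emulates the structural properties of real clips and
plants a controllable invasion signature. Everything downstream — the
preprocessing detectors, the transformer, the evaluation protocol, the
saliency maps — is exercised end to end on these phantoms.

## Preprocessing pipeline

`run_pipeline()` composes five deterministic stages, applied identically to
training and test clips:

1. **Information-band crop.** Clinical recorders burn a static text band
   into the frame. On the temporal-mean frame (the overlay is static while
   anatomy moves), the row with the maximal mean absolute horizontal
   Prewitt response inside the top/bottom 20% of rows marks the band edge;
   no crop is applied when the response stays below a floor of 0.1
   (normalized intensity). On phantom fixtures the crop lands within one
   row of the true band edge.
2. **Targeting-artifact removal.** Early frames often carry a circular
   alignment marker. A gradient-direction circle Hough transform over the
   first 10 frames proposes a center; an algebraic least-squares circle fit
   on the edge inliers refines it. Detection requires edge support of at
   least 0.6 per unit perimeter, residual spread below 1.5 px, angular
   coverage of at least 70%, and a bright-ring/dark-interior contrast —
   the last gate is what separates the open ring of a targeting artifact
   from a filled bolus blob. The detected disk, dilated by 2 px, is filled
   by harmonic (diffusion) inpainting in every frame whose ring-edge
   response persists. Absence of the artifact is not an error.
3. **Resolution unification.** Frames below the target size are zero-padded
   symmetrically, larger ones center-cropped, per axis. The target is the
   median corpus resolution, recorded once by `fit_preprocess()` and
   persisted — never recomputed per clip — so training and inference see
   identical geometry.
4. **Field-of-view masking.** Pixels outside the inscribed detector circle
   are set to exactly zero; the mask is reapplied after equalization, so
   the masked region is an exact zero set through the end of the pipeline.
5. **Denoising and equalization.** A bilateral filter (diameter 5 px,
   intensity sigma 0.1 of range, spatial sigma 3 px) precedes CLAHE
   (clip limit 2, 8x8 tiles — common defaults, configurable), followed by
   re-masking and clipping to [0, 1].

The pipeline records its geometry (crop rows, padding offsets) so that any
pixel mask defined on the raw frames — for instance the phantom's planted
invasion region — can be mapped into model coordinates with
`transform_mask()`.

## The model

The clip is cut into non-overlapping 3D patches of `Tp` frames by `P x P`
pixels; the clip is zero-padded at the end to the next multiple of `Tp`,
so the token count is `N = T/Tp * (H/P) * (W/P)`. Each flattened patch is
projected to a `D`-dimensional embedding, a learnable class token is
prepended, and learnable positional embeddings are added. Tokens are
enumerated in `(t, h, w)` row-major order and patches flattened with the
spatial column fastest; positional-embedding semantics depend on this
fixed order, which is documented in `extract_patches()`.

The encoder is `L` pre-norm transformer layers: multi-head self-attention
(scale `1/sqrt(D/h)`) and a position-wise FFN (hidden width `4D`, ReLU),
each wrapped in a residual connection with layer normalization. A final
layer norm feeds the class token into the classification head — by default
an MLP of widths 128 and 64 with ReLU and a sigmoid output (a single
linear head is available via `head_type = "linear"`). Training minimizes
binary cross-entropy in its numerically stable logit form.

Clinical-scale defaults are `Tp = 25` (one second at 25 fps, so one token
spans a complete swallow), `P = 16`, `D = 64`, `h = 8`, `L = 8`, inputs
isotropically resized to 256x256.

### Design choices worth flagging

* **Head reconciliation.** The closed-form description of the classifier
  is a single linear logit layer, while the stated hyperparameters specify
  an MLP head of widths 128 and 64. We implement the MLP head as the
  default — it describes the trained system — and keep the linear head as
  a config option.
* **Initialization.** Projections use fan-in-scaled (LeCun/Xavier-style)
  truncated normals; the positional table uses sd 0.02; biases and the
  class token start at zero. Fan-in scaling matters: with a fixed small
  sd (0.02) the attention logits start at order 1e-2 and their gradients,
  quadratic in the signal, leave the encoder on a chance-level plateau
  for thousands of Adam steps. With fan-in scaling an 8-clip batch is
  overfit to near-zero loss within a few hundred steps, which is what
  makes the desk-scale experiment below tractable on a CPU.
* **Temporal windows.** The patch-count formula implies non-overlapping
  windows, so the default stride equals `Tp`; the stride is exposed as a
  config knob.
* **Positional capacity.** The positional table is sized for the longest
  training clip; a longer clip at prediction time raises an explicit
  capacity error rather than being silently truncated.
* **Compiled attention.** The quadratic attention maps dominate training
  time and run as RcppArmadillo kernels, computed and cached in transposed
  (column-softmax) layout so every reduction is cache-contiguous. The test
  suite validates them against a plain per-head R loop.
* **Dropout** is not part of the architecture (default 0).

## Training and evaluation protocol

Splits are made at the *subject* level: all clips of one patient land in
exactly one of train/validation/test (defaults 10% test, then 0.8:0.2),
and the same invariant holds across cross-validation folds — the package
asserts this programmatically. Training uses Adam (learning rate 1e-3,
default maximum 200 epochs), batch size 1 with gradient accumulation over
8 clips (variable-length clips make padding-free batching impractical),
and per-clip augmentation on the training set only: rotation within ±5
degrees, zoom up to +10%, additive Gaussian noise (sd 0.01), each applied
independently with probability 0.5. Per-step gradients are clipped to a
global norm of 5 (configurable): small-batch transformer training emits
rare huge gradients at the moment the loss starts to fall, and a single
unclipped step at that moment can destroy the emerging solution — we
observed exactly this failure, a breakthrough epoch followed by a
permanent return to chance, before adding the ceiling.

At desk scale the package's stated protocol uses gradient accumulation 2
rather than the clinical-scale default of 8: with 140 training clips,
accumulation 8 yields only ~17 updates per epoch, so the optimizer is
still in its warm-up plateau when patience expires; accumulation 2 gives
70 updates per epoch, comparable per-epoch update counts to the
clinical-scale protocol, and seed-robust convergence.

Transformer warm-up length is itself a random variable of the
initialization, and occasionally outlasts any reasonable patience window.
`vfss_vit()` therefore applies a multi-start rule, the standard treatment
of a nonconvex fit (compare `kmeans(nstart = )`): when a finished run's
*best* validation loss never left chance level (above 0.6 BCE), training
restarts with a deterministically re-derived seed, up to `restarts` times
(default 2), and the run with the lowest validation loss is kept. A failed
warm-up is cheap — patience terminates it within a dozen epochs — so the
expected overhead is small, and every restart seed derives from the single
top-level seed, preserving reproducibility.

Early stopping follows the minimum-validation-loss rule: the returned
parameters are always the state at the epoch of minimum validation loss,
never the final epoch. The patience counter (default 10 epochs) only
resets on improvements larger than `min_delta` (default 1e-3 BCE): on
clean synthetic data the validation loss otherwise keeps creeping down by
~1e-4 per epoch indefinitely and a plain patience rule never terminates.

`metrics_report()` computes the confusion counts at the decision
threshold (default 0.5), accuracy, sensitivity, specificity, precision
and F1, the ROC by threshold sweep, and the AUC by the trapezoidal rule —
tested to equal the normalized Mann-Whitney statistic to 1e-10.
`paired_t_test()` compares per-fold metric vectors, with explicit flags
for the zero-variance degenerate cases.

## Attention-rollout saliency

For one clip we collect every head's attention matrix at every layer and
multiply residual-aware per-layer matrices recursively; the class-token
row, restricted to patch tokens and normalized, attributes the decision
to input patches. The default is the head-averaged rollout with residual
identity mixing, `A_bar = normalize(0.5 mean_h A + 0.5 I)`; a
gradient-weighted variant (`method = "grad"`,
`A_bar_l = normalize(I + mean_h (dlogit/dA * A)^+)`) is exposed as well.
On trained desk-scale models we found the plain rollout to localize the
planted abnormality clearly better and more consistently than the
gradient-weighted variant — gradient weighting, often recommended when
attention looks uniform, concentrated relevance on decision-aligned but
spatially uninformative tokens here — so the default follows the plain
form.

Each temporal segment's relevance slice is bilinearly upsampled to frame
resolution and min-max normalized. Per-frame weights `omega_t` come from
scoring each `Tp`-frame segment independently with the classifier and
softmax-normalizing its logits. "Independently" is implemented by tiling
the segment to the clip's full length: a lone `Tp`-frame input is far
outside the training length distribution and scores incoherently, and
zero-occluding the other segments breaks the conjunctive evidence the
model accumulates across windows; a tiled segment is length-typical while
containing only that segment's content, and empirically tracks the
invasion onset exactly (pre-onset segments score strongly normal,
post-onset strongly abnormal). The model emits one study-level
probability, so per-segment confidence is the finest classifier-derived
granularity available — a documented choice, not the only possible
reading. The cumulative map
`M = sum_t omega_t m_t` is thresholded at the 90th percentile of values
*inside the field of view* (including the zeroed corners would deflate
the threshold), and the mask is overlaid on a quiescent frame: the first
frame whose mean dense optical flow (Lucas-Kanade, 5x5 window) falls
below 0.5 px, with an argmin fallback when no frame qualifies.

Degenerate cases are handled explicitly: a constant relevance slice maps
to all-zeros (flagged) rather than NaN; if the class token attended only
to itself through every layer, relevance is attributed uniformly.

## The synthetic phantom

`simulate_vfss_study()` renders, per clip: a circular detector field of
view with dark corners; a bright patient-information band across the top
12% of rows; a ring-shaped targeting artifact (radius 5-15% of the frame)
in the first 8 frames; a truncated-Gaussian bolus blob advancing along a
3-segment pharyngeal polyline; and additive Gaussian noise (sd 0.03),
clipped to [0, 1]. Abnormal clips divert a fraction (default 0.5) of the
bolus amplitude into an airway disk offset anteriorly from the path, from
an onset frame sampled uniformly in the middle third of the clip — which
guarantees the signature falls inside at least one temporal patch.
Each subject's anatomy is jittered once by a rigid translation
(sd 1.5 px, clamped at 3 sd) shared across that subject's clips; rigidity
preserves the path/airway separation, so normal clips have *exactly* zero
airway intensity before noise, by construction. Defaults are 40 subjects
of 5 clips at 64x64 px, 30-60 frames, 47.5% abnormal — a scale chosen so
the full study (generation, preprocessing, training, saliency) runs on
one CPU in minutes.

What the phantom does **not** emulate: anatomical appearance, bolus
viscosity physics, quantum mottle, patient motion, scanner-specific
artifacts. A model that succeeds here has demonstrated that the pipeline,
optimization and attribution machinery work — not that the architecture
solves clinical VFSS; the clinical-scale numbers reported in the
literature require private data and GPU-scale training.

The pixel-sum oracle `airway_score()` — mean intensity inside the airway
disk — separates the phantom classes perfectly in the noise-free case and
nearly so under default noise. It bounds attainable classifier
performance and establishes that the planted signal is learnable.

## Numerical choices and degenerate inputs

* Quantile type 7 (R default) for the saliency percentile; on a ramp of
  100 distinct FOV values the 90th-percentile mask holds exactly 10.
* Harmonic inpainting iterates Jacobi averaging to a 1e-5 max-change
  tolerance (cap 500 iterations).
* Bilinear resampling uses pixel-center alignment with border clamping;
  the same routine backs isotropic resizing, saliency upsampling, and the
  rotation/zoom augmentation (one resample per clip, plan computed once).
* `eligibility_rules()` excludes clips under 25 frames (a swallow spans
  about one second); the minimum spatial side defaults to 128 px for
  clinical material and is configurable (the phantom uses 64 px).
* Single-class evaluation sets report `AUC = NA` with a warning, never 0.
* Degenerate paired tests (zero-variance differences) report `p = 1` or
  `p -> 0` with an explicit flag.

## Desk-scale problem sizes

The acceptance experiment and the heavyweight tests use: 200 clips from
40 subjects, 64x64 frames, 30-60 frames per clip, the reduced model
(`Tp = 10`, `P = 8`, `D = 32`, `h = 4`, `L = 2`, head [32, 16]), 10%
subject-level test split, early stopping on the validation partition.
These sizes keep a full run within minutes on a single CPU while leaving
the planted-signal problem non-trivial (the airway disk occupies about
one spatial patch at one to three temporal positions).

## Known limitations

* Whether attention rollout inherits the input-space localization of the
  planted signal depends on the training trajectory: some converged models
  keep near-uniform attention and route their evidence through value
  mixing, in which case the saliency maps are diffuse even though the
  classifier is perfect and the per-segment confidence weights still track
  the invasion onset. Across independently trained desk-scale models we
  observed in-region localization on roughly 10% to 90% of held-out
  abnormal clips. Saliency quality should therefore be checked per model,
  not assumed from classification accuracy.

* AVI/MP4 and DICOM containers are recognized but not decoded; clips must
  be converted to multi-page TIFF or NPY/NPZ first.
* The Hough gate assumes a ring-shaped (open) artifact; a filled-disk
  artifact would be rejected by the interior-contrast gate.
* Optical flow is plain Lucas-Kanade; large displacements (>2 px/frame)
  are underestimated, which is acceptable for quiescent-frame selection
  but not for motion quantification.
* Training is single-threaded, batch size 1; there is no mixed precision,
  scheduling, or multi-device support.
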