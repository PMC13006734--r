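---
title: "Decoding silent speech from optical strain maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding silent speech from optical strain maps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainspeech)
```

# The sensing and decoding problem

A camera-based optical strain sensor for silent speech consists of a soft
substrate printed with small dark circular markers, worn on the throat and
imaged from a few millimetres away at 320×240 px. Muscle motion deforms the
substrate; the markers move with it; and the displacement field of the
markers — magnitude *and* direction, across the whole field of view — is
the biosignal. Decoding proceeds in four stages, each a module of this
package:

1. **Detect** the markers in each frame (`imaging`).
2. **Track** the markers of interest, fit the frame-to-frame deformation,
   and express it as a multiaxial strain map and a residual-stress baseline
   map (`strainmap`).
3. **Condition** the per-utterance strain time series and segment a live
   stream into utterances (`signals`).
4. **Classify** each utterance into one of the 26 NATO spelling words, with
   user adaptation (`decoder`).

No public recordings from such a device exist, so the package also contains
a first-class synthetic generator (`synthfab`) whose outputs carry exact
ground truth; all tests and the acceptance script run against it.

# Micromarker detection

The detection chain is `enhance_contrast()` → `sharpen()` →
`remove_border()` → `binarize()` → `extract_markers()`.

* **CLAHE** (clip 2.0, 8×8 tiles) boosts local contrast. These are the
  conventional values for small frames; images are replicate-padded to a
  tile-divisible size and cropped back, since tile-wise equalization
  requires exact tiling.
* **Sharpening** is unsharp masking (`x + (x − blur(x))`), a Gaussian blur
  (σ = 1.0) to suppress the amplified noise, then a 3×3 kernel applied as a
  sliding weighted sum with replicate borders. The default kernel has −1 in
  the eight neighbours and a configurable centre weight, default 9 — the
  variant that preserves the local mean against the −8 surround; a heavier
  centre (e.g. 11) is selectable through `detect_config()` for stronger
  edge gain.
* **Border removal** blanks a 4 px frame ring to white before component
  extraction, because optical misalignment leaves a dark vignette that
  otherwise produces spurious components hugging the frame edge.
* **Binarization** uses Otsu's criterion computed on the integer 0–255
  histogram: the threshold maximizing between-class variance, ties resolved
  to the lowest level, dark class = marker foreground. Implementing the
  sweep directly (rather than on rebinned [0, 1] intensities) makes the
  output exactly equal to the exhaustive-sweep oracle the tests assert; the
  suite separately cross-checks it against `EBImage::otsu` within one gray
  level on overlapping-population images. A constant image falls back to
  all-background with a warning.
* **Component extraction** labels foreground 8-connectedly (4-connected
  labelling plus union–find merging of diagonal touches — circular blobs
  must not split across anti-aliased diagonals) and drops components with
  area outside [20, 500] px², the plausible disc-area window at the default
  6 px marker radius. Centroids are darkness-weighted means of the
  component pixels, which is what makes sub-pixel tracking possible:
  detection RMSE on noiseless renders is ~0.01 px, and the tests require
  < 0.5 px.

# Strain maps and the residual baseline

**Markers of interest.** The k = 16 detections nearest the image centre
(Euclidean distance, ties broken by (distance, x, y)) receive stable ids.
Central markers stay in view under deformation, so they anchor tracking.

**Matching.** All markers look identical, so correspondence must be
positional: greedy one-to-one nearest-neighbour matching accepted in
ascending distance order, capped at half the marker pitch to prevent
identity swaps between frames.

**Homography.** The deformation between the initial and current frame is
fit as a 3×3 projective transform by RANSAC (default 1000 iterations,
1.0 px reprojection threshold, seeded minimal samples) with a normalized
direct-linear-transform refit on the consensus set. The null space is taken
from the smallest eigenvector of the 9×9 normal matrix, which is exact for
minimal 4-point samples. Property tests require recovery of random
invertible transforms to 1e−6 from exact correspondences, and < 0.5 px
strain-amplitude error end-to-end through rendering and detection.

**Strain map.** Each point p of a sampling lattice (default 16×12 over the
320×240 frame; the resolution only changes sampling density, not values at
shared points) maps to p′ = Hp. Amplitude is `‖p′ − p‖₂` in px; direction
is `atan2(Δy, Δx)` in radians, range (−π, π], with y increasing downward
(image convention).

**Residual-stress map.** Re-attaching a worn device never reproduces the
previous marker geometry exactly; the deviation field between the designed
layout and the captured layout encodes that attachment state and correlates
with how utterance strain patterns shift. The map is computed by
translating the designed layout so the two centroids coincide, pairing each
captured marker to its nearest designed point, and recording the Euclidean
deviations. Centroid alignment makes the map exactly invariant to global
translation — only the shape of the deviation field matters.

**Scalar metrics.** `relative_pixel_change()` is `‖ΔMOI‖₂/‖MOI₀‖₂`. The
package measures MOI₀ from the image centre by default: a norm about the
raw pixel origin would make the denominator — and hence the reported
sensitivity — depend on where the coordinate corner happens to sit relative
to the sensor, which is arbitrary. The raw-origin convention remains
available (`reference = "origin"`). `mape()` is `100/n · Σ|1 − Aₜ/Sₜ|`, the
sensor-uniformity metric.

# Signal conditioning and voice activity detection

Utterances are T×C matrices at 50 Hz (default C = 4 strain feature
channels). The deterministic path is: moving average (window 5, shrinking
at the edges), validity check 100 ≤ T ≤ 220, centre zero-padding to 220
(odd remainder trailing, fixed for reproducibility; padding conserves each
channel's sum exactly), and global z-scoring with scalar statistics fit on
the training corpus only (per-channel vectors optional).

Training adds a stochastic chain on the padded sequence, in order:

1. **Time warp** — duplicate the values at 20 indices sampled *without*
   replacement within the active range (indices 20–200); sampling with
   replacement would allow triple copies, which plain duplication does not
   suggest. Output length 240.
2. **Crop** — a uniformly-placed 200-step window (shift invariance).
3. **Scale** — one multiplicative factor α ~ U(0.9, 1.1) per call.

For short signals the active warp range can fall inside the zero padding;
the chain is applied to the padded sequence as specified, so duplicated
zeros simply extend the pad.

**VAD.** The running energy is the trailing 200-sample boxcar sum of the
per-step squared channel norm (the simplest energy consistent with a
square-window convolution; no spectral content is used). Crossing the
threshold upward opens a segment; crossing downward closes it, with the end
index pulled back by the window length because a trailing window stays hot
for one window after activity ends. Segments outside the 100–220 validity
window are discarded. The default threshold is per-stream,
μ + 4σ of the energy over a leading calibration span — a standard
calibration rule used because no absolute threshold generalizes across
attachment states.

# The word decoder

`build_classifier()` constructs a hybrid CNN–Transformer:

* two strided 1-D convolutions (kernels 5, strides 2, filters 16→32, ReLU)
  reduce the 200-step input to 47 tokens of width 32 — the convolutional
  front end captures fine local deformation cues;
* learned positional embeddings plus one post-norm transformer encoder
  layer (4 heads, feed-forward width 64) reweight the sequence globally,
  compensating speed and timing variability that fixed receptive fields
  miss;
* mean pooling over tokens; the residual-stress-map feature (per-marker
  deviations resampled to length 16, the MOI count) passes through its own
  small ReLU branch and is concatenated at the fully connected stage, so
  the classifier conditions on attachment state;
* a 64-wide ReLU layer and a 26-way softmax head.

All layers, backpropagation and the Adam optimizer are base R matrix code;
the gradients were verified against central differences (agreement to
~1e−9 relative error). Training uses cross-entropy, batch 256 (evaluation
batch 1, deployment-style), early stopping on validation loss with
patience 8, and checkpointing of the best-validation weights. Seeded runs
are bit-reproducible.

**Cross-validation.** `make_folds()` builds subject-independent stratified
plans: subjects are greedily balanced into k = 5 groups and fold f tests
group f, so no subject's data ever appears on both sides of a fold. With
subjects balanced within classes each test fold holds exactly 1/k of every
class.

**Distillation.** The student (same topology, filters 12→24, widths halved;
~61% of the teacher's parameters) minimizes
`(1 − λ)·CE(hard) + λ·τ²·KL(teacher‖student)` with τ = 4, λ = 0.5 —
conventional values, exposed in `distill_config()`. λ = 0 reduces exactly
to hard-label training under the same seed, which the suite asserts.

**LoRA adaptation.** `lora_adapt()` attaches rank-8 factors (α = 16) to the
query and value projections, zero-initializing the second factor so the
adapted model is exactly the base model at attachment. Only the factors
receive gradients; the base weights are bit-identical afterwards, and the
trainable fraction (~5% at default sizes) is reported.

**Export.** Checkpoints serialize to a framework-neutral JSON text format
(architecture metadata + full-precision weights); reload reproduces outputs
to better than 1e−5 on probe batches. R has no ONNX bindings, so this
portable text checkpoint is the package's interchange format.

# DTW analytics

`dtw_distance()` is the classic dynamic program with symmetric steps
(↑, →, ↘), boundary-matched, local cost the squared Euclidean distance
across channels (no warping window by default; a Sakoe–Chiba band is
optional). It is tested to agree exactly with an exhaustive enumeration of
all warping paths on short sequences. `dtw_kmeans()` uses medoid centres —
exact, simple, and sufficient for condition-level clustering; its
within-cluster objective is non-increasing by construction and the suite
checks the trace. `distance_heatmap()` reports mean pairwise DTW between
labeled condition groups (e.g. tightness × vocal-intensity states).

# What the synthetic generator emulates — and what it does not

`generate_word_dataset()` produces balanced 26-class corpora in which:

* each class has a smooth random template (enveloped sinusoids per channel,
  quiet ends and an active middle, like a real utterance burst);
* subjects modulate templates with per-channel gains (N(1, 0.08)) and a
  speaking-speed factor (U(0.9, 1.1)) that changes sequence length —
  the two dominant inter-subject effects in wearable biosignals;
* attachment states add per-channel offsets and carry a smooth per-marker
  residual deviation field; tighter states expose fewer markers (counts
  16 ± 2 per state), reproducing the residual-map/strain-pattern coupling
  the fusion branch exploits;
* utterance lengths stay within the 100–220-step validity window, and noise
  enters as a smooth template-level drift plus white per-entry noise.

Defaults (26 classes, 5–6 subjects, 4 channels, noise SDs 0.05/0.02, 3
attachment states) were chosen once as plausible desk-scale conditions.
Test problem sizes — 260-sample corpora, 60–100 training epochs, 16-class
rendering grids — are the package's own choices for a fast, deterministic
suite.

What passing tests therefore demonstrate: the geometry chain is exact to
sub-pixel against analytic truth; the preprocessing contracts hold; the
decoder learns separable multi-subject data to ≥95% held-out-subject
accuracy and distils without meaningful loss. What they do **not**
demonstrate: performance on real human throat recordings. Real data add
articulatory coarticulation, non-rigid substrate deformation beyond a
homography, illumination drift, and motion artifacts, none of which the
generator models (and photorealistic silicone texture, LED illumination and
acoustics are out of scope by design).

# Numerical choices and degenerate inputs

* Rendering anti-aliases discs by 4×4 supersampled coverage, the minimum
  that makes sub-pixel centroiding testable.
* Otsu ties break to the lowest threshold; constant images are
  all-background.
* RANSAC re-fits on the final inlier set only when that does not shrink the
  consensus.
* Homography estimation refuses < 4 correspondences; strain-map evaluation
  errors on points mapped to infinity.
* `center_pad` refuses inputs longer than the target; `smooth_sequence`
  requires an odd window no longer than the sequence.
* Zero-variance corpora error in `fit_norm` unless an epsilon guard is
  requested.
* Training aborts on non-finite loss; empty VAD output is a valid result,
  not an error.

# Known limitations

* The decoder engine is CPU-bound base R; it is sized for desk-scale
  experiments (tens of thousands of parameters), not for the
  multi-million-parameter regime a GPU framework would serve.
* Marker matching is purely positional; it will swap identities if
  inter-frame motion exceeds half the marker pitch.
* DTW is O(nm) per pair in interpreted code; clustering hundreds of long
  sequences benefits from the optional band constraint.
* The homography is a global planar model; strongly non-rigid local
  deformation is only captured through the per-marker residual map, not the
  strain map itself.
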