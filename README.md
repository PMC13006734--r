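# strainspeech

Silent-speech interfaces (SSIs) decode what a person is saying from
non-acoustic biosignals, so that clear communication survives environments —
construction sites, flight decks, firing ranges — where a microphone is
useless. One promising sensing route is a *computer-vision optical strain
sensor*: a soft substrate printed with dark micromarkers, worn on the
throat and imaged by a tiny camera. As the throat muscles move, the markers
move; tracking them yields a **multiaxial strain map** (displacement
magnitude *and* direction over the sensor surface) far richer than the
single-axis resistance signal of conventional wearable strain gauges.

`strainspeech` is an R toolkit that implements the full decoding stack for
this class of sensor — and, because no public recordings of such a device
exist, a synthetic-fabrication module that generates every input the stack
needs, with known ground truth:

* **synthfab** — renders micromarker frames under known homographies and
  deformation sequences, and generates labeled 26-word strain-sequence
  datasets with subject and attachment-state structure.
* **imaging** — micromarker detection: CLAHE, unsharp masking + Gaussian
  blur + 3×3 sharpening, border removal, Otsu binarization, size-filtered
  8-connected components with sub-pixel centroids.
* **strainmap** — markers of interest (the 16 markers nearest the image
  centre), nearest-neighbour track matching, RANSAC homography
  H (initial → current), strain amplitude `‖Hp − p‖₂` and direction
  `atan2(Δy, Δx)` maps, residual-stress baseline maps (per-marker deviation
  from the designed layout after centroid alignment), relative pixel change
  `‖ΔMOI‖/‖MOI₀‖` and MAPE `100/n · Σ|1 − Aₜ/Sₜ|`.
* **signals** — utterance conditioning at 50 Hz: moving-average smoothing
  (window 5), the 100–220-step validity window, centre zero-padding to 220,
  global z-scoring `(x − μ_train)/σ_train`, the stochastic augmentation
  chain (duplicate 20 steps in the active range → random 200-step crop →
  amplitude scale α ~ U(0.9, 1.1)), and energy-based voice activity
  detection over a 200-sample boxcar.
* **decoder** — a hybrid CNN–Transformer word classifier (strided 1-D
  convolutions → learned positional embeddings → multi-head self-attention
  → mean pooling, with the residual-stress-map feature fused at the fully
  connected stage), trained with Adam + cross-entropy, early stopping and
  checkpointing; subject-independent stratified 5-fold plans;
  teacher→student knowledge distillation (soft loss at temperature τ);
  LoRA user adaptation (rank-r factors on the attention projections, base
  weights frozen). The network, backpropagation and optimizer are
  implemented in base R matrix code and verified against numerical
  gradients.
* **analysis** — dynamic time warping (exact DP, squared-Euclidean local
  cost), DTW K-means with medoid centres, and mean-DTW condition heatmaps.
* **pipeline** — `run_simulate()`, `run_detect()`, `run_strainmap()`,
  `run_train_pipeline()`, `run_vad_infer()` compose the modules into a
  manifest-logged end-to-end flow; `inst/cli/strainspeech.R` wraps them as
  shell subcommands.

## Worked example

Render a throat-motion sequence, detect the markers, and recover the strain
map of a later frame relative to the first:

```r
library(strainspeech)

spec   <- substrate_spec()                    # 5x5 dark markers, 320x240 frame
frames <- generate_motion_sequence(spec, "expand_contract", n_frames = 8, seed = 42)
m0 <- detect_markers(render_marker_image(spec, frames[[1]]))
m5 <- detect_markers(render_marker_image(spec, frames[[5]]))
nrow(m0)
#> [1] 25

mois <- select_mois(m0, spec$image_size)     # the 16 markers nearest the centre
head(mois, 3)
#>   id    x0    y0     dist
#> 1  1 159.5 119.5  0.00000
#> 2  2 135.5 119.5 24.00004
#> 3  3 183.5 119.5 24.00004

pairs <- match_markers(m0, m5, max_disp_px = spec$pitch_px / 2)$pairs
hom   <- estimate_homography(pairs, seed = 1)
round(hom$H, 4)
#>        [,1]   [,2]    [,3]
#> [1,] 0.9777 0.0000  3.5641
#> [2,] 0.0000 1.0219 -2.6174
#> [3,] 0.0000 0.0000  1.0000

sm <- compute_strain_map(hom, strain_lattice(spec$image_size))
max(sm$amplitude)
#> [1] 4.418006
```

The recovered homography shows the expand–contract phase directly: the
x-axis has contracted (0.978) while the y-axis elongated (1.022), and the
strain amplitude map peaks at ~4.4 px near the frame corners. The strain
sensitivity metric for one marker of interest:

```r
relative_pixel_change(c(mois$x0[2], mois$y0[2]),
                      c(mois$x0[2] + 1.2, mois$y0[2] + 0.9),
                      center = attr(mois, "center"))
#> [1] 0.0625
```

Training and streaming inference run the same way from a generated dataset
(see `?run_train_pipeline` and `?run_vad_infer`), or from the shell:

```sh
Rscript inst/cli/strainspeech.R simulate --seed 1 --out out/sim
Rscript inst/cli/strainspeech.R detect   --frames-dir out/sim --out out/det
Rscript inst/cli/strainspeech.R train    --dataset-dir out/sim/dataset --out out/run
```

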