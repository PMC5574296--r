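---
title: "polypscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polypscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Gastrointestinal polyps are the main precursor lesion of colorectal cancer,
and endoscopic screening produces long video sequences in which small or
flat polyps are easy to miss. polypscan implements a sliding-window
computer-aided detection pipeline for such frame sequences: each frame is
cropped to its informative region, tiled into 227×227 windows, every window
is classified polyp/nonpolyp, and positive windows are aggregated into a
single averaged marker per detected region.

The window classifier combines two complementary descriptions:

* **Color-wavelet texture features (144 values).** Mucosal and polyp
  surfaces differ in fine texture. Each window is split into its R, G, B
  channels; each channel gets a 3-level 2-D discrete wavelet transform; the
  three level-2 detail subbands per channel (indices 4–6 in the 1–9 detail
  numbering — the middle scale, where surface texture lives and both
  pixel noise and illumination gradients are attenuated) are kept. Each of
  the nine subbands is quantized to 32 gray levels and summarized by
  gray-level cooccurrence matrices in four directions (0°, 45°, 90°, 135°),
  each reduced to four Haralick statistics — correlation, energy,
  homogeneity, entropy. That is 3 channels × 3 subbands × 4 directions ×
  4 statistics = 144 features from 36 cooccurrence matrices.
* **CNN features (4096 values).** An AlexNet-style network (conv 96@11×11
  stride 4 → pool → conv 256@5×5 → pool → conv 384/384/256@3×3 → pool →
  fc 4096 → fc 4096 → fc 2 softmax) is trained on labelled windows with
  SGD + momentum on the cross-entropy, then frozen; the post-ReLU
  activations of the second fully connected layer are used as a learned
  representation.

The two blocks are concatenated (4240 features), z-scored per feature, and
classified by a linear SVM whose signed distance to the hyperplane is the
window score. Within a frame, positive windows are grouped by
single-linkage proximity of their centers; in each group, windows scoring
at least 0.8× the group maximum are kept and the marker is placed at the
arithmetic mean of their centers.

## Model assumptions

* A polyp occupies a compact, roughly elliptical region whose surface
  texture differs from the surrounding mucosa at the spatial scale of the
  middle wavelet subbands.
* One window size (227 px) is informative: polyps near that scale dominate
  the signal; much smaller or much larger lesions rely on the window
  overlap and on the CNN's partial-view response.
* Frames are independent: no temporal smoothing or tracking is applied.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `stride` | 32 px | sliding-window step; smaller = denser localization, linear cost in window count |
| `wavelet` | `"db3"` (6-tap Daubechies) | analysis filter for the DWT |
| `glcm_levels` | 32 | gray levels for cooccurrence quantization |
| `glcm_distance` | 1 px | cooccurrence pair offset |
| `epochs`, `lr`, `momentum`, `batch_size` | 10, 1e-3, 0.9, 32 | CNN training budget (SGD) |
| `cost` | 1 | SVM soft-margin C |
| `link_distance` | 227 px | single-linkage grouping radius (one window) |
| `score_fraction` | 0.8 | relative score cut inside a detection group |
| `darkness_threshold` | 10/255 | auto-ROI border trim level |

## Numerical choices

* **DWT boundary handling.** Symmetric (half-sample) extension with
  coefficient length `floor((n + L − 1)/2)` per level; the slight
  redundancy makes the inverse transform exact to machine precision for
  any orthogonal family, which the test suite verifies at 1e-8 on random
  images. Filters are stored to full double precision.
* **Quantization.** Per-subband linear min–max mapping to {0,…,G−1};
  a constant subband maps to all zeros. Signed coefficients are quantized
  directly (no magnitude folding).
* **Cooccurrence matrices** are symmetrized (pair counted in both
  directions) and normalized to sum 1.
* **Haralick correlation degenerate case.** When a marginal variance is
  zero (constant quantized subband) correlation is defined as 1: a
  constant image is perfectly correlated with itself. This matters for
  windows with flat channels, so it is fixed by convention rather than
  left NaN.
* **Entropy** uses log base 2 with 0·log 0 := 0.
* **Feature scaling.** Population (1/n) standard deviations; constant
  features get sd := 1 so scaling never divides by zero. Scaling is fit on
  training data only and reused at prediction time.
* **SVM orientation.** The hyperplane is exported explicitly (`W`, `b`)
  and oriented so positive scores mean the positive (polyp) class,
  regardless of the label order the underlying solver saw; `predict` is
  therefore verifiable against `w·x + b` exactly.
* **Window tiling.** The last window per axis is clamped to the frame
  edge: full coverage, all windows exactly 227², at the cost of extra
  overlap near the right/bottom edges.
* **Coordinates** are 0-based, `(x, y)` = (column, row), rectangles
  half-open — stated once here because every module shares them.

## Design decisions in genuinely open territory

* **Wavelet family.** The 6-tap Daubechies filter (`db3`) is the default;
  orthogonal Daubechies filters are the standard choice in the
  color-wavelet texture lineage this pipeline follows, and the family is
  configurable (`db1`–`db8` filter banks ship with the package).
* **Detail-subband numbering** is level-major — level 1 → 1–3, level 2 →
  4–6, level 3 → 7–9, with (horizontal, vertical, diagonal) within a
  level — making indices 4–6 the middle-scale details used by the
  extractor.
* **CNN training recipe.** SGD with momentum 0.9, lr 1e-3, cross-entropy,
  batch 32, no augmentation, no dropout: the plain settings for this
  architecture class. The network is trained first and then frozen; the
  SVM is fit separately on the frozen features. fc2 features are taken
  post-ReLU (hence nonnegative).
* **conv3–conv5 geometry** is 3×3, stride 1, padding 1 — the standard
  values for this architecture family, consistent with the stated filter
  counts and the 13×13 spatial maps between the last pools.
* **Marker aggregation.** "High-scoring" is a relative cut at 0.8× the
  group maximum: scale-free in the SVM score units, so it needs no
  recalibration when the score distribution shifts. Grouping is
  single-linkage at one window size; window *centers* (not origins) are
  averaged.
* **Multiclass labels** are supported via one-vs-rest hyperplanes, but
  binary polyp/nonpolyp is the validated mode.
* **Frame-sequence container.** polypscan reads and writes frame
  sequences as multi-frame TIFF (lossless 8-bit) or directories of
  PNG/JPEG stills. Lossless storage is what makes the round-trip tests
  exact; compressed video containers are out of scope.

## The synthetic fixture generator

`make_frame()`/`make_dataset()`/`make_video()` generate seeded
endoscopy-like imagery: a red-dominant smoothly varying background
(correlation length 48 px, contrast 25) with per-pixel Gaussian noise
(sd 8), and polyp regions as ellipses (semi-axes 55–90 px) carrying a weak
band-pass surface texture (amplitude 10, scale 4 px) plus a mild
brightness dome (5). Windows are labelled polyp exactly when their center
lies inside the ground-truth ellipse, and datasets default to the 1:2
polyp:nonpolyp ratio of a realistic screening window mix.

The difficulty knob is the texture-amplitude/noise ratio. The defaults
were calibrated once so the classes are separable but not trivially:
at these settings a wavelet-only classifier reaches roughly 0.94 held-out
accuracy, a CNN-only classifier roughly 0.96, and the fused classifier
roughly 0.98 — i.e. each family carries a partial, complementary signal
(texture for the wavelet block, the low-frequency dome for the CNN), and
fusion measurably helps, which is the property the pipeline exists to
exercise. The generator emulates *textural* detectability only: it has no
specular highlights, no vignetting or fish-eye geometry, no instrument
shadows, no motion blur, and its palette statistics are far narrower than
clinical footage. Passing the package's tests therefore demonstrates that
the pipeline's machinery works and that fusion helps on texture-defined
lesions; it says nothing quantitative about clinical performance.

## Problem sizes used by the tests and the acceptance script

The reference evaluation uses 300 windows (100 polyp / 200 nonpolyp),
a 70/30 stratified split, and a CNN budget of 3 epochs — enough for the
loss to fall steadily and the feature space to separate the fixture
classes, while keeping a full desk-scale run in minutes on one CPU.
Marker localization uses a 10-frame 320×320 video at stride 32. These
sizes are the package's chosen desk-scale defaults; the pipeline itself
has no dependence on them.

## Known limitations

* No temporal aggregation: each frame is scored independently.
* The linear SVM is fit by a general-purpose solver; for much larger
  training sets a dedicated linear solver would be the better backend
  behind the same interface.
* Training the CNN from scratch on small fixture sets underuses the
  architecture; the 4096-wide fc2 representation is heavily
  over-parameterized for 200-odd training windows, and is regularized
  only by early stopping (few epochs).
* The auto-ROI trim assumes the uninformative border is *dark*; bright
  overlays (timestamps, UI elements) are not removed.
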