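---
title: "Methods and design choices in pdscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in pdscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdscreen)
```

# What the package models

Parkinson's disease (PD) degrades two cheap, non-invasive biomarkers: drawn
shapes (micrographia — tremulous spirals, meanders and circles) and speech
(hypokinetic dysarthria — softer, rougher, more monotonous voice). `pdscreen`
implements a desk-scale screening framework over both modalities:

1. **Voice path.** Recordings are cut into non-overlapping fixed-duration
   segments at several durations (5, 15, 30, 60 s by default), each segment
   is summarized by a 281-column acoustic feature vector, and per-duration
   tables plus their concatenation ("combined") feed grid-searched classical
   classifiers. Segments can alternatively be rendered as time-frequency
   images for a convolutional model.
2. **Handwriting path.** Shape images are class-equalized by random
   augmentation, scale-converted, and classified by a small convolutional
   network whose hyperparameters are tuned by the Aquila Optimizer (AO)
   metaheuristic through a 14-dimensional codec.
3. **Fusion.** A patient's handwriting score (mean PD probability mass over
   three drawn shapes) and speech score (mean of the numeric and graphical
   path scores) combine by maximum (or mean) into a single decision at a
   0.5 threshold.

# Multi-duration segmentation

A record of duration $L$ seconds cut at duration $d$ yields exactly
$\lfloor L/d \rfloor$ segments; the remainder is always discarded, never
padded (a 95 s record at 10 s gives 9 segments and neglects 5 s). Segment
length is computed in whole samples, $\lfloor d \cdot f_s \rfloor$, so
concatenating the segments reproduces a bit-exact prefix of the record.
Pooling several durations is the diversity-increasing idea the feature
tables build on: the combined table simply concatenates the per-duration
rows with labels preserved.

Defaults the data sources leave open, chosen once and exposed in arguments:
sampling rate 22050 Hz; stereo collapsed by channel mean; labels inherited
unchanged from record to segment.

# The 281-column feature schema

Sixteen techniques produce per-frame matrices over an STFT with frame 2048,
hop 512, Hann window, reflect-padded centred frames (parameters the sources
do not state; configurable). Each coefficient/band is aggregated across
frames by the mean (pluggable), giving the fixed block layout: MFCC under
the Slaney and HTK mel conventions (40 + 40), mel-spectrogram (128), four
chroma variants (4 × 12), RMSE (1), spectral contrast (7), flatness,
centroid, bandwidth, roll-off (1 each), zero-crossing rate (1), and two
tonnetz variants (6 + 6) — 281 columns total.

Conventions that required a decision:

* **MFCC Slaney vs HTK** differ only in the mel scale of the filterbank
  (piecewise linear/log vs $2595\log_{10}(1+f/700)$); both use an
  area-normalized triangular bank of 128 filters followed by an orthonormal
  DCT-II truncated to 40 coefficients of the dB-scaled energies.
* **Chroma family.** "chroma-only" is the plain waveform chromagram
  (nearest-pitch-class binning of STFT power, per-frame max norm);
  "chroma-STFT" uses Gaussian soft assignment across neighbouring classes;
  "chroma-CQT" folds a log-frequency (constant-Q-like) semitone spectrum
  into 12 classes; "chroma-CENS" adds l1 normalization, quantization,
  temporal smoothing and l2 normalization.
* **Tonnetz** projects l1-normalized chroma onto the 6-dimensional tonal
  centroid basis (circle of fifths, minor thirds, major thirds); the
  "harmonic" variant applies a running-median time smoothing to the chroma
  first, emphasising sustained harmonic content.
* **Numerical safety.** An epsilon floor of `1e-10` precedes every
  logarithm and denominator; an all-zero (silent) segment gets an epsilon
  amplitude floor, so every feature is finite and the ZCR is exactly 0.
  Segments shorter than one analysis frame are rejected as invalid.

Graph rendering (five techniques: power spectrogram in dB, mel-spectrogram
in dB, log-magnitude STFT, and the two MFCC matrices) deliberately avoids a
plotting device: the matrix is min-max normalized, colour-mapped through the
viridis palette, upsampled to a `dpi`&times;`dpi` raster (480 by default) and
bilinearly resized to the (100, 100, 3) model input. This makes rendering
deterministic pixel-for-pixel across platforms.

# Image pipeline

The four scale conversions are whole-image formulas with scalar statistics:
$in/255$, $(in-\min)/(\max-\min)$, $(in-\mu)/\sigma$, $in/\max|in|$.
Degenerate denominators (constant or blank images) return all-zeros with a
warning so batch pipelines never abort. The six augmentations (shift, shear,
zoom, flip, rotation, brightness) draw each amount uniformly within its
range; geometric transforms are a single inverse-mapped affine warp about
the centre with nearest-edge fill. First-location defaults: 15% shifts,
15% shear, 15% zoom, both flips permitted, 25° rotation, brightness
[0.8, 1.2]. Equalization finds the largest class and augments randomly
chosen originals of every other class (with replacement — minority classes
may need more copies than they have originals) until all classes match it.

# Grid-searched pipelines

Every configuration is the pipeline scaler → variance threshold →
classifier, fitted on training folds only, evaluated by stratified 10-fold
cross-validation (fold count configurable). The table scalers are
per-column min-max, standardization and max-abs plus the stateless per-row
unit-norm "normalizer" (distinct from the image $in/255$ normalization).
Classifier grids: KNN 6×4×2 = 48, SVM 5×5×5×5 = 625, DT 2×2×12 = 48, NB 9;
crossing with 4 scalers and 7 thresholds gives e.g. 1344 KNN pipelines.

Decisions where the environment or the sources left room:

* **Averaging.** Micro averaging for precision/recall/F1 — for single-label
  data these all equal accuracy, which is why equal metric columns appear in
  grid-search reports. AUC is a one-vs-rest macro average computed rank-wise;
  a degenerate single-class fold records 0.5 with a warning.
* **Implementations.** No classifier package exists in the supported
  environment, so KNN (true Minkowski metric; `leafSize` accepted but, as in
  reference implementations, irrelevant to predictions), CART (gini/entropy,
  best/random splitter, maxDepth) and Gaussian naive Bayes are implemented
  in-package. The SVM is a least-squares SVM (kernel ridge classification,
  one-vs-rest) honouring C, kernel, degree and gamma — a documented variant,
  not a QP-trained SVC. The `precomputed` kernel is enumerated but skipped
  with a warning since no kernel matrix is defined.
* **NB alpha.** The smoothing parameter is additive *variance* smoothing:
  the 281 features are real-valued and signed, so Laplace count smoothing
  has no meaning for them.
* **Ties** in the grid break by enumeration order; configurations that fail
  are logged and scored invalid rather than aborting the search.

# The Aquila Optimizer

AO is a population metaheuristic over a bounded continuous domain with four
update rules. With best solution $X_{best}$, population mean $X_m$, a random
member $X_R$, iteration $t$ of $T$:

* Phase 1 (high soar): $X_{best}(1-t/T) + (X_m - X_{best}\,r)$
* Phase 2 (contour flight): $X_{best}\,Levy(D) + X_R + (y-x)\,r$
* Phase 3 (low flight): $(X_{best}-X_m)\alpha - r + ((UB-LB)r + LB)\gamma$
* Phase 4 (walk and grab): $QF\,X_{best} - G_1 X r - G_2\,Levy(D) + r\,G_1$

Exploration (phases 1–2) runs while $t \le \frac{2}{3}T$, exploitation
(3–4) after, the two admissible phases equally likely. Constants the
published equations leave open follow the original AO reference:
$\alpha=\gamma=0.1$; Mantegna Lévy steps with $\beta=1.5$ and step scale
0.01; spiral terms $r = r_1 + 0.00565 D_1$, $\theta = -0.005 D_1 + 3\pi/2$
with $r_1 \sim U(1,20)$; $G_1 = 2r-1$; $G_2 = 2(1-t/T)$;
$QF = (t+1)^{(2r-1)/(1-T)^2}$ (the $t+1$ avoids the degenerate $0^x$ at the
first, 0-based iteration). In the phase-1 reading, the random factor
multiplies $X_{best}$ inside the difference term, matching the printed
equation and the original reference.

Operational choices: the initial population is drawn uniformly in the
bounds with fitness *unset* (worst-possible), so the evaluation budget is
exactly `population_size * iterations` and the first iteration's candidates
are always accepted; replacement is greedy (a member only moves to a
candidate that improves its own objective); every candidate is clipped into
the bounds; non-finite objective values score as worst with a warning. The
optimizer is generic (any dimension, bounds, minimize/maximize); the CNN
use-case searches $[0,1]^{14}$ and leaves all physical ranges to the codec.

## The 14-dimension codec

Continuous dimensions rescale linearly; stepped dimensions (batch size
8–64 by 8, TL ratio 0–100, rotation 0–45) snap to the nearest grid point;
categorical dimensions (6 loss functions, 11 deduplicated optimizer tags,
the two flips) index by $\lfloor v \cdot n \rfloor$ clamped to the last
option; the brightness pair reorders so `from <= to`. The all-zeros vector
decodes to every first option / lower bound, all-ones to every last option
/ upper bound — both asserted in tests.

# The convolutional path

`tiny_stub` is a three-block convolutional backbone (3×3 kernels, 8/16/32
channels, two 2×2 max-pools, ~12k parameters) followed by global average
pooling, inverted dropout and a softmax head, trained by full
backpropagation in R. It stands in for the eight ImageNet backbones, which
cannot be used offline; requesting one raises an explicit error suggesting
the stub. The TL learning ratio unfreezes the top `round(ratio/100 * n)`
backbone layers, counted from the output end (direction was an open choice);
the head is always trainable. The 11 optimizer tags map onto four
implemented update-rule families (SGD; Nesterov momentum; Adagrad-type;
RMSProp-type; Adam-type) — a stated simplification, since e.g. Nadam and
AMSGrad differ from Adam only in refinements immaterial at stub scale. All
six loss functions (crossentropy, KL, Poisson, hinge, squared hinge,
categorical hinge) are exact, with gradients chained through the softmax.

**IOU and Dice for classification** are not standard; the package computes
them as overlap between the 0.5-thresholded probability mass and the
one-hot truth, micro-summed over the batch: $IOU = |P\cap T|/|P\cup T|$,
$Dice = 2|P\cap T|/(|P|+|T|)$. Dice ≥ IOU pointwise and both equal 1
exactly when thresholded predictions match the truth.

Evaluation uses a stratified 85/15 record split; a class absent from the
test split is an error instructing a different seed.

# Fusion

`handwriting_test` averages the PD probability mass (for 6-class shape
models: the summed probability of the three patient classes) over exactly
three drawings. `speech_test` averages per-segment probabilities within the
numeric and graphical paths and then averages the two path scores; when only
one modality or path is available its score is used directly with a logged
caveat. `fuse` takes the maximum (or mean) and decides PD at a configurable
0.5 threshold.

# The synthetic world

The fixture generators state a world rather than tune one:

* **Voice.** Tone+noise mixtures, peak-normalized to 0.9. The
  healthy-control profile is three harmonics at 140/280/420 Hz with
  noise SD 0.01; the patient profile shifts the fundamental to 110 Hz,
  raises noise to 0.15 and adds a 5 Hz amplitude tremor of depth 0.6 —
  label-correlated roughness, hoarseness and tremor knobs, not a model of
  dysarthric acoustics. Setting the knobs to zero yields null datasets for
  chance-level tests.
* **Drawings.** Parametric Archimedean spiral, square-wave meander and
  circle, rasterized dark-on-white at 100×100×3, with per-point Gaussian
  tremor jitter; a zero-tremor circle is rendered analytically and is
  exactly 90°-rotation symmetric. The handwriting-layout spec mirrors the
  public dataset's class counts 140/140/35/31/124/124 with patient-class
  tremor 2.5 px.
* **Reproducibility.** One master seed fans out to per-item seeds by a
  stable multiplicative hash, so any subset of a fixture set regenerates
  bit-for-bit.

A green test on this world establishes that the pipeline's mechanics —
counts, contracts, budgets, determinism, and separability when separability
is planted — are correct. It does not establish clinical performance: real
dysarthric voice and micrographia are far subtler than the planted effects,
and the published headline accuracies require the two external datasets,
eight pretrained backbones and a multi-day search, all out of scope here.

# Numerical choices and limitations

* Epsilon floors `1e-10` before logs/denominators; 16-bit WAV quantization
  bounds round-trip error at ~3e-5 per sample; resampling is linear
  interpolation (no DSP package available) — adequate below the Nyquist
  margins used here, but not band-limited.
* Grid ties break by enumeration order; KNN distance ties by row order.
* The least-squares SVM solves a dense linear system per class: O(n³) in
  training rows, intended for desk-scale tables.
* The pure-R CNN trains tens of images in seconds but is not meant for
  hundreds of epochs or large rasters.
* The end-to-end smoke experiment exercises the numeric speech path
  (grid-searched KNN) with score fusion; the graphical path and CNN
  training are validated by their own tests rather than inside the smoke
  loop, keeping the full suite inside a small CPU budget.
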