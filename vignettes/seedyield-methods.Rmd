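---
title: "Methods: from robot video frames to genotype rankings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from robot video frames to genotype rankings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`seedyield` re-implements, end to end and at desk scale, a pipeline for
estimating and ranking soybean plot yields from side-view ground-robot
video: fisheye capture and correction, frame-to-plot assignment, splitter
frame sampling, a point-proposal seed counting network, a frozen-backbone
yield regressor, moving-grid spatial adjustment, and selection-threshold
ranking. This vignette explains the models, the tunable parameters, what
the synthetic generator does and does not emulate, and the numerical
choices we made where the design was open.

## 1. The synthetic field and scenes

The real method is validated on breeding trials; we validate on a
generator with known ground truth.

**Field model.** A trial is a `n_ranges x n_passes` grid of two-row
plots. The true yield of plot *i* growing entry *g(i)* is

    y_i = e_{g(i)} + t(range_i, pass_i) + eps_i,

with genotype effects `e ~ N(3.5, 0.5^2)` MT/ha by default (the scale of
advanced soybean yield trials), a smooth environmental trend `t` —
separable linear slopes plus one Gaussian fertility bump, worth roughly
±0.6 MT/ha across the field — and plot noise `eps ~ N(0, 0.2^2)` MT/ha.
The plot's whole-plot seed count is `round(y_i * seeds_per_MT)` with
`seeds_per_MT = 160` by default, putting plot counts in the several
hundreds. Yields pushed non-positive are clipped (or resampled, per
config) with a message.

**Scenes.** A frame is a textured value-noise background (a cheap
Perlin-style surrogate for soil and residue), dim desaturated blobs for
background-plot seeds — rendered but never annotated — and shaded
ellipses with eccentricity 0.65–0.95 for foreground seeds. Foreground
seeds are placed by rejection sampling so they never overlap one another;
occlusion is explicit: a configurable fraction of seeds receives a dark
foliage blob near its rim. The annotation rule is mask-based and
testable: a seed enters the ground truth iff at least 50% of its rendered
pixels survive occlusion, our operational version of "clearly discernible
to a human rater". The per-seed label mask is returned so tests can audit
the rule directly.

**Collections.** The robot crosses each plot at constant speed (default
1 m/s; the true field speed is not fixed by the method, so it is config),
producing four frame sequences per plot (rows 1–2 × sides A–B), frame
interval `plot_length / speed / frames_per_plot`, plus alleyway frames
between plots and a plot-interval table `(plot_id, start_s, stop_s)` —
the same CSV contract the real robot's plot segmentation emits. Frames
are rendered at a small native size (64 px default) with intrinsics
rescaled from the full-frame calibration, and fisheye-distorted before
they enter the analysis side. Per-frame visible seed counts are Poisson
around `frame_fraction` (default 0.04) of the plot seed count, capped at
a packing-safe density so every frame stays renderable.

**What the generator does not emulate:** lodging, disease, weather,
photorealistic pods, motion blur from speed changes, or GPS/LiDAR errors
in plot segmentation. Passing tests therefore demonstrate that the
*machinery* is correct and that the method's orderings hold under its own
assumptions — not field-level performance.

## 2. Optics

We use the equidistant fisheye model with a polynomial distortion of the
incidence angle `theta = atan(r)`:

    theta_d = theta (1 + k1 theta^2 + k2 theta^4 + k3 theta^6 + k4 theta^8).

The method's published calibration gives only focal lengths (410, 410) px
and principal point (383, 526) px for the 1,920 × 1,080 frame; the
distortion coefficients are not printed, so the simulator defaults to
`k = (−0.05, 0.01, 0, 0)` — visible barrel distortion that remains
cleanly invertible. Undistortion inverts the polynomial by Newton
iteration (12 steps from `theta = theta_d`; machine-precision inverse for
any `|k|` small enough to keep `theta_d` monotone). Images are remapped
with bilinear sampling and cached inverse maps; coordinates are 0-based
with the point at the pixel centre, which is what makes the round-trip
tests exact to state. After undistortion a central square (1,000 px at
native scale, 48 px in the desk-scale runs) is cropped without
resampling; odd margins shift toward the top-left for determinism.

## 3. Frame assignment and splitter sampling

Frames map to plots through the interval table under a half-open
`[start, stop)` convention — a frame at an exact stop time belongs to the
next interval or the alleyway, never the closing plot. For sampling, each
row-side sequence's traversal span (the frame span padded by half a frame
interval at each end, since frames sit at the centres of their exposure
slots) is divided into eight sections by seven splitters; splitters 2–6
are kept — the outermost two sit too close to the plot ends to be useful
— and the nearest frame in time is taken at each, earlier frame on a
tie. Two rows per side, two sides: 10 images per side, 20 per plot.
Splitters are positioned on the time axis; at constant simulated speed
this equals distance, and the package exposes the axis as a config switch
because under real wheel slippage the two differ.

## 4. Sensor-effect augmentation

Each training image gets exactly one augmented copy with independently
drawn intensities: Gaussian blur (sigma 0–1.5 px), chromatic aberration
as opposite sub-pixel lateral shifts of the red and blue channels
(0–2 px), multiplicative exposure gain (0.6–1.5), and additive Gaussian
noise (SD 0–0.10 on [0, 1] intensities), composed in that order — noise
last, as in a physical sensor chain. The composition order and the
default ranges are this package's choices (the ranges were picked once to
produce visible but plausible corruption); all are config. Point
annotations are untouched by all four effects: the green channel is the
geometric reference under chromatic aberration.

## 5. The counting network

The counting model is a point-proposal ("crowd counting") network: a
backbone of `conv 3x3 + ReLU + maxpool 2x2` blocks (default widths
8–16–16, spatial stride 8) and a 1×1 convolutional head emitting, per
feature cell and anchor (`density = 2` anchors per cell), a 2-D offset
from the anchor reference point and a confidence logit. The head is
initialized at zero so an untrained model proposes every anchor at score
exactly 0.5 with zero offset — a convenient testable state.

Training pairs ground truth with proposals by one-to-one Hungarian
matching (shortest augmenting path, written here and verified against a
brute-force permutation oracle) on the cost
`||p_i − t_j|| − lambda * score_i` with `lambda = 0.5`; the loss is
cross-entropy on matched (target 1) versus unmatched (target 0)
confidences plus `loc_weight = 5e-3` times the mean squared matched
offset. At inference, proposals below `score_threshold = 0.5` are
dropped and survivors are merged greedily by descending score with a
uniform-grid spatial index (`merge_radius` 8 px at the 1,000 px working
scale, 4 px in the 48–64 px desk-scale runs, i.e. roughly one seed
diameter). Optimization is Adam; the desk-scale experiments use
`lr = 1e-3` (chosen for convergence within ~10 epochs at 64 px; the
module default of `1e-4` suits longer schedules).

All tensor machinery — im2col convolution on BLAS matrix products, max
pooling, manual backprop, Adam — is implemented in base R and checked
against numerical differentiation; no deep-learning framework is
involved.

## 6. Yield regression

For each plot the 20 sampled images pass through the *frozen* counting
backbone; the 10 feature maps of each side are summed elementwise and the
two side sums concatenated along the channel axis (channel concatenation
preserves spatial registration; side order fixed A then B). The fused
map feeds `conv 3x3 (64) → maxpool → flatten → fc 256 → 64 → 1`,
predicting MT/ha, trained with batch 8, 50 epochs, Adam, MSE.

Two standardizations stabilize this small regression: targets are
z-scored during training and inverted at prediction, and fused inputs are
standardized by the global mean and SD of the training features (stored
in the regressor, re-applied at prediction). The input side matters in
practice: summed ReLU activations have magnitude in the tens, and a
He-initialized head optimizes poorly at that scale — with
standardization the held-out predicted-vs-true yield R² on the synthetic
recovery experiment rises from ~0.19 to ~0.8. Freezing is asserted, not
assumed: training checksums the backbone parameters before and after.

Seed counts are deliberately not an intermediate of this path — the
regressor reads the feature maps, and the package's TSC output
(`sum of per-image counts over the 20 samples`) is computed separately.

## 7. Moving-grid adjustment and ranking

Plot phenotypes (true yield, estimated TSC, estimated yield) are spatially
adjusted before ranking:

    p_adj = p_obs − b (x_i − x̄),

where `x_i` is the mean phenotype over the plot's 5×5 neighbourhood minus
the four corners and the centre (20 cells; edge plots use whatever masked
neighbours are in bounds), `x̄` the mean of the `x_i`, and `b` the
ordinary-least-squares slope (with intercept) of `p_obs` on `x_i`. Since
the deviations sum to zero, the field mean is preserved. Zero variance in
`x_i` yields `b = 0` with a warning rather than an error — on degenerate
inputs (e.g. a constant estimate) adjustment is a no-op. Adjustment is
applied once, and with replicated entries the package adjusts plot values
first and leaves any averaging to the caller.

Ranking at a selection threshold `q` takes the top `ceiling(qN)` plots of
truth and estimate independently (ties broken by stable plot order, which
forces FP = FN), and reports accuracy `(TP+TN)/N`, sensitivity
`TP/(TP+FN)` and specificity `TN/(TN+FP)`; zero denominators are returned
as `NA` with a warning, never silently zero. Combine masses are
normalized to MT/ha at 13% grain moisture by dry-matter proportionality
`mass × (100 − m)/(100 − 13)` before per-hectare scaling — the standard
target moisture fixes only the endpoint, the proportional formula is our
choice.

## 8. Problem sizes and the two headline experiments

The package ships two experiment drivers sized for a single CPU:

* `run_aug_ordering_experiment()` — 200 training scenes at 64 px, a
  one-for-one augmented copy, 12 epochs for both the plain and augmented
  runs, evaluation on a 50-image sensor-corrupted test set. The expected
  (and observed) ordering is `MAE_augmented <= MAE_plain`: corruption
  matching the augmentation family is precisely what augmentation buys
  robustness to.
* `run_yield_recovery_experiment()` — a 10 × 20 field (100 training / 100
  held-out plots), full optical chain per plot (8 frames per sequence,
  splitter-sampled to 20), a backbone pretrained on 100 annotated scenes,
  then the frozen-backbone regressor. Success is a positive
  predicted-vs-true slope and held-out R² above a floor of 0.3; observed
  values run ~0.8 under the default generator, comfortably above.

These sizes are the package's chosen study conditions; the absolute error
levels of the full-scale method on real imagery are outside what a
synthetic desk-scale rig can or should reproduce.

## 9. Known limitations

* The backbone is a small generic CNN, not the full published
  crowd-counting architecture (attention and multi-scale reception are
  out of scope); conclusions transfer as orderings, not absolute errors.
* Splitter placement assumes constant speed within a plot.
* The scene model's difficulty knobs (occlusion, clutter, radius) are
  coarse proxies for foliage occlusion and camera limits.
* Spatial adjustment assumes a smooth trend; sharp soil discontinuities
  violate the moving-mean model and would bias `b`.
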