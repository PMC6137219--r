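---
title: "Target-modulated visual search: model, generators and evaluation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-modulated visual search: model, generators and evaluation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivsn)
```

## The model

The package implements a zero-shot model of goal-directed visual search.
Both the target cue $I_t$ and the search image $I_s$ are processed by the
same feed-forward convolutional hierarchy (the "ventral stream"), with
weights $W$ fixed in advance — nothing is trained or tuned on the search
images. The activations of the cue at a top layer are held as a template
(the "pre-frontal" store) and applied as a convolution kernel over the
search image's activations at the layer immediately below, summing over
channels:

$$M_f = \varphi_{\mathrm{top}}(I_t, W) \ast \varphi_{\mathrm{mod}}(I_s, W),$$

where $\ast$ is 2D cross-correlation (the deep-learning "convolution") with
'same' zero padding. $M_f$ is the top-down attention map. A winner-take-all
(WTA) rule selects its global maximum as the next fixation; a
target-presence decision (an oracle against the ground-truth box by
default, or a recognition step) stops the search, and otherwise inhibition
of return (IOR) suppresses the fixated region and the loop continues.

Search images larger than the backbone's input are partitioned into a
non-overlapping grid of square tiles; the model runs per tile and the
feature-space maps are upsampled bilinearly to pixel space, each feature
cell anchored at its receptive-field centre
($\mathrm{offset} + (i - \tfrac12)\cdot\mathrm{stride}$ pixels), and
concatenated in grid order. Remainder tiles are zero-padded; the padding
lies outside the image and is cropped away.

### Backbones

The backbone is a pluggable contract: any feed-forward convolutional
network exposing addressable layers works, and published classification
networks (e.g. a 16-layer VGG-style net whose top feature vector has 512
channels) satisfy it when their weights are available. Because pretrained
weights cannot be redistributed with the package, the shipped default is
`tinynet`: three bias-free blocks of 3×3 convolution + ReLU + 2×2 max
pooling (4, 8, 16 channels), with weights drawn once from a fixed internal
seed so the network is bit-identical across machines and sessions. Layer
ids are symbolic (`conv1_relu`, `pool1`, …, `pool3`); the default layer
pair is the deepest pooling layer over the convolution beneath it
(`pool3` → `conv3_relu`), and `default_layer_pair(bb, depth = k)` exposes
the shallower variants. A random-weight control
(`make_random_weights_backbone()`, Gaussian weights with mean 0 and
standard deviation 1000) reproduces the classic untrained-filter baseline.
The numeric layer indices used in the deep-net literature map onto these
symbolic ids per architecture; for a VGG-16 the conventional top/modulation
pair corresponds to pooled-over-rectified top-block features, which is
exactly the `pool`-over-`conv_relu` convention used here.

### Fixation generation

* **WTA**: global argmax; ties broken at the lowest row-major index.
  Coordinates are 1-based `(row, col)`, origin top-left, as usual in R.
* **Infinite IOR**: a $w\times w$ pixel window centred on the fixation is
  masked permanently. The mask value is $-\infty$ rather than a literal
  zero so masked cells can never win the WTA on maps with zero background.
  Window defaults follow the convention of matching the average object
  size: 45 px (object arrays), 200 px (natural scenes), 100 px (dense
  cartoon scenes), all at 32 px/deg.
* **Finite IOR** (`ior_mode = "finite"`): the feature map is multiplied by
  a memory field, $A_f(x,y) = M_f(x,y)\, M_m(x,y,t)$, where a location
  visited at ordinal $j$ carries weight $M_m = 1 - a e^{-(t-j)/\tau}$
  within the revisit radius (3° by default) — inhibition of depth $a$
  recovering with timescale $\tau$ fixations. The most recent visit wins
  where discs overlap. With $a = 1$ and $\tau \to \infty$ this reproduces
  infinite IOR exactly on fixed maps (a property the test suite checks).
* **Saccade-size constraint** (`size_constraint`): the working map becomes
  $w\,M_f + (1-w)\,M_{sc}$ with $M_{sc}$ the gamma density of the distance
  (in degrees) from the current fixation, rescaled to peak at 1; the
  default weight is $w = 0.2346$.
* **Array mode**: six-object array trials carry the object centres; the
  engine scores each object by the maximum of $M_f$ inside its box and
  visits objects in decreasing priority, fixating centres, with
  object-level IOR. This is the fixed point of "WTA → snap to the nearest
  centre → object-wise IOR" and cannot livelock when the upsampled
  attention bleeds past an object's mask; it guarantees no object is
  visited twice, hence 100% cumulative performance by fixation 6 with an
  oracle decision, for any backbone. Pixel-level behaviour is available
  via `snap_to_objects = FALSE`.

### Target-presence decisions

The **oracle** accepts a fixation inside a half-open $w\times w$ window
centred on the target-box centre (or inside the box itself when no window
is given) — it isolates search from recognition. The **recognition**
decision crops the fixated window, extracts the backbone's final-layer
descriptor for the crop and the cue, L2-normalizes both and accepts iff
their Euclidean distance is strictly below 0.9. Normalization is applied
because a fixed distance threshold is only meaningful on unit-scale
vectors; raw activations have arbitrary scale. Note that descriptors of a
rectified network are non-negative, so normalized distances concentrate
well below $\sqrt 2$; with the tiny test backbone the recognition decision
is therefore permissive, and the tests exercise its geometry (identical
crop → 0; zero crop → 1; strictness at the threshold) rather than its
discriminative power, which depends on the backbone's depth.

## Null models

* **Chance**: array mode draws a uniform random permutation of the six
  slots per repetition (mean fixations-to-target $(6+1)/2 = 3.5$,
  first-fixation rate $1/6$). Free mode draws uniform random fixations;
  detection uses the window-overlaps-target rule (the
  window-contains-centre rule is available as `detection = "center"`) and
  the same window sets the IOR region, with subsequent fixations
  rejection-sampled outside all inhibited windows. Overlap was chosen as
  the default because it reproduces the published ~7% first-fixation rate
  for natural-scene-sized targets; centre containment gives roughly half
  that.
* **Sliding window**: deterministic raster of window centres from the
  top-left with stride 28 px (plus one flush-to-edge position when the
  stride does not divide exactly), oracle detection; slot order in array
  mode.
* **Template matching**: the cue is resized to a canonical 28×28 template
  and scored against every image patch by negative SSD ('same' zero
  padding); normalized cross-correlation is available as `score = "ncc"`.
  SSD was chosen as the plainest pixel-level score. The map feeds the same
  WTA/IOR engine, so this baseline is "attention-guided" template
  matching.
* **Bottom-up saliency**: a minimal centre-surround stand-in (intensity
  contrast across a dyadic pyramid plus four-orientation edge energy, each
  channel normalized and summed), with no target information. It is a
  baseline interface, not a re-implementation of any published saliency
  model; externally computed saliency maps can be fed to the engine
  directly as `attention_map` objects.

## Synthetic stimuli

`generate_procedural_objects()` builds part-based objects (ellipses and
bars) whose within-category instances jitter part geometry, so
within-category distances are smaller than between-category distances.
`normalize_object_image()` applies the standard array preprocessing:
tight-crop, aspect-preserving rescale so the larger content side equals
156 px (at 32 px/deg), global 256-bin histogram equalization computed on
content pixels only (equalizing the padding would distort the content
histogram), and centring on a mid-gray canvas. Mid-gray (0.5) is used as
the neutral display background throughout. `compose_object_array()`
places six such objects at $k\cdot 60° + \mathrm{phase}$ on a 10.5°
circle (phase 0 puts the first slot at 3 o'clock; the slot angles are a
free choice and configurable), drawing the target slot uniformly.
`synth_cluttered_scene()` embeds one transformed copy of a target into
clutter built from rotated distractors plus band-limited noise, which
gives pixel-level template matching and feature-level search genuinely
different difficulty.

The default display geometry is 1024×1280 px subtending 32×40°
(32 px/deg); natural-scene canvases of 1028×1280 and other printed sizes
are configurable through `display_geometry()`, and the package treats
1024×1280 as the canonical default.

## Synthetic scanpaths and parameter recovery

`synth_scanpaths()` generates fixation sequences with two controlled
properties: gamma-distributed saccade amplitudes (default shape 2, scale
3.8° — mean 7.6°, a typical human free-viewing amplitude), and a
revisit probability by lag. At each step a candidate lag is drawn
uniformly on $2..L$; with probability $p(\ell)$ (and provided the
candidate fixation is itself "fresh" — a lag-independent condition) the
new fixation lands inside the revisit radius of that earlier location
while staying outside the radius of every other fixation; otherwise a
fresh location is placed one gamma saccade away, rejection-sampled
(direction first, so the amplitude is preserved) outside the radius of
all previous fixations. By construction the only within-radius pairs are
the planned ones, so the pairwise estimator
`estimate_revisit_curve()` is unbiased for $p(\ell)/L$ up to a constant
factor, and `fit_memory_params()` — bounded, precision-weighted least
squares of $c\,(1 - a e^{-\ell/\tau})$ — recovers $(a, \tau)$. Lag-1
pairs are excluded from the fit by default because a short saccade is
indistinguishable from a deliberate immediate return.

Two couplings are worth knowing. First, the no-revisit guarantee
necessarily truncates saccades shorter than the revisit radius, so
amplitude fidelity and revisit control trade off through that radius: the
amplitude-recovery fixtures use a small radius (0.5°, truncating <1% of
the gamma mass), while the revisit-recovery fixtures use 1° with long
sequences (500 sequences × 150 fixations), where amplitude purity is not
asserted. Second, the recovery tolerances (15% on $a$ and $\tau$; 10% on
the gamma shape and scale at $10^4$ amplitudes) were verified by
simulation across ten independent seeds at these problem sizes before
being frozen into the tests.

## Evaluation metrics

* `cumulative_performance()`: the empirical distribution of the
  fixation ordinal at detection and its running sum; unfound trials
  contribute to no bin, so the curve plateaus below 1 and
  $\sum_n p(n) + \text{unfound fraction} = 1$.
* `scanpath_similarity()`: pooled fixations are clustered by flat-kernel
  mean shift (bandwidth 1° = 32 px by default, about eye-tracker
  precision); each fixation maps to its cluster's character and the two
  strings are aligned by Needleman–Wunsch with match = 1, mismatch = 0,
  gap = 0 — under this scoring the alignment score equals the longest
  common subsequence — normalized by the longer string's length. The
  score is symmetric, lies in $[0,1]$, is 1 exactly for identical strings
  and 0 when the sequences share no cluster. The cited scanpath-metric
  literature does not print its substitution/gap scores or bandwidth, so
  both are exposed as arguments and should be treated as a fidelity risk
  when comparing against published similarity values.
* `fixation_count_pairs()`: per-trial fixations-to-target pairs restricted
  to trials found by both sides, with a Spearman rank correlation (counts
  are heavy-tailed) and a Fisher-z 95% CI.
* `fit_memory_params()` accepts per-sequence subject ids and then fits on
  a random subset of 7 subjects, holding out the remaining 8, mirroring
  the usual cross-validated protocol for fitting the memory function to
  behavioural data.
* `object_similarity()`: images resized to a common side, flattened, and
  the Euclidean distance divided by $\sqrt{\text{pixels}} \times$
  intensity range, so identical images score 0 and black-vs-white scores
  1.

## Fixation-table preprocessing

`read_fixation_table()` consumes the tabular export
(`trial_id,onset_ms,duration_ms,x,y`) produced upstream of this package
(eye-tracker parsing is out of scope) and validates rather than repairs:
malformed rows are reported with row numbers, off-screen fixations are
flagged at evaluation time, never silently dropped at read.
`preprocess_raw_fixations()` merges consecutive fixations within a 45-px
box of the running duration-weighted centroid (duration weighting is the
standard fixation-merging convention; the box is anchored to the running
centroid, not to display objects) and drops merged fixations of ≤ 50 ms.
The merge-and-drop pass is iterated to a fixed point, which makes the
operation idempotent — a single pass is not, because successive cluster
centroids can drift within the box and dropping a short fixation can make
its neighbours adjacent.

## Numerical choices and degenerate inputs

* Cross-correlation, not flipped convolution, everywhere (the
  deep-learning convention); a `flip` argument exists for fidelity checks.
* 'same' zero padding anchors even-sized kernels at cell
  $\lfloor(k-1)/2\rfloor$ from the top/left.
* `normalize01()` maps a constant map to all zeros by convention and
  preserves masks; the WTA argmax is invariant under it.
* Constant images are rejected by histogram equalization (undefined) and
  produce degenerate (all-zero) saliency maps rather than errors.
* All generators are exactly reproducible from their seed; backbone
  weights carry an MD5 fingerprint so a scanpath's provenance pins the
  exact network.

## Problem sizes used by the tests and the acceptance script

Tests and the acceptance script run the full pipeline at a reduced
display geometry — 256×320 px at 8 px/deg, 40-px objects, 64-px backbone
tiles — which preserves every angular quantity (10.5° eccentricity, 5°
objects, 1.4° IOR windows) at a quarter of the pixel density; the
measured guarantees (100% at fixation 6; chance levels; oracle
equivalences) are geometry-independent by construction. The chance-model
analyses use $10^5$ draws; parameter recovery uses 500 sequences.

## Limitations

The shipped backbone is deliberately tiny: it demonstrates and tests the
architecture contract, not the search efficiency a deep pretrained
hierarchy delivers — with random shallow features, array search performs
near chance guidance even though all structural guarantees hold. The
synthetic generators emulate geometry, luminance statistics and revisit
dynamics of laboratory search displays; they do not emulate semantic
scene structure, object co-occurrence, foveated acuity or saccade
latency, so green tests here certify the machinery, not behavioural
realism on natural images. The recognition decision inherits the
backbone's representational power. The finite-IOR and size-constraint
parameters are meant to be fitted to behavioural data via the provided
estimators; their defaults are fixture values, not behavioural claims.
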