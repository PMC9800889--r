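---
title: "Automatic myocardial strain: models, phantom and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic myocardial strain: models, phantom and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echostrain)
```

## The measurement model

Longitudinal strain summarizes how much the myocardial wall shortens along
its long axis during systole. The pipeline measures it geometrically:

1. segment the left-ventricular myocardium (LVM) in every frame;
2. extract the **centerline** — the mid-curve between endocardium and
   epicardium — on the end-diastolic (ED) frame, where the wall is longest;
3. estimate a dense displacement field $f_t$ between consecutive frames and
   advect the centerline materially, $\check{c}(t+1) = \check{c}(t) + f_t$,
   sampling $f_t$ bilinearly at each sub-pixel point;
4. with $\tau(t)$ the centerline arc length (mm), report
   $\varsigma(t) = \bigl(\tau(t) - \tau(0)\bigr) / \tau(0)$, peak GLS
   $= \min_t \varsigma(t)$, and regional strain per segment of the
   16-segment model.

The strain is a signed fraction internally; user-facing CSV output prints
percent. Study-level GLS is the mean of the available apical-view peaks
(`average_gls()`).

## Networks

**Segmentation (3D-CSN).** A U-net style encoder-decoder over 3-frame
volumes: per level two 3×3×3 convolutions with ReLU, then max pooling; the
decoder mirrors it with upconvolutions and skip concatenations; a 1×1×1
convolution produces two-class logits, softmaxed per voxel. The 3×3×3
kernels mix adjacent frames so each frame's boundary is constrained by its
neighbours. One architectural deviation was forced by arithmetic: a 3-frame
temporal axis cannot be halved four times, so pooling and upconvolution act
spatially only (2×2×1) while convolutions remain 3D. Channel widths start at
`base_filters` (default 32) and double per level; the stated description
leaves encoder widths open, and this is the conventional choice. The loss is
cross-entropy plus one minus the mean soft Dice: the two-term form is used
because a literally negated sum of log-probability *and* Dice overlap would
reward low overlap; the stated intent "Dice loss + cross entropy" governs.
Training uses SGD with momentum (default learning rate 2e-4, batch 6).

**Motion (RAFT-style).** Both frames pass through a shared-weight residual
encoder (filters 64, 64, 128, 128, 192, 192; strides 2, 1, 2, 1, 2, 1, so
features live at 1/8 resolution). The all-pairs correlation volume
$C_{ijkl} = \sum_h g(I_1)_{ijh}\, g(I_2)_{klh}$ is computed as one matrix
product, then average-pooled over the target ($kl$) dimensions into a
4-level pyramid (kernels 1, 2, 4, 8) while the source ($ij$) dimensions keep
full resolution. Each refinement iteration looks up a $(2r+1)^2$ window
(default radius 4) around the flow-displaced position in every level by
bilinear sampling, feeds the features with the current flow and a context
encoding into a ConvGRU (hidden width 96), and emits an update $\Delta f$;
the flow starts at zero and the final 1/8-resolution estimate is upsampled
bilinearly (×8 in size and value). Twelve iterations are the default.
Training minimizes the sequence loss
$\sum_{i=1}^{N}\gamma^{\,N-i}\,\overline{\lVert f_{gt}-f_i\rVert_2}$ with
$\gamma = 0.8$ (per-pixel mean, final iterate weight 1; the printed exponent
uses an undefined symbol and is read as $N-i$, matching the stated emphasis
on later refinements) under AdamW ($\beta = 0.9, 0.999$).

Because no deep-learning framework exists in the target environment, both
networks are implemented directly: im2col + BLAS products with hand-derived
backward passes, verified against numerical differentiation in the tests.
Flow training uses *truncated* backpropagation through time: each iterate's
loss flows through its own update step, the correlation volume and both
encoders, while the hidden state, the incoming flow and the lookup
coordinates are treated as constants at iteration boundaries. This keeps
memory linear in iterations, and the gradient checks confirm it is exact for
a single iteration; the small bias it introduces across iterations does not
prevent the fine-tuning smoke tests from converging.

## The phantom: a stated world with exact answers

`make_phantom()` builds a horseshoe-shaped band (annulus of radii
`r_endo`/`r_epi` with an angular opening at the base) in a 256×256 image at
0.3 mm/px — typical of apical echocardiographic views — with ~180 material
points spread evenly inside it by seeded Lloyd clustering. Contraction is a
uniform scaling about the apical focal point,
$s(t) = 1 - A\sin^2(\pi t / T)$, chosen deliberately: a uniform scaling
multiplies *every* arc length by $s$, so the true strain has the closed form
$\varsigma(t) = s(t) - 1$ and the acceptance checks compare against an exact
oracle rather than a simulation. Defaults $A = 0.15$ and $T = 16$ frames per
cycle sit in the physiological range of healthy GLS magnitudes and typical
cine lengths. Rigid-translation and zero-motion modes provide null controls.
The analytic flow field is affine in position, which has a useful
consequence: bilinear interpolation reproduces it exactly, so oracle-flow
tracking is exact to rounding error and any end-to-end error isolates the
geometry stages.

Speckle is emulated as smoothed exponential multiplicative noise attached to
*material* coordinates, so texture advects with the tissue and motion is
learnable from intensity alone. What the phantom does **not** emulate:
point-spread-function blur, attenuation, shadowing, out-of-plane motion,
vendor texture statistics, or pathological regional heterogeneity (the five
motion patterns of clinical simulation datasets are reduced to
contraction / rigid / zero). A green test on the phantom therefore
establishes the correctness of the machinery — geometry, tracking, losses,
training dynamics — not clinical-grade accuracy on real ultrasound.

Material points keep a ~3 px clearance from the band boundary (shrunk for
narrow bands) so that advected points and all four bilinear taps stay
strictly inside every rasterized mask.

## Annotation operators

Masks are generated from point sets by an **alpha-shape** (Delaunay
triangulation filtered by circumradius; rasterization is inclusive
point-in-triangle): the standard concave-hull construction, with `"auto"`
choosing the smallest alpha whose kept triangles form one edge-connected set
covering every point. Sparse point displacements $V_k = P_k(t{+}1) - P_k(t)$
become dense supervision by **thin-plate-spline** scattered interpolation.
The source material says only "cubic interpolation"; no triangulated-cubic
(Clough-Tocher style) interpolator is available in the environment, and the
thin-plate spline satisfies the same contracts this package tests — exact at
anchors and exact for constant and affine fields — while being smooth
everywhere. Mask pixels outside the anchors' convex hull fall back to
nearest-anchor extrapolation and are counted in a log message. Cine-loop
clipping takes the two stride-2 phase subsequences and splits each into
halves — the reading of "sampling every other frame … cut into 4 cine-loop"
that yields exactly four loops partitioning the frames; stride-2 sampling
doubles apparent inter-frame motion, widening the displacement distribution
seen in training. Augmentation substitutes generic transforms (horizontal
flip with flow negation, gamma jitter, multiplicative noise) for unavailable
scanner-specific recipes; small rotations were omitted as they add little at
phantom scale.

## Numerical choices

* **Centerline.** Zhang-Suen thinning, longest geodesic path (8-connected,
  Euclidean weights), spur trimming by clearance (distance-transform value
  below 0.9× the median half-width, capped at 3 half-widths per end), light
  binomial smoothing, then end regrowth along a Kasa circle fit of the
  terminal points (straight-line fallback), stopping at 2 px boundary
  clearance. The 2 px stop is load-bearing: a tracked end point keeps all
  four bilinear taps inside the (contracting) mask, which is what lets
  oracle-flow strain recovery come out exact. The apex is the point of
  maximal perpendicular distance from the end-to-end chord (ties toward the
  smaller index; the source never defines the apex operationally).
* **Segments.** Boundaries are arc-length parameters fixed at ED (three
  equal arcs per side of the apex); membership is material. Edges straddling
  a boundary are split by their ED arc fraction, so the six segment lengths
  sum *exactly* to the total at every frame — conservation holds to
  rounding, not to a tolerance.
* **Window fusion.** Overlapping 3-frame segmentation windows average class
  probabilities before the argmax (ties go to myocardium); the combination
  rule is unstated in the source and averaging is the symmetric choice.
* **Correlation scaling.** The exported `correlation_volume()` returns raw
  dot products (the stated definition); inside the model the pyramid is
  divided by $\sqrt{C}$ for update stability, absorbed into the learned
  weights.
* **Flow masking.** The pipeline zeroes flow outside the 2 px-dilated mask
  rather than cropping, preserving the fixed input-size contract while
  honouring the region of interest; corrupting flow values outside that
  region provably changes no output (tested).
* **Degenerate inputs.** Empty-vs-empty Dice returns 1 with a message;
  all-equal ICC tables return 1 with a warning; straight centerlines admit
  any interior apex; disconnected masks reduce to their largest component
  with a warning; out-of-bounds tracked points are clamped and counted.
* **Determinism.** Every stochastic step (weight init, batch sampling, point
  placement, speckle) flows through one seed argument and restores the
  caller's RNG state; pipeline outputs are bitwise identical across runs
  with the same seed.

## Tiny-scale training regime

The stated hyperparameters (learning rate 2e-4, batches 6/12, 50k-100k
iterations) are the configuration defaults, but exercising them at desk
scale is neither possible nor intended. The smoke tests train on a 32 px
phantom with reduced widths (segmentation: 2 levels × 4 filters, SGDM at
lr 0.05, batch 2; flow: filters 8-16, hidden 16, 4 iterations, AdamW at
3e-4): learning rates appropriate to the tiny regime, documented here once
and not tuned against outcomes. Under fixed seeds the segmentation loss
falls well below half its initial value within 200 iterations and reaches
Dice > 0.9 on every frame, and fine-tuning reduces the flow network's
end-point error on held-out pairs several-fold.

## Known limitations

* Clinical-scale results (Dice ≈ 0.8 on real echo, AEPE ≈ 0.05 mm/frame,
  GLS bias ≈ −1.2%) require vendor simulation data, annotated patient
  studies and GPU training; nothing at desk scale validates them, and this
  package does not claim them.
* Truncated BPTT biases multi-iteration flow gradients (exact only per
  iteration); full unrolling would be straightforward but slower.
* The centerline's skeleton stage is accurate to ~1-2 px near band ends;
  strain is insensitive to this (it is a *relative* length change), but
  absolute arc lengths inherit the error.
* ED/ES event detection, view classification and DICOM ingestion are out of
  scope; frame 0 is taken as ED.
* The 18 per-view segments collapse onto the 16-segment model by averaging
  duplicated apical labels — a labeling convention, not an anatomical
  registration.
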