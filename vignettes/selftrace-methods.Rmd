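---
title: "Self-learning neuron tracing: model, parameters, and design notes"
author: "selftrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-learning neuron tracing: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Automatic neuron tracers reconstruct a neuron's tree-shaped morphology from a
3D fluorescence microscopy volume. Most of them threshold the image, follow
bright tubular signal, and stop wherever the signal drops out — so a staining
or imaging gap truncates the reconstruction, and the distal arbor beyond the
gap is silently lost. Supervised voxel classifiers can recognize neurite
texture across such gaps, but they normally need hand-labeled training data
for every new image type.

`selftrace` removes the human from that loop. The key observation is that an
*initial* automatic reconstruction, however incomplete, already contains its
own training data: the parts of the tracing that are unambiguously correct
can be identified automatically and used as foreground exemplars, with their
surroundings as background exemplars. A classifier trained on those exemplars
then predicts neuron signal over the whole volume — including across gaps —
and the tracer is re-run on the cleaned-up image.

# The pipeline

One round executes these stages (`run_pipeline()`):

1. **Initial tracing.** Any SWC reconstruction is accepted
   (`trace_adapter()`); otherwise the built-in shortest-path-tree tracer
   runs (`baseline_trace()`).
2. **Confidence scoring** (`score_segments()`). The reconstruction is cut
   into segments at branch points. For a segment with endpoints $i, j$ and
   mean intensity $\bar I_{ij}$ (arc-length-weighted trapezoidal mean along
   the centerline), the image is masked along the segment's tube and the
   cheapest intensity-weighted path between $i$ and $j$ *around* the mask is
   found. With $\bar I^*_{ij}$ the mean original-image intensity along that
   alternative path, the score is
   $C_{ij} = \bar I^*_{ij} / \bar I_{ij}$.
   If a genuine alternative bright route exists (a parallel neurite, a loop
   artifact, an ambiguous tangle), $C_{ij} \approx 1$ and the segment is
   suspect; if the only way around is through dark background,
   $C_{ij} \ll 1$ and the segment is trustworthy. Segments with
   $C_{ij} \le \theta$ (default $\theta = 0.5$) are *confident*.
3. **Exemplar layers** (`build_label_volume()`). Around confident-segment
   centerlines three concentric layers are laid out by exact Euclidean
   distance: a core (foreground samples), a middle annulus (uncertain,
   excluded from training), and an outer annulus (background samples). The
   dilated neighborhood of uncertain segments is excluded as well. Border
   voxels whose feature window would leave the volume are dropped.
4. **Balanced sampling** (`draw_training_samples()`). Equal numbers of
   foreground and background voxels, drawn uniformly without replacement.
5. **Features** (`mwr_features()`). For each sample voxel a
   $16^3$ window is decomposed by a 3-level separable 3D wavelet transform;
   all detail coefficients plus the final smooth band form a feature vector
   whose length equals the window's voxel count (4096).
6. **Selection** (`mrmr_select()`). The top 20 features by
   minimum-redundancy maximum-relevance: greedily maximize
   $I(c, f) - \frac{1}{|S|}\sum_{s \in S} I(f, f_s)$, with mutual
   information estimated from 3-state discretized features.
7. **Classifier** (`train_classifier()`). A soft-margin RBF-kernel SVM at
   the LIBSVM defaults (cost 1, $\gamma = 1/|S|$), on standardized features.
8. **Foreground growth** (`grow_foreground()`). Starting from the confident
   cores, a breadth-first front marches to 26-connected neighbors; each
   unknown voxel is classified exactly once, accepted voxels extend the
   front. Because acceptance depends only on the classifier, the final mask
   does not depend on the expansion order.
9. **Adjustment and re-trace** (`adjust_image()`, `baseline_trace()`).
   Predicted background is zeroed; predicted foreground is raised to at
   least the final tracing threshold (1); the tracer re-runs on the adjusted
   image and now walks straight across former gaps.

`run_iterative()` feeds each round's reconstruction in as the next round's
initial tracing. A gap too wide for the first round can succeed later:
round 1 typically extends the reconstruction closer to the gap, so round 2
trains on exemplars that flank it.

# Parameters

| parameter | default | meaning |
|---|---|---|
| `confidence_threshold` | 0.5 | segment confident iff $C_{ij} \le$ this |
| `layer_radii` | radius-derived | core / middle / outer exemplar radii (voxels); default core $=\max(\text{median SWC radius},1)$, middle $=$ core$+2$, outer $=$ middle$+3$ |
| `window_side` | 16 | cubic feature window side (voxels) |
| `mwr_levels` | 3 | wavelet decomposition depth |
| `k_features` | 20 | mRMR-selected feature count |
| `wavelet` | haar | orthonormal filter pair (`"d4"` selectable) |
| `max_per_class` | 500 | training-sample cap per class |
| `final_trace_threshold` | 1 | tracing threshold on the adjusted image |
| `connectivity` | 26 | neighborhood for path search and growth |
| `rounds`, `convergence_ratio` | 1, 0.05 | iterative mode control |

The window, level, feature-count and final-threshold defaults are the
reference operating point for confocal single-neuron stacks; everything is
overridable per run.

# The synthetic phantoms

`generate_phantom()` renders anti-aliased tubes (exact distance-to-polyline,
1-voxel linear falloff) of configurable radius and intensity on a constant
background, with branch points, hard signal gaps, faded sections, an
optional per-axis intensity ramp, and clipped additive Gaussian noise — and
returns the exact centerline tree. `make_loop_phantom()` adds the one
structure a tree cannot represent: a closed bright loop, half of which is
"traced", so the traced half has a genuine alternative path.

What the phantoms emulate: tubular geometry of varying caliber,
branch points, signal dropout (the gap failure mode), intensity
inhomogeneity, detector noise. What they do not emulate: the microscope's
anisotropic point-spread function, autofluorescence clutter, crossing
neighbor neurites, and multi-neuron scenes. Tests passing on phantoms
therefore validate the algorithmic contracts (scores separate the intended
fixtures, gaps of the constructed kind are bridged, determinism holds) — not
performance on any particular real dataset.

Phantom sizes used in the validation suite: $96 \times 128 \times 128$ for
the end-to-end gap phantoms, $48 \times 64 \times 160$ for the iterative
rescue phantom, and $\le 48^3$ for the geometry oracles; these keep the full
suite in the minutes range on a single core while leaving every tube several
window-widths away from the volume border.

# Numerical and design choices

**Path cost.** Node cost $c(x) = (1 - I(x)/I_\max)^2 + 10^{-6}$; the cost of
a step between neighbors is the mean of their node costs times the Euclidean
step length. Bright voxels are nearly free, dark voxels cost $\approx 1$ per
voxel. Distance ties in the search are broken by linear voxel index
(z fastest), so paths are deterministic.

**Hard mask exclusion.** The masked segment tube is *excluded* from the
alternative-path graph rather than merely zeroed. With a soft mask, the
cheapest route between the endpoints of any fairly straight segment is to
re-thread the masked corridor itself (a detour around the tube costs more
than the $\approx 10\%$ per-voxel saving of background over zero), and since
$\bar I^*$ is measured on the original image the score collapses to 1 for
exactly the segments that are most reliable. Exclusion implements the
question the score is meant to ask — *is there a different bright route?* —
robustly. The endpoint protection spheres are sized one voxel larger than
the masking tube so a free corridor always surrounds each endpoint; if
exclusion still disconnects the endpoints, no alternative route exists at
all and the segment scores 0.

**Wavelets.** Periodized orthonormal filters (Haar default, 4-tap Daubechies
selectable) keep the coefficient count equal to the voxel count at every
level, give perfect reconstruction to round-off, and conserve energy
(Parseval) — all three are asserted in the tests. Windows at the volume
border are mirror-padded (edge-repeating reflection).

**MI discretization.** Features are binned into 3 states at mean
$\pm$ one *population* standard deviation. With the sample ($n-1$) standard
deviation a balanced binary feature falls entirely inside the middle bin and
loses all information; the population form places the boundaries exactly on
the two values.

**mRMR scheme.** The first-order incremental (difference) form, the only
scheme with per-step work linear in the remaining candidates. Exact ties go
to the lowest feature index.

**Baseline tracer.** Deliberately simple and deliberately gap-limited:
threshold, keep the seed's connected component (this is what makes it stop
at gaps), build an intensity-weighted shortest-path tree, then repeatedly
accept the geodesically furthest unclaimed voxel's walk-back path as a
branch. Engineering details that matter: candidate leaves are ranked by
geodesic *length* (cost-weighted distance is nearly zero everywhere inside
bright tubes and ranks surface voxels above tube ends); nodes are
hill-climbed (strict ascent) onto the ridge of the distance-to-background
transform so the estimated radius spans the tube; acceptance counts only
the *uncovered* portion of the walk-back (otherwise surface bumps re-thread
long covered stretches as duplicate branches); claimed territory is stamped
with spheres of radius EDT$+2$; terminal twigs shorter than
`min_branch_length` are pruned; and chain nodes get two passes of Laplacian
smoothing — on thick predicted-foreground sleeves the ridge is a plateau and
unsmoothed node chains zigzag, inflating reported length by up to a quarter.
The re-trace after foreground prediction uses a larger pruning length
(`final_min_branch_length`, default 10) because the predicted sleeve is
thicker than the neurite it contains.

**Brightfield.** When the background is brighter than the foreground,
scoring runs on the intensity-inverted image ($I_\max - I$), which keeps the
bright-is-cheap cost semantics instead of re-interpreting the score ratio.

**Degenerate inputs.** Segments with fewer than 3 nodes or shorter than 5
voxels are too short to score and inherit their parent segment's label
(confident at the root). A segment with zero mean intensity scores
$+\infty$ (uncertain). An image whose maximum is 0 is rejected. If no
segment is confident, the pipeline aborts with an `insufficient_exemplars`
condition and advice to lower the threshold or supply a better initial
tracing — iterating from a richer tracer is the documented remedy.

# Known limitations

* **Classifier variance on out-of-distribution windows.** The RBF-SVM's
  decision on patterns between its two training clusters (e.g. a much
  fainter tube than any exemplar) can flip with the random background
  subsample. On the iterative-rescue phantom this is visible as a minority
  of sampling seeds in which round 1 already crosses, or round 2 does not;
  the validation suite exercises one fixed draw and this vignette records
  the sensitivity. Averaging several balanced draws would reduce it, at the
  cost of departing from the single-classifier design.
* **Isotropic voxels assumed.** `spacing` is carried but not used in path
  costs or distances.
* **The growth front classifies the sleeve.** Windows centered next to a
  neurite still contain it, so the predicted foreground is systematically
  one to three voxels thicker than the tube; the re-trace's centerline is
  recovered by the ridge climb, but reported radii reflect the sleeve.
* **No PSF or multi-neuron simulation** in the phantom generator; results on
  phantoms bound algorithmic correctness, not biological recall.
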