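---
title: "Tracking unlabeled cells in 3D phase-contrast volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking unlabeled cells in 3D phase-contrast volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellshift)
```

## The problem

Migration assays in 3D gels follow large populations of unlabeled cancer
cells through time-lapse phase-contrast Z-stacks. The imaging regime is
hard for segmentation-first pipelines: low magnification, strongly
anisotropic voxels (0.78 µm in X/Y versus 8 µm between slices), gel
texture, and phase-contrast optics that turn every cell into a bright
focal disk wrapped in off-focus interference cones. No linear point
spread function exists for phase contrast, so deconvolution is not an
option. `cellshift` implements a detection-plus-model-evolution design:

1. **Template matching.** Each contrast-boosted volume is
   cross-correlated (via FFT) with a small subvolume cropped around one
   cell. Cells become smooth correlation blobs whose peak sits at the
   cell center; irregular halo artifacts are averaged away.
2. **Soft-maximum detection.** All distinguishable correlation peaks are
   detected with a morphological soft maximum filter and labeled as
   objects.
3. **Mean-shift tracking.** Every cell carries one flat-kernel mean-shift
   tracker that re-converges in each new frame, yielding continuous
   (sub-voxel) positions.
4. **Collision management.** When trackers converge to the same spot the
   affected trajectories are stopped — unless one of them is a
   short-lived "parasite", which is removed without harming the long
   trajectory. Untracked objects always receive a fresh tracker, so
   every detected cell is tracked at all times.
5. **Trajectory descriptors.** Trajectories long enough to be meaningful
   are summarized by duration-normalized migration features and compared
   across conditions with a rank-based k-sample test.

The design premise is worth spelling out: *because* every detected object
holds a tracker, a tracker drifting onto a neighbor is guaranteed to
produce a detectable collision. Stopping at collisions trades trajectory
length for validity; no probabilistic re-linking of fragments is
attempted, because when cells mingle even an expert cannot say with
certainty which emerged where.

## Conventions

Volumes are numeric arrays with axis order `(z, y, x)`; all positions are
continuous `(x, y, z)` voxel coordinates, 1-based (the first voxel center
is `(1, 1, 1)`). Physical units enter only through the voxel spacing
`(0.78, 0.78, 8)` µm and the frame interval (4 min). Distances used by
the tracker (kernel, collision, margins) are in index space, as the
anisotropy is handled by the anisotropic parameter defaults below.

## Preprocessing

`enhance_contrast()` clips intensities at two quantiles (defaults 0.01
and 0.99) and rescales to 8-bit. The operator is order-preserving inside
the clip window; its purpose is only to suppress the dim gel background
before correlation. `correlate_volume()` then computes plain
(unnormalized) cross-correlation — a raw product sum, with no mean
subtraction or local-energy normalization — implemented as zero-padded
FFT correlation cropped to the input shape, so no circular wrap-around
can join opposite faces. The result is rescaled per volume to `[0, 255]`
(min–max); a fixed global range is available via `rescale = "range"` for
sequences where a shared scale matters. The template's center voxel is
aligned with the output voxel, so a blob peak coincides with the cell
center.

## Detection: the soft maximum filter

Three parameters drive detection, all on the 8-bit correlated scale:

| parameter | default | meaning |
|---|---|---|
| `neighborhood` | 20 × 20 × 10 voxels (x, y, z) | local-maximum window, about one cell volume; anisotropic to match the voxels |
| `soft_thresh` | 5 | leniency: a voxel within 5 of its neighborhood maximum counts as "at" the maximum |
| `noise_thresh` | 120 | minimal correlated intensity of a genuine cell peak |

A maximum filter assigns each voxel its neighborhood maximum (windows are
truncated at the faces — zero padding would suppress genuine border
maxima; even extents put the extra voxel toward lower indices so the
oracle tests can be exact). Voxels within `soft_thresh` of that maximum
form the mask; masking the correlated volume and thresholding at
`noise_thresh` yields one foreground blob per distinguishable peak.
Connected components use 26-connectivity, deliberately: two cells close
enough for their peaks to merge inside the window *should* come out as a
single "conjoined" object and be followed by one tracker until they
part. Dim cells whose peak falls below `noise_thresh` are simply not
detected until their signal rises — by construction such weak peaks are
also the least able to steal a neighbor's tracker.

## Mean-shift tracking

Each tracker repeatedly moves to the intensity-weighted mean of the
voxels under a flat (uniform) cubic kernel of side 7 voxels, stopping
when the shift drops below 0.01 voxel (`max_iterations = 100` guards
against pathological inputs; the paper-style stop rule almost always
fires first). Convergence is insensitive to kernel sides 3–9, while an
oversized kernel risks capture by adjacent cells.

One numerical choice deserves emphasis. If the kernel window is snapped
to the nearest integer voxel, the kernel-mean map becomes piecewise
constant in the tracker position: for realistic blob widths the pull per
step is below half a voxel, every rounding cell contains its own
spurious fixed point, and trackers stall one to three voxels behind a
moving cell — association then breaks. `kernel_mean()` therefore
positions the kernel continuously: an edge voxel contributes in
proportion to the overlap between its unit cell and the kernel extent.
The kernel mean is then continuous in the kernel position, the only
fixed points are genuine blob peaks, and convergence to sub-0.01-voxel
precision is routine. This is a property of the estimator, not a change
to the model: the kernel is still flat with a 7-voxel support.

Trackers whose center comes within 10 voxels of an X/Y face or 5 slices
of a Z face (inclusive) are stopped (`boundary`); a tracker whose whole
kernel sees zero intensity stays put and is logged.

## The per-frame loop and collision management

`advance_frame()` runs, in order: converge all active trackers → stop
those near the boundary → find and resolve collisions → detect all
objects → associate trackers to objects → spawn a tracker on every
untracked object. New trackers hold the object centroid at their birth
frame and first converge in the next frame. If a centroid rounds outside
its own (non-convex) object, the tracker snaps to the nearest member
voxel, which makes the "every object holds a tracker" invariant hold by
construction rather than by luck.

Collisions are groups of converged trackers whose positions agree within
`d_xy = 3.5` voxels in x and y (half the kernel: two kernels closer than
that overlap one peak) and `d_z = 2` slices; groups are connected
components of the pairwise relation, so chains resolve together. The
resolution rule:

* if **exactly one** member has a lifetime of at most
  `parasite_max_life = 5` frames, it is a parasite — typically born of a
  false detection or an oversegmented cell extension that immediately
  converged back onto the tracked cell — and is removed; the longer
  trajectory continues unbroken;
* otherwise **all** members stop. Their trajectories end at the previous
  frame's position, and the conjoined object picked up at the same frame
  starts a fresh trajectory. Ambiguous groups (several parasite-range
  members) stop everyone: stopping is the validity-preserving default.

Tracker ids are never reused; every trajectory carries exactly one end
reason (`collision`, `boundary`, `parasite`, `sequence_end`).

## Trajectory descriptors

Features are computed in physical units (µm, hours) after per-axis
scaling. For a trajectory with points \(p_0, \dots, p_{n-1}\) over
duration \(T\) hours:

* **average speed** \(= \sum_i \lVert p_{i+1} - p_i \rVert / T\) (µm/h);
* **MRDO rate** \(= \max_i \lVert p_i - p_0 \rVert / T\) (µm/h), the
  maximum relative distance covered from the origin, duration-normalized;
  the unnormalized maximum displacement is attached for transparency.

Average speed is read as path length over duration (the standard
meaning); readers wanting net-displacement speed can derive it from the
emitted maximum displacement. Both features are translation-invariant
and satisfy speed ≥ MRDO rate, with equality only on straight
constant-velocity paths. Because duration normalization makes short
follow-ups noisy and outlier-prone, trajectories with fewer than
`min_frames = 45` points (3 h at 4 min/frame) are excluded from feature
analysis — they remain in the trajectory output. Condition comparisons
use the Kruskal–Wallis rank test with tie correction
(`compare_conditions()`), reported as H, degrees of freedom and p-value
alongside per-condition medians and interquartile ranges.

## The synthetic scene generator

Real validation data for this method is supervised microscopy, which a
package cannot ship. Instead `simulate_scene()` produces ground-truthed
scenes and `render_frame()` draws them:

* **appearance** — a Gaussian-profile bright focal disk (radius 7.5
  voxels, i.e. a 15-pixel cell diameter, core σ = radius/3) with
  additive off-focus rings growing linearly with defocus over 12 slices:
  the double-cone geometry of a phase-contrast cell. Per-cell intensity
  factors (0.85–1) reproduce the real spread of peak brightness that
  motivates `noise_thresh`;
* **background** — seeded band-limited texture (white noise smoothed
  with a (3, 3, 1) window, amplitude 12): fine-grained relative to a
  cell, like gel fiber texture, so correlation averages it away;
* **motion** — Gaussian random walks (σ = 0.8 voxels/frame in X/Y,
  0.15 in Z; steps rarely exceed a cell radius, matching the imaging
  cadence) reflected at an inset box two voxels inside the tracking stop
  margin, plus scripted events: crossings (straight pass-through paths),
  divisions (child offset ramps up from one voxel), entries (a cell
  appears at the inset edge and moves inward) and exits.

Scenes are bit-reproducible under a seed, and rendering never touches
the caller's RNG stream. `score_against_truth()` measures recall
(fraction of ground-truth points covered by a trajectory point within
10 voxels XY / 3 slices Z), precision, and an identity-switch fraction.
Identity matching uses hysteresis: a trajectory keeps its matched cell
while that cell remains in range, so legitimately conjoined tracking is
not scored as an error, while a tracker that truly drifts to another
cell (its old cell leaves the neighborhood) is.

**What passing synthetic tests does and does not show.** The generator
reproduces the geometry that the algorithm's parameters key on — blob
scale, peak spacing, motion per frame, event topology — so it exercises
every code path (detection, convergence, collisions, parasites, entries,
divisions, filtering). It does not reproduce real phase-contrast optics
(no negative halo lobes unless `halo_sign = -1`), cell morphology
changes, gel drift, or focus wobble; quantitative scores on synthetic
scenes are design targets, not claims about any particular microscope.

## Scenario fixtures and the benchmark

Three deterministic (noise-free) scenes pin down the event semantics:
`scene_crossing()` (two cells pass through each other; the expected
outcome is exactly four trajectories: the two originals stopping at the
collision, one conjoined tracker, one spawned at parting),
`scene_parasite()` (a transient secondary peak whose tracker is removed
as a parasite when short-lived, or stops both trajectories when not),
and `scene_division()`. In the crossing fixture the two cells differ in
brightness (factors 1 and 0.75) and pass three voxels apart: two real
cells are never identical, and a perfectly symmetric head-on crossing
would leave the conjoined tracker balanced on a saddle point, which is a
measure-zero configuration rather than a behavior worth pinning tests
to.

The default benchmark (`benchmark_scene()`) uses a 160 × 160 × 24 voxel
volume — 125 × 125 µm across and 14 slices of headroom above the Z
margins — with 20 cells over 100 frames (6.7 h), two scripted crossings,
two entries and one division; initial positions are laid out separated
and clear of the crossing corridors so that event statistics are driven
by the script plus genuine random-walk encounters. This scale keeps a
full tracking run to a few minutes on one CPU while exercising every
mechanism; it is the problem size used throughout the test suite and the
acceptance script.

Random-walk encounters make the raw trajectory count on the benchmark
much larger than the cell count: every near-contact stops two
trajectories and starts new ones, and every oversegmentation blip costs
a parasite. That is the intended economy of the method — short fragments
are cheap, identity errors are expensive — and the 45-frame filter
removes the fragments from feature analysis.

## Degenerate inputs and numerical edges

* Constant volumes have no contrast: `enhance_contrast()` warns and
  returns zeros.
* A segmentation of an empty (all-background) volume yields an empty
  object list; tracking simply spawns nothing.
* A tracker in a zero-intensity region keeps its position (flagged) —
  cells legitimately dip below `noise_thresh` and reappear.
* Collision lifetimes count tracked points including the collision
  frame; "lifetime ≤ 5" is inclusive.
* The boundary test is inclusive (`distance ≤ margin`).
* FFT sizes are padded to products of 2, 3, 5 for speed; the correlation
  is exact (oracle-tested to 10⁻⁶ relative against the sextuple loop).

## Known limitations

* Conjoined cells are tracked as one object; no attempt is made to
  re-identify which cell is which after they part.
* The detector will merge any two peaks closer than the neighborhood
  window; very dense fields degrade into conjoined tracking.
* The per-volume min–max rescale of correlated volumes couples
  `noise_thresh` to the brightest cell in the frame; sequences with a
  single dominant outlier cell may need the fixed-range option.
* Cell morphology is not measured; the trackers carry position only.
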