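---
title: "Tree-based consensus targeting: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-based consensus targeting: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treetarget)
```

## The targeting problem

Connectivity-guided TMS targeting seeks the point in the dorsolateral
prefrontal cortex whose resting-state time course is most anticorrelated
with the subgenual cingulate, under the additional constraint that near-scalp
points are preferable (stimulation intensity — and with it side-effect burden
— scales with coil–target distance). Fixed thresholds on either quantity
generalize poorly across datasets: absolute FC values shift with population,
acquisition and preprocessing, and any single sulcal-depth cutoff is
arbitrary. The tree-based algorithm replaces both choices with *sweeps over
ranges* and a consensus vote.

## The model and its assumptions

All computation happens on a shared voxel grid (`volume_grid`) carrying a
NIfTI-style affine. Voxel indices are 1-based in R; internally the affine
follows the NIfTI convention (0-based index to world mm), so round trips are
exact. The algorithm assumes:

* a per-subject network parcellation (input, not estimated here) in which a
  known subset of labels marks the stimulation-relevant networks;
* a seed-FC map `r(v)` obtained by correlating each voxel with a *weighted*
  seed time course — a weighted average of gray-matter voxel series with
  weights from a group-level seed FC map, excluding the stimulation mask
  itself (this sidesteps the poor SNR of the deep seed region);
* a depth map `D(v)` — Euclidean distance-to-scalp where a head mask exists,
  or FreeSurfer-style sulcal depth as a proxy — where *smaller is closer to
  the scalp*. Both conventions are unified by treating "better" as "smaller"
  at load time.

Percentile thresholds are nearest-rank with a ceiling, taken **within** the
mask passed in: the depth threshold within the personalized ROI, the FC
threshold within the depth-surviving set. Exactly `ceiling(p/100 * N)`
voxels survive, ties broken by value then voxel index, so masks are nested
in `p` and every run is deterministic.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `depth_percents` | 5–10 step 1 | % of ROI | near-scalp sweep |
| `fc_percents` | 5–100 step 5 | % of near-scalp ROI | FC sweep (stringent first) |
| `fc_direction` | `negative` | — | `negative` for anticorrelation seeds, `positive` for circuit maps |
| `connectivity` | 26 | — | component neighborhood; 26 (faces+edges+corners) matches the "components merge as thresholds loosen" behavior best |
| `dedup_tol_mm` | half a voxel | mm | duplicate-candidate radius |
| seed-region radius | 5 | mm | sphere used when a target is re-used as an FC seed for evaluation |
| cone radii | 2,4,7,9,12 | mm | documented shells; weights decay linearly to zero at 12 mm, then are normalized to mean one over the realized voxels |
| intensity slope | 3 %/mm × RMT fraction | — | linear distance-to-intensity conversion (2.7 %/mm at the default 0.9) |

The sweep ranges are the algorithm's point: they are *fixed* across
applications (the anxiety-circuit variant changes only the FC direction, the
mask and the weight map), so there is essentially nothing to tune per
dataset. The cluster baseline, by contrast, needs an FC threshold, chosen
per subject by leave-one-individual-out cross-validation
(`loocv_cluster_threshold`): each held-out subject receives the threshold
that maximized the favorable evaluation FC averaged over the *other*
subjects.

## Design choices where the design was open

* **Leaf rule.** Candidates are the childless tree nodes plus parents with
  at least two children. A component that first appears at a lenient FC
  level is a childless node and therefore a candidate; we keep this literal
  reading rather than restricting leaves to the most stringent level.
* **Parent linkage** is exact voxel-subset containment (components only grow
  under nested thresholds), tested via a single representative voxel — never
  centroid proximity.
* **Deduplication.** A centroid rediscovered at several depth thresholds is
  collapsed (within half a voxel, configurable) before the consensus vote,
  so repeated discovery does not multiply a site's vote. Whether the
  original procedure deduplicated is unknown; we chose the variant that
  keeps the vote a vote over *locations* rather than over *thresholds*.
* **Consensus ties** are broken by the more favorable FC value at the
  candidate's voxel, then by lexicographic voxel index — deterministic, and
  preferring the better-connected site.
* **Centroids are not snapped** to their component (a `snap_to_component`
  option exists): for non-convex components the reported point can lie off
  the component, which is the literal meaning of "centroid".
* **Scalp surface.** The surface is the *face-connected* (6-neighbor)
  exterior boundary of the head mask. A 26-neighbor boundary is up to a
  voxel diagonal thick along oblique directions and systematically
  underestimates surface distances by more than a voxel; the face-connected
  layer keeps the sphere-phantom error below one voxel edge. Distances are
  exact Euclidean point-to-surface-voxel-center distances (not geodesic),
  computed by chunked brute force.
* **Inter-individual distance** uses each subject's session-1 target against
  the other subjects' session-1 targets; an intra-individual distance of
  zero makes the reliability ratio *undefined* (flagged infinite and
  excluded from summaries), not "very good" — a group-level target would
  otherwise look perfectly reliable.
* **Cross-session metrics** are always computed derive-on-A/evaluate-on-B,
  roles swapped, and the two values averaged arithmetically (a Fisher-z
  option exists for correlations but the plain mean is the default).
* **E-field reliability** is reported as inter/intra correlation with the
  favorable direction *smaller* — the opposite of the distance-based ratio —
  and the output schema says so explicitly.

## What the phantom emulates — and what it does not

`phantom_spec()` builds a spherical head (radius 52 mm, 3-mm isotropic
voxels on a 40³ grid), a 9-mm cortical shell whose outer surface undulates
as meridian ridges (amplitude 3 mm, angular frequency 5) — gyral crowns are
extended ridges, not isolated bumps, and this matters: an earlier
checkerboard-bump geometry fragmented the top-depth percentile set into
dozens of one-voxel islands, each a legitimate leaf candidate that degraded
the consensus — an angular-sector network parcellation (4 labels, rotated
per subject), and signed Gaussian coupling blobs between voxel series and a
unit-variance white seed signal. Session noise is white in time, spatially
smoothed (FWHM 4 mm, as volumetric rs-fMRI data are after preprocessing) and
renormalized so the per-voxel noise sd is exactly `noise_sigma`; the
expected voxel–seed correlation at a blob center is therefore the exact
attenuation law `a / sqrt(a^2 + s^2)`, which the tests verify within three
standard errors. A smooth per-subject background coupling field (sd 0.15,
FWHM 15 mm) makes the FC map graded everywhere, as real seed-FC maps are.
Between-subject variability is rigid jitter plus amplitude scaling of the
blobs and rotation of the parcellation; within-subject sessions share the
layout and differ only in noise. All randomness derives from explicit seeds;
cohorts are bit-reproducible, and all subjects share one grid so
cross-subject registration is the identity.

Two calibrated variants exist. `phantom_spec_recovery()` is the
*unambiguous-blob* configuration used for planted-target recovery: one wide
anticorrelated cluster (sigma 15 mm — the centimetre scale of real
anticorrelation clusters — dominating the 32-mm search mask), low noise
(0.1), no background field. A consensus-of-candidates algorithm can only be
expected to pin a planted target to within a voxel when the anticorrelation
ordering over the whole near-scalp strip is unimodal; any FC-indifferent
stretch spawns genuine (per the leaf rule) but uninformative candidates that
bias the medoid by a voxel or two. `phantom_spec_two_blob()` plants a strong
deep blob in a sulcal trough and a weaker shallow blob on a crest ~27 mm
away: depth-blind clustering chases the deep blob while the tree (and cone)
algorithms stay near the scalp — the qualitative behavior that motivates the
method.

The phantom does **not** emulate BOLD physics, temporal autocorrelation
(an AR(1)-free white seed is used; the algorithms under test are invariant
to it), motion or physiological noise, surface meshes, or nonlinear
cross-subject anatomy. Passing tests on the phantom therefore validate the
*algorithmic* contracts — geometry, thresholds, tree construction, metric
arithmetic, parameter recovery under the stated conditions — not performance
on real MRI.

## Numerical choices and degenerate inputs

* Percentile counts use `ceiling(p·N/100 − 1e-9)` so that exact rational
  percentages are not inflated by floating-point noise, with a floor of one
  voxel.
* Sphere membership uses `distance ≤ radius + 1e-9`; a zero-radius sphere on
  a voxel center contains exactly that voxel.
* Empty ROIs, zero-variance seeds and absent labels are hard errors; empty
  spheres and empty surface-seed sets are warnings with empty results;
  cone seeds without valid FC coverage and LOOCV thresholds that fail for a
  training subject are skipped with a logged message.
* Weighted seed averages divide by `sum(w)`; when positive and negative
  weights nearly cancel, the error message points to the `sum(|w|)` mode.
* Component labels are ordered by decreasing size, ties by the lowest
  contained voxel index, so labelings (and "largest component" choices) are
  stable across runs and platforms.

## Problem sizes

The test suite runs the full pipeline on 28³ (4-mm) phantoms with 60 frames
and two sessions, the recovery and depth-discrimination experiments on 20
seeded 40³ (3-mm) phantoms each, the component oracle on 200 random masks up
to 10³ voxels, and the FC-attenuation check on a 20³ phantom with 500
frames. These sizes were chosen so that every contract is exercised at full
fidelity while the complete suite runs in well under two minutes on a single
core; the algorithms themselves have no size-dependent switches.

## Known limitations

* Distance-to-scalp is computed by exact chunked brute force; for very large
  surface sets (high-resolution whole-head masks) a dedicated distance
  transform would be faster. At package problem sizes this is a non-issue.
* The cone kernel's "linear decay" is a continuous linear ramp to zero at
  the outer radius; the original per-shell calibration is documented only in
  external supplementary material, so the shell-constant variant is provided
  (`profile = "shells"`) but the ramp is the default.
* The cluster baseline's threshold dialect is a retention percentile (the
  LOOCV search space); an absolute-correlation cutoff mode exists because
  the original description is ambiguous between the two.
* Cross-subject registration is assumed done by the caller (identity on the
  phantom); no nonlinear warping is provided.
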