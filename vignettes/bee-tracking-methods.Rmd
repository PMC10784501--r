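---
title: "Tracking dense bee swarms by detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking dense bee swarms by detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beetrackr)
```

## The problem

Observation-hive footage of honey bees is about as hostile as multi-object
tracking gets: hundreds of nearly identical, small, elongated targets per
frame, frequent occlusion, erratic individual motion, and a background (comb)
that looks much like the foreground. `beetrackr` implements the
tracking-by-detection half of a pipeline for such footage: an upstream
instance-segmentation detector (out of scope here) produces, for every frame,
a set of *detections with masks* — class label, bounding box, confidence
score and mask polygon per bee body. This package consumes those records,
links them into identities over time, and scores the result.

Because no public hive dataset with per-instance identities exists, the
package also ships a synthetic dense-swarm generator that plays the role of
both the footage and the detector, with a controllable error model. All
tests and the acceptance script run against it.

## The tracking core

The tracker is the classic online constant-velocity formulation. Each live
target carries a 7-dimensional state

\[ x = (u, v, s, r, \dot u, \dot v, \dot s)^\top \]

where \((u, v)\) is the bounding-box center in pixels, \(s = w h\) the box
area, \(r = w/h\) the aspect ratio (assumed constant — it has no velocity
component), and the dotted quantities are per-frame velocities. The motion
model is linear constant velocity; the observation model picks
\((u, v, s, r)\) from a detection box. Default covariances place large
initial variance (\(10^4\)) on the unobserved velocities, small process
noise on \(\dot s\) (\(10^{-4}\)), and measurement variances of 1 on the
center and 10 on area/aspect; all are exposed through `tracker_config()`.
If a predicted area would become nonpositive, the area velocity is clamped
to zero first, so every state converts back to a valid box. The measurement
update uses the Joseph form, which keeps the covariance symmetric positive
semidefinite through arbitrarily long predict/update cycles (this is
asserted property-style in the tests).

Association is per frame: the cost of pairing detection \(i\) with predicted
track \(j\) is \(1 - \mathrm{IoU}(i, j)\), solved exactly with a dense
Hungarian/Jonker–Volgenant assignment (compiled code; verified in the test
suite against exhaustive permutation search on 1000 random matrices).
Assigned pairs with IoU below the gate `iou_min` (default 0.5, i.e. 50%
overlap) are demoted to unmatched on both sides. Box IoU is the default
association score; mask IoU is available (`association = "mask"`) but costs
more and rarely changes the result when boxes are tight.

Lifecycle rules, in frame order: predict all tracks; associate; update
matched tracks, attaching the matched detection's mask; open a new track for
every unmatched detection; age unmatched tracks; delete a track once it has
gone `t_lost` + 1 consecutive frames without a detection (default
`t_lost = 1`). A deleted target that reappears is a new identity — there is
no re-identification model. `min_hits` (default 1) can require a
confirmation streak before a track's outputs are reported.

Two reporting choices deserve emphasis:

* **Outputs carry the matched detection's box and mask, not the Kalman
  posterior.** The filter is used to *predict* where a target will be so
  the right detection can be claimed; once claimed, the detection itself is
  the best available estimate of the target's extent, and the mask must come
  from a detection by construction. This is also what makes a tracker fed
  perfect detections score 100% MOTP/MOTSP rather than 100-minus-filter-lag.
* **Coasting tracks emit nothing.** A predicted-but-unmatched track has no
  mask to report; it survives silently up to `t_lost` frames awaiting
  re-association.

Defaults the upstream literature leaves open were fixed as follows:
`t_lost = 1` and `min_hits = 1` (the common online-tracking defaults;
every detection may open a reported track), deterministic tie-breaking in
the assignment (equal-cost optima resolve toward lower detection index),
and detections are pre-filtered at score ≥ 0.7, the detector operating
point used throughout (the threshold is inclusive: the stated minimum is
accepted).

## Coordinates, I/O and downsampling

All coordinates are 0-based with origin at the top-left; boxes are half-open
\([x, x+w) \times [y, y+h)\), so a box's discrete area is exactly \(wh\) and
box IoU coincides with the pixel-set IoU of an equally sized rectangular
mask. Masks are polygon ring lists combined by the even-odd rule; a pixel
belongs to a mask iff its *center* is inside. That single rule decides every
boundary dispute deterministically and makes the rasterizer exactly
invertible against an independent point-in-polygon oracle (tested).

Annotation files use a COCO-dialect JSON: `images`, a single category `"b"`,
and `annotations` with `bbox = [x, y, w, h]`, polygon `segmentation` (flat
coordinate lists; uncompressed RLE is accepted on read and converted to
exact rectangle rings), `score` on detections and a persistent `instance_id`
on ground truth and tracking output. Tracking results additionally export as
MOTChallenge text (`frame, id, bb_left, bb_top, bb_width, bb_height, conf,
-1, -1, -1`; 1-based frames in that format only).

The letterbox transform mirrors the square model input used by the upstream
detector: a 1920×1080 frame is padded with zeros to a square and scaled by
`model_size / max(w, h)` (512/1920 by default). Padding is bottom/right by
default (`pad_top = pad_left = 0`) so original coordinates are unchanged
before scaling; the pad fields make any other convention recoverable. The
transform is affine, hence exactly IoU-preserving, and round-trips to
\(10^{-6}\) px.

Frame-rate downsampling keeps frames \(0, k, 2k, \dots\) with
\(k = \mathrm{fps}/\mathrm{target}\), which must be a whole number — there
is no resampling. A 30 fps, 10-second sequence yields exactly 50, 100 and
150 frames at 5, 10 and 15 fps. Kept frames are renumbered from 0 with the
original indices preserved as metadata.

## Evaluation stack

**Average precision** (instance segmentation, single class, so mAP = AP):
detections pooled over frames, sorted by descending score, each greedily
matched to the highest-IoU unmatched ground truth in its frame, a true
positive iff IoU ≥ 0.5 (inclusive). AP integrates the exact
precision–recall step curve under its precision envelope (all-point
interpolation, the modern convention; 11-point is available as an option).
With no ground truth and no detections AP is reported as 1 with a
`degenerate` flag; with ground truth but no detections it is 0.

**CLEAR MOT** on boxes: per frame, correspondences from the previous frame
are carried over while their IoU still clears the gate; the remainder is
matched by the Hungarian algorithm maximizing IoU (pairs below the gate are
made ineligible before solving, so an ineligible high-IoU pair can never
outbid two eligible ones). Unmatched ground truth are misses, unmatched
results false positives, and a ground truth matched to a different result id
than its *last* match — across gaps — is an identity switch. Then
MOTA \(= 100\,(1 - (\mathrm{FN}+\mathrm{FP}+\mathrm{IDSW})/\mathrm{GT})\),
recall \(= 100\,\mathrm{TP}/\mathrm{GT}\), and MOTP is the mean IoU of
matches × 100. The original CLEAR formulation defines MOTP as a distance
error; the percentage convention used by the MOT benchmarks is adopted here
because it is the scale these metrics are reported on in this domain (high
is good).

**MOTS** on masks: the same walk with pixel-mask IoU and a *strict*
threshold (match requires IoU > 0.5, per the MOTS convention — contrast
with AP's inclusive ≥ 0.5; both boundaries are tested). Result masks within
a frame must be pairwise disjoint, as the MOTS problem definition requires;
violations are a validation error listing the offending pairs.
MOTSA \(= 100\,(\mathrm{TP}-\mathrm{FP}-\mathrm{IDS})/\mathrm{GT}\), MOTSP
\(= 100\,\sum_{\mathrm{TP}}\mathrm{IoU}/\mathrm{TP}\), and the soft variant
sMOTSA is reported as an extra field. Note that a *dense* swarm corrupted
with localization noise generally violates the disjointness precondition
(bodies legitimately overlap up to the visibility allowance), so MOTS is the
right tool for separated scenes and CLEAR MOT the right tool for dense ones.

Whether the box or the mask drives matching in the MOT layer is a genuine
open choice; box IoU for CLEAR MOT and mask IoU for MOTS is adopted,
consistent with the respective toolkits. Both walks agree exactly on all
counts when every mask equals its bounding box (tested).

## The synthetic scene generator

`simulate_scene()` emulates the statistical structure of the recorded
footage the tracker targets: 1920×1080 frames, ≈370 bee-sized elliptical
agents, 10-second sequences at 5/10/15 fps. Each agent is an oriented
ellipse (half-axes 31×11 px by default — with a 40 cm field of view imaged
over 1920 px, ≈4.8 px/mm, a 13 mm bee body is ≈62 px long) that advances
along its heading with bounded-uniform heading noise and reflects off the
frame boundary. A configurable fraction of agents (default 0.4) is
*inactive*: they jitter by well under a pixel per frame, do not turn, and
stand in for resting bees. Agents are painted per frame in id order (higher
id occludes lower); an agent whose visible — in-frame and un-occluded —
pixel fraction falls below `visibility_min` (default 0.8) is omitted from
the ground truth for that frame, mirroring the annotation practice of only
labeling bodies that are more than 80% visible. A direct consequence, which
the tests assert on every generated frame, is that two retained masks can
never overlap by more than the visibility allowance of the smaller body.
Boxes are the tight bounds of the rasterized mask.

Two motion-model choices are deliberate and worth knowing about:

* **Bounded tails.** Heading steps are uniform on
  \(\pm\sqrt3\,\sigma_\theta\) (same standard deviation as the Gaussian they
  replace) and base speeds are truncated at mean ± 2 sd. Real body turn
  rates and walking speeds are bounded, and bounded tails are what make
  guarantees possible: with Gaussian turns, the frame-to-frame bounding box
  of an elongated body occasionally changes shape so fast that *no* tracker
  gated at 50% overlap can follow it, regardless of seed.
* **Defaults follow the target regime.** At 10 fps the defaults (speed
  4 ± 1.5 px/frame ≈ 8 mm/s, heading noise 0.1 rad/frame ≈ 1 rad/s) keep the
  consecutive-frame box IoU of an unoccluded agent above ≈0.57, the regime
  in which a 50%-gated tracker is designed to operate. These are
  order-of-magnitude choices: no quantitative motion statistics exist for
  dense hive scenes, and the numbers are stated here precisely so they can
  be criticized.

`well_separated_scene()` encodes the benign regime used by the identity
tests: each agent is confined to a private grid cell with reflecting cell
walls (so the scene is occlusion-free for any duration) and moves gently
(speed 1.5 ± 0.5 px/frame truncated, heading noise 0.08 rad/frame). Under
these bounds the worst case for association is a wall bounce coinciding with
a maximal turn: the constant-velocity prediction overshoots by twice the
speed (≤ 5 px) while the box rotates by ≤ 0.14 rad, and the resulting
inter-frame box IoU still exceeds ≈0.59 — comfortably above the 0.5 gate.
That margin, not luck, is why a tracker fed uncorrupted detections of such a
scene preserves every identity (MOTA = MOTSA = 100%, zero switches) at any
seed.

`corrupt_detections()` is the detector error model: each object is
independently dropped with probability `miss_rate`; survivors get Gaussian
center jitter and a radial mask grow/shrink (boxes recomputed from the
perturbed mask); `Poisson(fp_rate)` spurious ellipses are added per frame;
scores are Normal, clipped to [0, 1]; ids are stripped. One uniform draw per
object decides the miss *before* any other randomness, so runs with the same
seed and increasing miss rate drop nested detection sets — degradation
curves are monotone by coupling, not merely on average. All randomness flows
from the two explicit config seeds (scene, corruption); the global RNG state
is never touched.

What the generator does *not* emulate, and hence what passing tests cannot
show: appearance (there is no pixel intensity at all, so detector errors are
independent rather than correlated with visual ambiguity), body articulation
(real masks flex; ellipses are rigid), comb structure and entrance/exit
traffic (agents persist by default; `boundary = "exit"` exercises
creation/deletion but without real hive-entrance geometry), and any
correlation between occlusion and detector failure — in real footage a
detector misses *because* of the occlusion that also hides the bee from the
annotator. Scores on synthetic scenes are therefore expected to exceed
scores on real footage of the same density.

## Trajectories

`extract_trajectories()` reduces a tracking result to one record per
identity: box-center points per frame (mask centroids optional), path length
summed over consecutive observed frames only — occlusion gaps are left as
gaps, never interpolated, so a miss cannot inflate a path — duration as the
spanned frame count over fps, and mean speed as path length over duration.
`classify_activity()` labels a track inactive iff its mean speed falls below
a threshold, default 5 px/s: the synthetic inactive regime measures ≈2 px/s
(sub-pixel jitter plus box quantization) and the slowest active agents
≈15 px/s, so the default sits in a wide empty band. No field-validated
criterion exists; the threshold is exposed and the label is a convenience,
not a validated behavioral classification.

## Numerical and degenerate-input choices

* Rasterization resolves all boundary pixels by the pixel-center even-odd
  rule; no epsilon tuning anywhere in the geometry.
* Empty union in mask IoU is defined as 0; AP with no ground truth and no
  detections is 1 with a flag; an empty detection sequence tracks to an
  empty result rather than an error.
* The assignment solver requires finite costs and resolves ties
  deterministically; `associate()` gates *after* solving, and the MOT walks
  zero out ineligible pairs *before* solving so eligibility can never be
  outbid.
* Division guards: MOTP/MOTSP are `NA` when there are no matches; areas and
  aspect ratios are floored at tiny positive values when converting states
  to boxes.
* Problem sizes in the shipped tests and acceptance script: the full
  370-agent, 1920×1080, 100-frame stress pipeline (simulate → corrupt →
  track → CLEAR MOT + AP) completes in well under two minutes on one CPU;
  the identity and degradation studies use 10–60 agents at 5–10 fps, sizes
  at which every scenario remains exhaustively checkable.

## Known limitations

* No re-identification: any target lost for more than `t_lost` frames
  returns as a new identity, and dense occlusion therefore costs identity
  switches by design.
* The aspect ratio is modeled as constant per target; strongly articulated
  postures (grooming, waggle) violate this faster than the covariance can
  absorb at low frame rates.
* MOTS evaluation refuses overlapping result masks rather than resolving
  them; dense scenes should be scored with CLEAR MOT and AP.
* The generator's motion statistics are stated guesses; conclusions about
  absolute tracking accuracy on real hives require real footage.
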