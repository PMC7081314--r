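---
title: "Test-time augmentation for microscopy segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Test-time augmentation for microscopy segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttaseg)
```

## The method

Test-time augmentation (TTA) predicts on several geometrically transformed
copies of a test image and combines the reverted predictions into one
output. For nuclei segmentation the useful transforms are the ones already
used to augment training data — horizontal and vertical flips and the three
axis-aligned rotations — because a network trained under them is
approximately equivariant to them, and because they are exactly invertible
on the pixel grid. The pipeline has four steps:

1. **Augmentation.** Each transform `t` of the augmentation set is applied
   to the test image (`apply_transform`). The set always starts with the
   identity, which supplies the "original" no-TTA baseline.
2. **Prediction.** A pluggable predictor is invoked once per view. The
   engine never inspects pixels itself; any function obeying the contract
   (probability map or instance set, in the frame of its input) can be
   plugged in, including an external command via `subprocess_predictor`.
3. **Dis-augmentation.** Each prediction is reverted with the stored
   inverse of its transform (`disaugment`), so all views share the original
   frame. Because only flips and right-angle rotations are allowed, round
   trips are bit-exact — there is no interpolation anywhere.
4. **Merging.** Semantic predictions are averaged pixel-wise and
   thresholded once at 0.5. Instance predictions go through the
   object-matching and majority-voting algorithm below.

TTA helps exactly when per-view errors are independent deviations around an
equivariant core: averaging then cancels boundary noise, and voting
restores objects missed in some views while suppressing spurious
detections present in few. When the predictor is *perfectly* equivariant,
every dis-augmented view is identical and merging provably changes nothing
— the package ships that case as a negative control
(`make_equivariant_predictor(..., equivariant = TRUE)`).

## The instance merge

Given `N` dis-augmented instance sets (identity view first) and a matching
threshold of 0.5 IoU:

* **Round 0.** Every object of the identity view seeds a match group. The
  seed greedily takes its best-IoU unconsumed candidate from each other
  view, accepting only IoU ≥ 0.5; each object is consumed by at most one
  group.
* **Rounds 1 … ⌊N/2⌋.** Objects of the first, second, … augmented view
  that are still unconsumed seed further groups against the remaining
  unconsumed objects of all other views. This recovers objects undetected
  in the original image. Rounds stop once a strict majority is no longer
  theoretically reachable.
* **Majority rule.** A group is kept iff its support (number of
  contributing views, counting the seed) exceeds `N/2` — for the default
  six views, at least four.
* **Pixel vote.** Each kept group emits one mask: a pixel is foreground iff
  it is set in at least half of the group's paired masks, ties resolved to
  foreground. The electorate is the group's paired objects, not all `N`
  views.

### Decisions the description leaves open

These points are underdetermined by the verbal description of the
algorithm; the package fixes them as follows and tests them explicitly.

* **Strict vs weak majority.** "Present in the majority" is read strictly:
  support must exceed `N/2`, so 3-of-6 objects are dropped. This reading
  makes the seed-round cutoff (⌊N/2⌋) exactly the last round from which a
  keepable group can still arise, which is why the two rules are presented
  together.
* **Tie pixels.** A pixel present in exactly half the paired masks is
  foreground, mirroring the inclusive `>= 0.5` semantic threshold.
* **Matching order.** Seeds are processed in stored object order; IoU ties
  break toward the lowest candidate index. Matching is greedy per object,
  not a global optimal assignment — the description iterates per object,
  and a deterministic tie rule is required for reproducibility.
* **Consumption of discarded groups.** A seed and its accepted matches are
  consumed even when the group is later discarded for lacking support. In
  the unambiguous regime the tests operate in (true correspondences well
  above, non-correspondences well below the threshold) this cannot change
  the output: a discarded group's members could never reach majority under
  any other assignment.
* **Overlap of merged outputs.** Voted masks of different groups can
  overlap; labeled-mask output must not. A contested pixel goes to the
  group with the greater vote fraction at that pixel, then to the larger
  object, then to the earlier output index; objects emptied by the
  resolution are dropped. Any deterministic rule would do; this one prefers
  the more confident claim.
* **Soft per-object masks** are binarized at 0.5 before matching, keeping
  IoU set-based. Detector confidence scores are ignored (score filtering,
  if desired, belongs in the predictor adapter).

## Evaluation metrics

* **Instance (DSB-style mAP).** For IoU thresholds 0.50–0.95 in steps of
  0.05, predictions and ground truth are matched one-to-one; a matched
  pair is a true positive at threshold `t` iff its IoU is *strictly*
  greater than `t` (the strict inequality is honored literally, so IoU
  exactly 0.6 passes only the 0.50 and 0.55 thresholds). The per-threshold
  score is `TP / (TP + FP + FN)`; the per-image score is the mean over the
  ten thresholds; the dataset score the mean over images. Matching is
  computed once from the full IoU table, greedily in descending IoU — for
  disjoint ground truth and predictions this is provably optimal at every
  threshold above 0.5, and the suite checks agreement with an exhaustive
  matcher on 200 random scenes.
* **Semantic (pixel IoU).** Sum the two binary masks, count pixels greater
  than one, divide by the count of pixels greater than zero.
* **Edge conventions.** Reference evaluation never meets empty images, but
  the simulator can produce them, so a convention is required: two empty
  masks/sets score 1.0 (a correct empty prediction is perfect), empty
  versus non-empty scores 0.0.
* **Paired comparison.** `compare_scores` reports per-image
  `delta = merged − original`, mean and median delta, and a two-sided
  paired Wilcoxon signed-rank p-value. With fewer than two pairs or
  all-zero deltas the test is refused and reported as degenerate rather
  than fabricating a p-value.

## The synthetic world

The simulator makes the pipeline testable without trained networks. Its
defaults are the stated conditions of the reference setting and of the
acceptance properties; they were chosen once and are not tuned.

* **Scenes.** `n_objects` (default 25) disjoint, slightly irregular filled
  ellipses with semi-axes 8–20 px on a 512 × 512 canvas (the standard crop
  size), ≥ 4 px clearance, each ≥ 20 px area, fully inside the canvas.
  Irregularity is a low-order sinusoidal modulation of the boundary radius
  (relative amplitude 0.15) — enough to avoid the unrealistic perfection of
  exact ellipses while keeping rasterization integer-exact and seeded.
* **Per-view corruption.** Each ground-truth object is dropped with
  probability `p_missed` (default 0.15); survivors are dilated or eroded by
  a uniform radius up to `jitter_radius` (default 2 px), emulating
  uncertain borders; `Poisson(spurious_rate)` (default 0.5) false objects
  are added at least `spurious_gap` (8 px) away from every true object, so
  a spurious detection can never IoU-match a true group — which keeps the
  oracle tests unambiguous. Corruption is applied in the *transformed*
  frame with a per-view seed, so errors are independent after
  dis-augmentation: the regime in which TTA helps.
* **Semantic output.** The corrupted foreground is softened with a
  Gaussian (`prob_blur_sigma`, default 2 px), per-pixel Gaussian noise
  (`prob_noise_sd`, default 0.1) is added, and values are clipped to
  `[0, 1]`.
* **What it does not emulate.** No intensity/texture rendering, no
  tissue-vs-fluorescent appearance, no touching or overlapping nuclei, no
  correlated (systematic) network errors. A green improvement property
  therefore establishes that the merge algorithms behave as designed under
  independent noise — not that any particular trained network gains a
  particular score on real data.

## Numerical choices

* All geometry is pixel-permutation only; determinism is exact across
  platforms for instance mode (integer grids throughout).
* Seeded generators save and restore the caller's RNG state; per-view
  seeds are derived by integer mixing kept below 2^31.
* Thresholds: semantic binarization `>= 0.5`; instance matching
  `IoU >= 0.5`; metric true positives `IoU > t` (strict). These three
  boundary conventions are deliberate and tested.
* Degenerate inputs: empty view lists, empty probability-map lists, and
  empty score vectors are invalid-argument errors; empty instance sets are
  legal values and flow through merge and metrics under the conventions
  above.

## Known limitations

* Only interpolation-free dihedral transforms are supported, by design;
  elastic or affine TTA would break bit-exact dis-augmentation.
* The greedy per-object matching is not a global optimal assignment; in
  heavily overlapping detector output (IoU between distinct true objects
  approaching the matching threshold) it can group differently than an
  exhaustive matcher. The guarantees are stated, and tested, for the
  separated regime typical of nuclei.
* Mask I/O uses ASCII PGM and plain-text probability maps rather than
  PNG/TIFF, keeping the package dependency-free; converting real imagery
  to PGM is a one-liner in any image tool.

## A complete run

```{r example, eval = FALSE}
gt <- generate_scene(scene_spec(canvas = c(256, 256), n_objects = 12,
                                seed = 42))
predictor <- make_equivariant_predictor(gt, noise_spec(seed = 7),
                                        mode = "instance")
res <- tta_predict(instance_labels(gt), predictor,
                   run_config(mode = "instance"))
dsb_map(res$merged, gt) - dsb_map(res$original, gt) # the per-image delta
```
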