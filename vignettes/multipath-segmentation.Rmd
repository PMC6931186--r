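---
title: "Multi-path 2.5D segmentation of stroke lesions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-path 2.5D segmentation of stroke lesions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lesionfuse)
```

## The problem and the model

Hand-segmenting stroke lesions from structural MRI is slow and only
moderately reproducible between expert raters, which bottlenecks
lesion-deficit research. `lesionfuse` implements a fully automatic
segmenter for skull-stripped, atlas-aligned T1-weighted volumes
(optionally paired with FLAIR) built from three ideas:

1. **Nine 2D views.** A 3D volume is sliced along each of the axial,
   coronal and sagittal planes, and each slice stack is intensity-normalized
   three ways: z-scored within each slice (`in_plane`), z-scored per pixel
   position along the slicing axis (`across_third`), or the first followed
   by the second (`both`). The 3 x 3 grid of (plane, scheme) combinations
   gives nine complementary views of the same anatomy: a lesion that is
   inconspicuous in one plane or under one normalization is often salient
   in another.
2. **A dual-encoder U-network per view.** Each view is segmented by a 2D
   encoder-decoder network with two encoders -- one for the primary
   modality and one for an auxiliary modality, which is either a
   co-registered FLAIR or, in the single-modality case, the left-right
   *flipped* T1 (an "augmented synthetic modality" that lets the network
   compare each location against its contralateral counterpart; stroke
   lesions here are unilateral). Encoder features from the two modalities
   are merged at every scale by a 2x1x1 convolution -- one learned weight
   pair per channel -- and the decoder adds (rather than multiplies) the
   fused skip features to the upsampled ones before a ReLU, avoiding the
   vanishing gradients that elementwise products of small activations
   produce. Each path ends in a 1x1 projection to two channels with a
   per-pixel softmax: channel 1 predicts lesion, channel 2 its complement.
3. **A learned 3D fusion post-processor.** The nine per-path soft volumes
   are binarized at 0.5, each stacked with the original input volume
   (channels `2 x 9 = 18`), and merged by a chain of 3x3x3 convolutions
   with channel plan `18 -> 36 -> 9 -> 9 -> 2`, ReLU between layers, and a
   per-voxel softmax. The hard mask takes channel 1 >= 0.5. Voxelwise
   union and majority-vote (>= 5 of 9) fusion are provided as reference
   strategies; the learned fuser can suppress single-path false positives
   that the union necessarily keeps, which is why its Dice is expected at
   or above the union's.

All networks -- paths and fuser alike -- are trained on the two-channel
soft-Dice loss

$$\mathcal{L} = 2 - D(p;\, r) - D(q;\, 1-r), \qquad
  D(p; r) = \frac{2\sum_i p_i r_i}{\sum_i p_i^2 + \sum_i r_i^2 + \varepsilon},$$

where $r$ is the binary target. The loss lies in $[0, 2]$, vanishes only
at a perfect prediction, and stays informative on slices with empty masks
through the complement channel. $\varepsilon = 10^{-7}$ guards the
denominator for empty targets.

## Architectural conventions the figures leave open

Several wiring details are under-determined by the published block
diagrams; the package fixes them as follows.

* **Five encoder blocks, four pooling steps.** Four 2x2 stride-2 average
  poolings (after blocks 1-4) exactly match the four stride-2
  deconvolutions of the decoder, and the working grids (224/192 and the
  desk-scale 64/48) are divisible by 16 but not 32. Block 5 is the
  bottleneck at 1/16 scale. A fifth pooling would be impossible to undo
  with four doublings.
* **Constant channel width.** Every encoder level carries `filters`
  channels (default 32), matching the stated `32 x x x y` fusion shape; no
  doubling pyramid, and no batch/instance normalization anywhere.
* **Per-path output head.** Each path gets the same two-channel softmax
  head and soft-Dice loss as the post-processor, so paths can be trained
  independently (and in parallel) before the fuser is trained on their
  frozen outputs. Joint fine-tuning is not implemented.
* **Fuser output wiring.** The channel plan is read as four convolutions
  `18 -> 36 -> 9 -> 9 -> 2`, with the last 3x3x3 layer projecting to the
  two softmax channels. All 3D convolutions use padding 1 so dimensions
  are preserved.
* **Binarization ties.** 0.5 maps to lesion everywhere a threshold
  appears (mask loading, path binarization, final mask).
* **Normalization operator.** "Normalize" is implemented as z-scoring
  over *non-background* voxels only (background = exact zeros, which is
  what skull-stripping produces); background stays exactly zero, and
  slices or profiles with fewer than two foreground voxels or standard
  deviation below 1e-8 map to zero rather than dividing by noise.
  "Across the third plane" is the per-pixel profile along the slicing
  axis -- the only axis left once in-plane statistics are excluded.
* **Fuser warm start.** The post-processor is initialized *at the
  majority-vote operating point*: one filter per layer carries the vote
  count of the nine prediction channels through centre-tap identities and
  the output layer maps it to logits $\pm(\text{votes} - 4.5)$, with all
  other weights small random. From a cold random start, whole-volume
  soft-Dice training is seed-fragile -- it can fall into the all-background
  attractor and stay there -- whereas from the vote baseline gradient
  descent only has to refine an already-good segmenter. Majority vote is
  exactly recoverable at initialization, so the trained fuser has no
  excuse to do worse.
* **Weight initialization** elsewhere is uniform fan-in scaling,
  $U(-1/\sqrt{\text{fan}_{in}}, 1/\sqrt{\text{fan}_{in}})$, with a
  recorded seed; gradients use the `relu'(0) = 0` subgradient convention.

## Geometry

Arrays are held in a fixed canonical order: axis 1 inferior-superior,
axis 2 posterior-anterior, axis 3 left-right. NIfTI inputs are reoriented
on load when the header permits; registration to a common atlas space,
resampling and skull stripping are upstream responsibilities. Volumes are
conformed to a fixed grid (default 192 x 224 x 192, every dimension
divisible by 16) by centre cropping and symmetric zero padding; how
off-grid volumes should be handled is not prescribed anywhere, so
centre crop/pad is this package's convention.

## Training

Optimization is plain stochastic gradient descent with Nesterov momentum
0.9 and weight decay 1e-4. The full-scale defaults are batch size 32,
initial learning rate 0.01 decayed geometrically by 3% after each epoch
(`lr(e) = 0.01 * 0.97^e`), for 50 epochs. The "3% per-epoch decay" is
applied to the learning rate, not as a second weight-decay mechanism --
the weight decay of 1e-4 is already specified separately. Batches sample
2D slices uniformly across cases within a path's plane; slices with empty
masks are retained. The fuser is trained afterwards on the frozen paths'
stacked outputs, one volume per update.

## The phantom generator

Real multi-site stroke MRI cannot ship with a package, so the test bed is
a synthetic phantom that reproduces exactly the structure the pipeline
relies on:

* an ellipsoidal brain support with *exact-zero* background (what the
  foreground-aware normalizations key on);
* a smooth low-frequency tissue field (a baseline plus a few random
  Gaussian bumps) so that in-plane and across-third normalizations
  produce genuinely different inputs;
* one connected ellipsoidal lesion per volume, centre constrained to the
  left hemisphere (the training distribution is unilateral), hypointense
  in modality A (T1-like, offset about -0.35 to -0.6) and hyperintense in
  modality B (FLAIR-like, +0.5 to +0.8), matching the clinical contrast
  relationship;
* additive Gaussian noise (sd 0.08 against a tissue baseline of 1).

Lesion sizes are drawn so that a requested fraction of cases falls
strictly under the 20 x 20 x 25 mm small-lesion bounding-box rule
(boundary equality counts as large). Phantoms do **not** emulate MRI
physics, bias fields, partial voluming, multi-focal lesions, or
inter-site scanner differences -- so passing phantom benchmarks
demonstrates that the machinery trains and generalizes on clean
single-lesion data, not that real-data accuracy would match.

## The desk-scale profile

The end-to-end benchmark (`phantom_benchmark()`) runs the entire system --
nine paths plus fuser -- on one CPU in minutes. Its profile:

| setting | full scale | desk profile | why |
|---|---|---|---|
| grid | 192 x 224 x 192 | 48 x 64 x 48 | smallest 16-divisible grid that leaves room for a brain with small and large lesions |
| filters | 32 | 16 | quarter of the arithmetic at equal depth |
| batch | 32 slices | 8 slices | ~100-slice epochs |
| path training | 50 epochs | 5 epochs x 20 batches | a few hundred updates suffice on high-contrast phantoms |
| learning rate | 0.01 | 0.2 | with only ~100 updates the full-scale rate never escapes the all-background solution; soft-Dice gradients are O(1/volume) |
| fuser | 50 epochs, lr 0.01 | 3 epochs over 30 volumes, lr 0.01 | warm-started at majority vote, it only needs gentle fine-tuning; larger rates destabilize whole-volume soft-Dice updates |

The learning-rate choice deserves emphasis: soft-Dice training on heavily
imbalanced slices first collapses to the all-background prediction and
then needs enough effective steps to lift the lesion channel; at the
desk-scale update count that requires the larger rate. The full-scale
defaults remain the package defaults.

## Evaluation machinery

`dice_coefficient()` counts TP/FP/FN and applies
`2TP / (2TP + FP + FN)`; two empty masks score 1 by convention (perfect
agreement on absence). `classify_lesion_size()` uses whole-foreground
bounding-box extents in mm. `wilcoxon_rank_sum()` is two-sided, exact by
enumeration when the combined sample is at most 12 and tie-free,
otherwise normally approximated with tie and continuity corrections.
`kfold_split()` produces balanced, seed-deterministic folds, and
`cross_study_eval()` hard-fails on any case identifier appearing in both
the training and the test role, so no leakage can pass silently.

## Known limitations

* Single-lesion, left-hemisphere training distribution (by construction
  in the phantom; by selection in the intended real data).
* The learned fuser is only as good as its training volumes; with very
  few volumes it can sit marginally above union rather than clearly above
  majority vote.
* No connected-component cleanup or CRF post-processing; the 3D fuser is
  the only false-positive filter.
* CPU-only: full-scale training of nine paths on hundreds of volumes is
  out of reach here; the desk profile demonstrates system behaviour, not
  clinical accuracy.
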