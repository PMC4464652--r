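---
title: "A recurrent connectionist account of verbal overshadowing in face recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A recurrent connectionist account of verbal overshadowing in face recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Verbal overshadowing is the finding that describing a face in words during the
retention interval can impair later recognition of that face. Under the
*recoding interference* account, verbalization does not switch the observer
into a "verbal mode" of processing; it changes the non-verbal representation
itself, and that recoded representation then drives the recognition decision.
`vosim` implements a fully interactive recurrent network in which this account
is not an assumption but an emergent consequence of attractor dynamics, and
provides the experiment harness that reproduces the classic behavioural
pattern: overshadowing with similar distractors, no overshadowing with
dissimilar ones, overshadowing after describing an irrelevant face, and a
non-monotonic relation between description accuracy and the size of the
deficit.

## The model

Three peripheral layers — a retinotopic input layer (4200 units, one per
pixel), a visual image layer (4200 units, the clean item-specific face code)
and a verbal layer (6 units, one per feature label) — are bidirectionally
connected to a single hidden layer of 20 units. A peripheral unit is connected
only if its input/target value varies across the 64 faces (sparse
connectivity); constant units carry no item information and are omitted from
the simulated state.

Each trial runs in cycles. Per cycle every unit's net input is time-averaged,

$$s_{i,t} = s_{i,t-1} + 0.1\,\big(\textstyle\sum_j w_{ji}\,a_{j,t-1} + b_i - s_{i,t-1}\big),
\qquad a_{i,t} = \frac{1}{1+e^{-s_{i,t}}},$$

with all layers updated synchronously from the previous cycle's activations.
A retinotopic stimulus is hard-clamped: the layer's activations are set to the
external input from the start of its presentation window. External verbal
input is soft-clamped with gain 0.5,

$$a' = a + 0.5\,( \text{external} - a),$$

a convex blend of the internally computed output and the external input, so
internal dynamics and external evidence both matter. Net inputs persist
across phase boundaries: what verbalization has done to the network state is
still there when the face appears. This carry-over is the entire mechanism of
the overshadowing simulations.

## Stimuli

The 64 faces cross 4 eye x 4 nose x 4 lip subordinate types on a 70 x 60
binary canvas; each feature pair of subordinate types shares a verbal label
(*drooping*/*slanted* eyes, *long*/*button* nose, *thick*/*downturned* lips),
so every verbal label triple is shared by exactly 8 faces and the verbal code
cannot identify an individual face. Glyphs live in disjoint row bands; the
two subordinate variants under one label share a pixel core but each also has
pixels of its own (long-thin versus short-thick strokes, shifted or re-shaped
rather than nested), because a variant that is a strict subset of its sibling
cannot be discriminated by reconstruction. Retinotopic inputs are the images
smoothed by a normalized separable Gaussian kernel (SD 0.2 px, reflect-padded,
clipped to [0, 1]); the width is a parameter because the montage images the
structure emulates are not reproducible pixel-for-pixel. A seeded random half
of the faces (32) is trained ("old"); the rest are "new".

## Tasks and training

Visual recognition maps the retinotopic input to the clean face; verbalization
maps it to the three label units; mental imagery soft-clamps the item's three
label units (external input 1.0, partners float) and asks for the face. Since
8 faces share each label triple, imagery is one-to-many and can never reach
100% — the model, like a human listener, cannot know *which* long-nosed,
drooping-eyed, thick-lipped face was meant.

Training is cross-entropy by backpropagation through time (learning rate 0.05,
weight decay 1e-8, momentum 0, batch size 1), with Gaussian noise (SD 0.2)
added to the hidden layer's summed input to push hidden units toward polarized
outputs. A unit whose output is within 0.1 of its target back-propagates no
error (zero-error radius). The curriculum is visual-recognition pre-training
until nearest-neighbour accuracy exceeds 50%, then a single shuffled deck in
which every trained item appears equally often in all three tasks
(`training_config("full")`: 3000 repetitions per item per task;
`"reduced"`: 2000, the desk-scale operating point used by the packaged
experiment suite and its tests — chosen because the result pattern is stable
from several hundred repetitions on while a full run costs roughly an order
of magnitude more compute).

Four numerical choices deserve explanation, because the network's published
description leaves them open and they decide whether this architecture trains
at all:

* **Error timing.** Targets are compared to outputs from the first cycle, but
  under synchronous updates the target layer's cycle-1 output is causally
  independent of the stimulus (input reaches hidden at cycle 1 and the
  opposite peripheral layer at cycle 2). Injecting error on cycle 1 therefore
  trains a stimulus-independent response; empirically it drives the hidden
  layer into a single collapsed attractor from which item discrimination
  never emerges. Error is injected from `error_start_cycle = 2`, the first
  stimulus-dependent output cycle, through the end of the trial.
* **Error aggregation.** The per-trial objective is the *mean* per-cycle
  cross-entropy rather than the sum (`error_aggregation = "mean"`). With the
  sum, the gradient magnitude scales with trial length and, at the stated
  learning rate and batch size of 1, training oscillates without converging;
  the mean keeps the step size independent of the number of error cycles.
* **Early stopping.** The classic procedure ends a training trial once every
  target unit is within 0.5 of its target. Because familiarity is read out at
  the 10th cycle, training only the early cycles leaves the late cycles
  unconstrained, and the settled state drifts away from the item attractor
  (nearest-neighbour accuracy measured per cycle fell from 100% at cycle 3 to
  about 60% at cycle 10). Trials therefore run all 10 cycles by default
  (`early_stop_threshold = 0`); the loose 0.5 criterion remains available.
* **Initialization.** Weights are uniform, symmetric, and scaled by the
  inverse square root of each projection's fan-in. With a flat range the
  4200-unit layers inject an item-independent net-input component an order of
  magnitude larger than the item signal, and roughly half of random seeds
  collapse. A minority of seeds still collapse during pre-training; these are
  detected by an epoch cap and restarted from a deterministically derived
  seed, so a model instance remains a pure function of its seed.

## Familiarity, the old/new decision, and the simulations

After training, a face's familiarity is measured as *polarity*: one minus the
binary entropy of a unit's activation,
$a\log_2 a + (1-a)\log_2(1-a) + 1$, averaged over the connected visual-image
units at the 10th cycle after retinotopic onset, with noise disabled. Trained
faces settle into deep attractors with extreme activations (polarity near 1);
untrained faces produce more ambiguous states. The old/new criterion is
placed, per model instance, just below that instance's minimum old-item
polarity — hits are 100% by construction and the correct-rejection rate is
emergent — and is then frozen for all verbalization conditions. Accuracy is
the unweighted mean of hit and correct-rejection rates.

Verbalization is simulated as a two-phase trial: selected verbal units are
soft-clamped to 1.0 for 10 cycles (the network settles toward the label
attractor), then the retinotopic input is presented for 10 more cycles with
the verbal input maintained or removed. Conditions differ only in which units
are selected (consistent with the probe face; the within-pair opposite; or
exactly *k* of 3 correct with the rest flipped, feature identities drawn per
item from a logged seed) and in whether the clamp is maintained. Cross-model
statistics are paired t-tests over the per-instance accuracies (df = number
of instances - 1), and the single-trial lineup draws one old and N new items
from the polarity samples, scoring a success when the old item's polarity is
strictly maximal.

## What the synthetic stimuli do and do not show

The generator reproduces the *structure* that the simulations depend on —
factorial features, two subordinate types per label, faces sharing labels
sharing pixels — not any particular published bitmap. Quantities that depend
only on that structure (perfect trained recognition, above-chance
generalization, the direction of every verbalization effect) are expected to
reproduce; point values inherit a glyph-bank dependence and are meaningful at
the level of a few percentage points only. Real faces differ in ways the
generator deliberately omits: no hair or contour features, no within-type
variability, no correlated features, and a retinotopic degradation far milder
than real viewing noise.

## Reproducing the experiment suite

```{r}
library(vosim)
suite <- run_experiment_suite(stim_seed = 1, verbose = TRUE)
print(suite)
```

`run_experiment_suite()` builds the stimulus set, trains 5 instances
(different seeds), fits the control criterion and runs all conditions; it is
exactly what `scripts/acceptance.R` drives. With the reduced profile it takes
roughly a quarter of an hour on one CPU; `training_config("full")` reproduces
the 3000-repetition curriculum in a few hours.

## Known limitations

* The decision criterion is the minimum old-item polarity, a fragile order
  statistic; correct-rejection rates therefore vary noticeably across
  instances and seeds, which is also why the per-instance lineup simulation
  is noisy (individual differences are part of the account).
* Single-trial dynamics are deterministic at evaluation; noise-at-test is a
  configuration switch, not the default.
* Verbal facilitation and global/local (Navon-type) manipulations are outside
  the implemented scope.
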