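---
title: "Consensus-driven particle pruning: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-driven particle pruning: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(picksieve)
```

## The method

Automatic cryo-EM particle pickers are imperfect in *different* ways:
template matchers, Gaussian-blob detectors and learned pickers make
largely independent mistakes. `picksieve` turns that independence into
training labels. If two pickers with false-positive rates $q_1$ and $q_2$
err independently, a coordinate reported by *both* is false with
probability on the order of $q_1 q_2$ — much smaller than either alone.
The intersection of picker outputs (the AND set) is therefore a
high-precision positive training set, even though it has poor recall.
The union (the OR set) has the opposite character: it contains nearly all
true particles plus everything any picker got wrong, and it is exactly
the set worth pruning. Random coordinates far from all picks (the NEG
set) complete a binary training problem, and a convolutional network
trained on AND vs NEG generalizes to score every OR candidate.

The three set constructions are distance rules relative to the box size
$b$ (the square crop side in pixels):

* **AND**: two coordinates on the same micrograph match when their
  Euclidean distance is *strictly* smaller than $0.1\,b$; the matched
  pair contributes its mean. With more than two pickers the rule is
  folded left: (((1 ∩ 2) ∩ 3) ∩ …), the running averages being matched
  against the next set. Matching is greedy nearest-pair-first and
  one-to-one; ties in distance break deterministically by input order.
* **OR**: all coordinates pooled; coordinates on the same micrograph
  closer than $0.1\,b$ are single-linkage clustered and replaced by the
  cluster centroid, so one physical particle yields one candidate.
* **NEG**: uniform draws over valid box centers, rejected while
  *strictly* closer than $0.5\,b$ to any OR coordinate. Rejection
  sampling is capped at $50\times$ the requested count; a crowded
  micrograph yields fewer negatives and a warning rather than a hang.

Both inequalities are deliberately strict; the boundary cases (distance
exactly $0.1\,b$ or $0.5\,b$) are pinned by unit tests.

Random negatives over-represent empty background. When the user supplies
no contamination stack, the worst-sorted fraction (default 1%) of the AND
particles is recycled into the NEG set. The sorter is a deliberately
simple three-feature outlier score — the Euclidean norm of the z-scores
of crop mean, crop variance and a center-vs-edge radial contrast — and is
documented as such; it stands in for more elaborate particle-sorting
tools and is not a re-implementation of any of them.

## The classifier

The network is four blocks of (conv + relu, conv + batch-norm + relu,
pool), max pooling for blocks 1–3 and average pooling for block 4,
followed by one 512-unit dense relu layer with dropout $p = 0.5$ and a
2-way softmax. Filter counts are 8/8, 8/16, 32/32, 64/64 with kernel
sizes 15, 7, 3, 3 and pools 7/2, 5/2, 3/2, 4/2 ("same" padding
throughout, so a 128 px input halves to 64, 32, 16, 8). At the defaults
this is 2 193 890 trainable parameters.

Training minimizes the two-class cross entropy with Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$) at an initial
learning rate of $10^{-4}$, with L2 weight penalty $10^{-5}$ on every
kernel. A stratified 10% of the training data is held out; when
validation accuracy has not improved for 300 batches the learning rate is
divided by 10, and after the second decay a further stall of
$3 \times 300$ batches stops training ("convergence" is otherwise
undefined, so this package defines it that way). Each batch is
supplemented 1:1 with augmented copies drawn from the non-identity
dihedral transforms of the square — flips and rotations by multiples of
90°, which permute pixels exactly and therefore preserve each crop's
statistics; arbitrary-angle rotations would interpolate and blur the
noise statistics, so they are not used. Batches default to 32 originals
(the batch size is not prescribed anywhere authoritative; 32 is a common
default and configurable).

Implementation notes, for reproducibility across backends:

* Weights are initialized Glorot-uniform, biases zero, batch-norm scale
  one / shift zero.
* Batch norm uses per-channel batch statistics during training and
  exponentially averaged running statistics (momentum 0.9, our backend's
  default, chosen so that running estimates settle within the short
  CPU-scale trainings this package targets) at inference; inference is
  fully deterministic (dropout off).
* All randomness — initialization, shuffling, augmentation, dropout,
  validation split — flows through one integer seed; two runs with the
  same seed are bit-identical. The backprop implementation is verified
  against finite differences in the test suite.
* `width_scale` multiplies all filter counts and the dense width, and
  `input_side` may be any multiple of 16. These two knobs exist so the
  identical topology trains in minutes on one CPU core; the defaults
  (`width_scale = 1`, `input_side = 128`) are the reference
  architecture.

Scoring assigns each OR candidate the softmax probability of the particle
class. The default decision threshold is 0.5 with the boundary retained
(score ≥ 0.5 ⇒ keep); `score_histogram()` supports choosing a different
threshold by inspection.

## Evaluation battery

`metrics_report()` computes MCC, accuracy, precision and recall at the
MCC-maximizing threshold (exhaustive scan over midpoints of consecutive
unique scores, ties toward the smaller threshold), plus ROC and PR areas
by trapezoidal integration over the unique-score sweep. Two conventions
are worth stating because tools differ: MCC is defined as 0 when any
confusion-matrix marginal vanishes, and the PR area integrates the
monotone-interpolated curve (precision replaced by its running maximum
from the high-recall end). The ROC area equals the pairwise concordance
probability with ties counted ½; the tests verify this identity
exhaustively and cross-check against an independent ROC implementation.

The label-corruption harness measures robustness to the mislabeling that
consensus-derived training sets necessarily contain: a fraction of each
class is *swapped* with the other class (swapping, rather than
relabeling, keeps both class sizes fixed — the experiment's size axis
stays interpretable), a fresh network is trained per cell of the
(corruption level × training size) grid, and the clean held-out test set
is scored. Levels are capped at 0.5, where labels carry no information
and performance must collapse to chance — a useful built-in control.

## The synthetic data generator

`generate_micrograph()` emulates what matters for this pipeline and
nothing more: dark particles with internal structure (a soft-disc
envelope carrying 2–4 Gaussian lobes) planted at least one diameter
apart, one large smooth carbon-like intensity gradient and a few small
very dark ice-like dots per micrograph, and white Gaussian noise scaled
so that SNR = (signal variance over the particle support)/(noise
variance) — SNR conventions vary, so the definition is fixed here.
Simulated pickers retain each true particle with probability `tpr`, add
isotropic Gaussian localization jitter, and place `fp_density × n_true`
false picks uniformly, excluded from a one-diameter zone around true
particles so that ground-truth labels of picks are unambiguous.

Default scene: 1024² px micrographs, 150 particles of 40 px diameter
(≈20% area coverage — dense but comfortably below the random-placement
jamming limit), SNR 0.3 (modern direct-detector data at usual defocus is
lower; 0.3 keeps CPU-scale networks learnable while remaining visibly
noisy), 3 contaminants. The benchmark used in the tests and the
acceptance script runs two pickers at `tpr` 0.9/0.8, `fp_density` 0.3
and 2 px jitter over 14 micrographs (~2100 particles), trains at
`input_side = 64`, `width_scale = 0.25` for one epoch, and evaluates on
two freshly generated held-out micrographs; the corruption experiment
uses 500 particles/class, two replicates and 48 px crops. These sizes
were chosen once as the package's CPU-scale study conditions.

What passing on synthetic data does *not* show: the generator has no CTF,
no structured (pink) noise, no particle orientation/conformation
diversity, and its contaminants are crude. Success here demonstrates that
the consensus labeling, the training loop and the pruning logic are
correct and that the network can exploit real signal at realistic SNR —
not that any particular precision figure transfers to experimental
micrographs.

## Degenerate inputs and numerical choices

* Constant crops standardize to all-zeros rather than dividing by zero;
  normalization is idempotent to float precision.
* Crops are extracted at `b × b` and resampled by exact area averaging
  (fractional pixel coverage handled analytically; a 2:1 ratio reduces
  to the 2×2 block mean), which suppresses noise aliasing that
  interpolating resamplers would introduce. Edge coordinates whose box
  does not fit are dropped and counted, never padded — padding would
  hand the network an artificial border cue.
* BOX-dialect corner coordinates convert to centers as `corner + b/2`
  and back exactly; the minimal STAR dialect preserves unknown tags on
  round-trip.
* The outlier ranking is stable under ties (input order preserved), and
  an all-identical stack scores uniformly zero.
* MCC/precision/recall zero conventions as above; empty inputs raise
  errors rather than returning NaN.

## Known limitations

* The OR-set de-duplication radius equals the AND radius by default;
  whether duplicated candidates should instead be scored independently
  is configurable (`or_merge_fraction`) because published practice is
  not uniform on this point.
* The AND radius is interpreted against the user-supplied box size, not
  a measured particle diameter; if the box is much larger than the
  particle, tighten `and_dist_fraction`.
* Training runs single-threaded on CPU; the reference-width network at
  128 px is trainable but slow, and the package makes no attempt at GPU
  execution.
* The z-score negative augmentation is a simplified stand-in for
  dedicated particle-sorting tools.
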