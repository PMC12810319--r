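---
title: "Scoring and sifting cryo-EM 2D class averages: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and sifting cryo-EM 2D class averages: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-particle cryo-EM pipelines produce stacks of 2D class averages of
very uneven quality: sharp projections with secondary-structure detail sit
next to fuzzy, artifact-ridden or outright junk classes, and the particles
behind the bad classes degrade 3D reconstruction. `cryosift` scores each
class average on a continuous quality scale and uses the scores to drive an
iterative particle-curation policy. It is aimed at people automating 2D
class selection (in place of manual picking in a GUI) and at method
developers who need a fully synthetic, deterministic test bed for such a
policy.

## The quality score and its CNN

Expert graders assess class averages on an A-F rubric, from "best: secondary
structure, very sharp" down to "unusable: nothing resembling a particle".
The rubric maps linearly to numeric anchors: A = 1.0, B = 2.0, C = 3.0,
D = 4.0, F = 5.0 (lower is better). The scorer is a regression, not a
classifier: it is trained with an MSE loss and a single linear output, so
predictions are *unbounded* — a class worse than the worst training class
scores above 5, a class better than the best scores below 1. This
open-endedness is intentional and is asserted in the tests.

The model is a residual CNN with metadata fusion:

* **Input canvas.** Every class average (any square side >= 31 px) is mapped
  to a fixed 210 x 210 canvas. Larger images are *Fourier-cropped*: only the
  central 210 x 210 block of the centered 2D spectrum is kept, which
  down-samples while preserving native low-frequency features exactly. The
  crop primitive preserves the image mean (the DC term is carried over with
  the right normalization); the unpaired Nyquist band of the cropped
  spectrum is Hermitian-symmetrized so the inverse transform is real to
  machine precision. Smaller images are standardized (zero mean, unit SD)
  and placed centered in a zero field — so the padding matches the
  background statistics of a standardized image — with odd remainders
  padding one extra row/column at the bottom/right. Cropped and 210 px
  images are standardized too, so every canvas carries comparable
  statistics. Degenerate constant images standardize to all zeros rather
  than NaN.
* **Trunk.** A small-kernel stem followed by residual stages (two 3 x 3
  convolutions per block, batch normalization after every convolution,
  identity skip). There are *no pooling layers in the trunk*: every
  downsampling step is a pair of consecutive 2 x 2 stride-2 convolutions,
  which acts as a learned weighted pooling. The trunk ends in adaptive
  average pooling to a fixed 6 x 6 spatial map, whatever the trunk depth.
* **Metadata fusion.** Six per-class scalars are concatenated to the
  flattened 6 x 6 map: pixel size (Å/px), FRC resolution estimate (Å),
  relative class distribution (fraction of the particle stack in the
  class), and the three mass-deviation features described below (kDa).
  Features are z-scored with training-split statistics stored inside the
  model. The fusion point — after pooling, before the fully connected
  head — is a design choice; the head is one hidden ReLU layer and a
  linear output.
* **Training.** Adam, learning rate 1e-4, weight decay 1e-4 (L2 added to
  the gradient), batch size 32, a seeded 10% validation split held out
  before training, per-epoch train/validation MSE recorded. The final
  layer starts near zero with its bias at the training-label mean, the
  standard initialization for a regression head; it also makes the
  degenerate all-one-label corpus converge within a few epochs, which the
  tests use as an oracle.

### Configurations

The default configuration uses four residual stages at widths
32/64/128/256 with two blocks per stage and 200 epochs. The package also
ships a *desk-scale* configuration (`deskScorerConfig()`): widths 6/12/24,
one block per stage, a 64-unit head, 30 epochs, and `stemDownsample = TRUE`,
which makes the network's entry point itself a paired 2 x 2 stride-2
downsampling block (the only downsampling device the architecture uses)
followed by the 3 x 3 stem. That ordering means no wide full-resolution
tensor is ever materialized, and a full train-and-validate cycle on a
2000-image synthetic corpus completes in minutes on one CPU core. All
structural properties — residual blocks, batch norm after every
convolution, paired strided downsampling, no pooling in the trunk, the
6 x 6 adaptive pool, unbounded output — are identical across
configurations and are asserted structurally in the tests. Exact
layer-by-layer widths of the reference network are not public; widths here
are configurable by design.

Training n = 2000 for 30 epochs was chosen as the desk-scale study
condition: validation loss plateaus well before 30 epochs on corpora of
this size, and the held-out Spearman rank correlation with the true grade
exceeds 0.9.

## Mass features

Per-class particle masses are estimated from pixel intensities:

1. **Segmentation.** Particle pixels are those more than three standard
   deviations above the image mean, both statistics over the whole image,
   with no morphological clean-up. An empty mask is legal (constant or
   pure-noise images) and yields mass 0.
2. **Mass.** `mass = c * sum over mask of (I - mean(background)) * a^2`,
   with `a` the pixel size in Å/px. The background mean is subtracted
   per-pixel before summation — the reading under which the summation step
   is meaningful — making the estimate exactly invariant to additive
   offsets and quadratic in pixel size.
3. **Calibration.** On standards of known mass, integrated intensity is
   linear in mass; the factor `c` (kDa per intensity·Å²) is the
   least-squares slope through the origin, `sum(I*M)/sum(I^2)`, with the
   residual RMS reported.
4. **Deviation features.** Within a stack, each class's signed deviation
   (kDa, not normalized — scaling is the scorer's job) from the stack's
   mean, median, and histogram-mode mass. The mode of a continuous sample
   needs a binning rule: Freedman–Diaconis width (`2*IQR/n^(1/3)`,
   scale-free), right-open bins from the minimum, mode = centre of the
   most populated bin, ties to the lowest bin, and a single bin (range
   centre) when the IQR is zero.

## The synthetic generator

The generator emulates exactly the properties the scorer and the mass
estimator consume, not cryo-EM image formation. A particle-like shape
(disc, annulus, two-lobe; or nothing for noise-only junk) is rendered and
blurred; the image is normalized so integrated intensity x pixel area
equals a target mass under the unit calibration (Fourier-space Gaussian
blur preserves the sum, so normalization survives it); correlated Gaussian
noise and occasional artifacts (smooth streaks, edge clipping) are added.
Degradation follows the grade g in [1, 5]:

* blur sigma: geometric from 0.2 px (grade 1) to 6 px (grade 5). A
  geometric schedule reflects that resolution degrades multiplicatively;
  it also keeps grade-1/2 particles sharp enough that the 3-sigma
  segmentation recovers their target mass to a few percent, which the
  mass-recovery invariants require.
* noise SD: geometric from 0.02 to 1.0 of the nominal shape amplitude.
* artifact probability: linear from 0 to 0.9.

The additive noise is white noise smoothed with a sigma of 3 px and
rescaled — the residual background of an *average* of aligned images is
spatially correlated, not white — which also keeps the generator's spectral
ordering clean: total power above 0.2 cycles/px decreases along the grade
axis down to a noise floor, a property the tests assert (with a 5%
tolerance at the floor).

Metadata co-varies with grade the way real classification metadata does:
the FRC-proxy resolution is the frequency where the blur transfer function
`exp(-2*pi^2*sigma^2*f^2)` falls to 0.5, capped at Nyquist, mapped to Å
through the pixel size and jittered lognormally (SD 0.05) — a
self-consistent stand-in, not a claim about real Fourier ring correlation.
Class distributions are drawn from gamma weights with shape `6 - grade`
(better classes hold more particles) and normalized within pseudo
classification runs of 8-25 classes, so the per-class fractions live on
the same scale a real run — or the synthetic backend, whose k classes
carry fractions near 1/k — produces; masses scale with the cube of the
particle diameter.

What passing tests on this generator do show: the scorer can recover a
graded degradation signal from image + metadata and generalize across
generator seeds, and the policy routes particles correctly given scores.
What they cannot show: performance on real micrograph-derived class
averages, with CTF effects, heterogeneous backgrounds and expert-label
noise.

## The sift policy

Particles iterate through classify -> score -> route rounds. Each round,
every working particle inherits the score of its 2D class. Routing:

* score >= 4.5: discarded, permanently;
* score <= 2.5: a seeded uniform-random 70% is *banked* (set aside, no
  further iterations), the other 30% keeps iterating;
* between the cutoffs: keep iterating.

The banked split is sampled globally (not per class) with a per-round seed
derived from the policy seed, and the banked count is the rounded fraction,
so 1000 good particles bank exactly 700. The number of rounds follows the
extraction box side as a proxy for particle size: under 200 px -> 5 rounds,
200-300 px (inclusive) -> 3, above 300 px -> 2. After the last round,
banked and surviving working particles are pooled — mid-score survivors
enter unconditionally and are re-filtered by their final-round scores — for
one final classification and scoring, and the pool is split into three
*nested* batches at scores <= 2.5, <= 3.5 and <= 4.5. If the working set
empties early, remaining rounds are skipped and logged. Every run emits a
line-oriented JSON audit log; identical inputs and seed give a
byte-identical log.

Box-size-dependent classification parameters mirror the same tiers: small
boxes use the small-particle settings (3 Å maximum resolution, initial
class uncertainty factor 3, force-max over poses/shifts off, 40 online-EM
iterations, batch 400), mid-size boxes the platform defaults, large boxes
a 100 px Fourier-cropped box.

The classification backend is pluggable. The shipped synthetic backend
groups particles by a noise-perturbed latent grade (emulating that 2D
classification co-locates particles of similar quality) and renders each
class at its members' median grade. A live cryo-EM platform binding is out
of scope.

## Numerical choices and degenerate inputs

* Fourier crop: centered-spectrum convention; DC lands at the canvas
  centre; the asymmetric Nyquist band is symmetrized; the imaginary
  residue of the inverse transform is asserted below 1e-6 relative.
* Batch norm: biased batch variance for normalization, unbiased in the
  running statistics (momentum 0.1); epsilon 1e-5; inference uses running
  statistics so single images can be scored.
* Determinism: one integer seed covers split, initialization, batch order
  (scorer) and routing/backend sampling (policy, derived per-round seeds);
  a seed-scoped RNG wrapper restores the session RNG state afterwards.
* Degenerate inputs: constant images standardize to zeros and segment to
  an empty mask; an empty mask gives mass 0; all-zero calibration
  intensities, empty corpora and unscored working particles are errors.
* MRC I/O: MRC2014, always written as mode 2 (float32) little-endian;
  modes 0/1/2/6 are read and converted to double; pixel size travels in
  the cell dimensions. STAR output uses `_rlnReferenceImage` with 1-based
  `N@file` references (class indices are 0-based everywhere else) and the
  `_cryosiftScore` column.

## Known limitations

* The CNN kernels are CPU-only, double precision, single-threaded; the
  package targets desk-scale corpora, not the tens of thousands of images
  of a production training run.
* The generator's artifacts are stylized; its noise is stationary and
  Gaussian.
* The reference tool's reported validation losses depend on its
  private expert-labeled corpus and are not reproducible here; the
  package's empirical claims are exactly those its tests compute on the
  synthetic generative model.
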