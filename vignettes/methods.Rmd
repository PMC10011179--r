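---
title: "Grading tomato drought stress from hyperspectral leaf images: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading tomato drought stress from hyperspectral leaf images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsidrought)
```

## The problem

Water-deficit stress changes a tomato leaf before the plant wilts: pigment
concentrations drop, cell structure reorganizes, and both leave a signature
in the visible/near-infrared reflectance spectrum. `hsidrought` implements a
complete pipeline that grades plants into three watering classes
(well-watered, reduced-watered, deficient-watered) from hyperspectral leaf
cubes (272 bands, 400–1000 nm in the reference configuration), combining
four ideas:

1. **Effective wavelengths (EWs)** — a genetic algorithm with an SVM
   cross-validation fitness prunes the heavily collinear spectrum down to a
   small informative band subset.
2. **Reflectance image set (RIS)** — among the EW band *images*, ReliefF
   picks a reference image and a Pearson-correlation container collects up
   to four further images that are mutually weakly correlated
   (|r| ≤ 0.3), so the CNN sees complementary, non-redundant channels.
3. **Spectroscopy–image combination** — LeNet-5 features extracted from the
   RIS stack are concatenated with the EW spectra.
4. **Subsample fusion** — the combined vectors of a young leaf and a mature
   leaf from the same plant are concatenated into one sample, exploiting
   the observation that the two leaf stages respond to stress in different
   spectral regions.

Classifiers (SVM, random forest, a 1-D DenseNet) are trained on a 7:3
calibration/prediction split and reported with ACC_C, ACC_P, per-class
precision/recall/F1, confusion matrices and one-vs-rest ROC curves.

## Calibration

Raw counts are converted to reflectance with the standard white/dark
correction `Ic = (Ir − Id)/(Iw − Id)`, elementwise. References follow the
push-broom convention: one value per spatial column and band, averaged over
scan lines and broadcast along the scan axis. Reflectances outside
`[0, 1.2]` (specular glints, noise below dark level) are clipped and
counted in a QC field; a pixel-band with `Iw = Id` aborts with its
coordinate. Reflectance is held as 64-bit in memory and written as 32-bit
float in the ENVI files the package reads and writes (BIL/BIP/BSQ
interleaves, wavelength list in nm).

## The leaf-cube simulator

No public instrument data accompany the method, so the package ships a
simulator that reproduces the spectral phenomenology the pipeline relies
on. The noiseless spectrum is a sum of smooth components:

* a low visible baseline (0.05),
* a Gaussian green peak at 560 nm (width 30 nm) whose amplitude grows with
  stress level — stressed leaves absorb less green light,
* a logistic red edge at 730 nm (scale 12 nm) whose inflection blue-shifts
  8 nm per stress level,
* a NIR plateau at 0.55 reflectance.

Mature leaves get a fixed smooth perturbation (amplitude 0.02) plus
different effect gains than young leaves (by default young leaves respond
more in the green peak, mature leaves more in the red edge), which is what
makes per-stage wavelength selection land in different spectral regions and
gives subsample fusion something to gain.

Within-class biological variability is not documented for the reference
instrument, so the simulator draws per-leaf jitter once per leaf: the
green-amplitude and red-edge-position jitters default to half the
respective per-level effect step (0.015 reflectance, 4 nm), plus a 0.01
baseline shift and 3% multiplicative amplitude jitter. Half-a-step jitter
makes adjacent stress classes genuinely overlap — single-stage accuracy
stays below 100% — without drowning the signal; it was fixed once as the
study condition for all property tests. Pixel noise is i.i.d. Gaussian
(sd 0.01); switching `blue_light = FALSE` adds band-uncorrelated noise
(sd 0.03) below 500 nm, emulating acquisition without supplemental blue
illumination. The noise stream is arranged so the same seed yields
identical common noise with and without blue light, making the comparison
paired.

What the simulator does **not** emulate: leaf 3-D geometry and shading,
specular bidirectional effects, petioles and veins, sensor smile/keystone,
and temporal stress dynamics. Tests passing on simulated cubes therefore
validate the algorithmic chain, not instrument-specific robustness.

## Segmentation and the noise metric

The leaf ROI is thresholded on the band nearest 800 nm (default threshold
0.35 reflectance), where leaf/background contrast is maximal, and the
largest connected component is kept; masks flooding >95% of the frame are
flagged. The acquisition-noise metric subtracts a Savitzky–Golay smoothed
copy (window 11 points, order 2 — both configurable) from the spectrum and
reports the RMS deviation inside 400–700 nm; high RMS in 400–500 nm is the
signature of missing blue illumination. The metric presumes a band spacing
fine relative to the smoothing window (2.2 nm vs an 11-point window on the
reference grid); on very coarse grids the deviation instead measures the
polynomial model bias of the smoother.

## Wavelength selection

The GA uses binary band masks, tournament-of-two selection with single
elitism, uniform crossover applied with probability 0.5, and the published
operating point: population 100, 400 generations, mutation figure 0.1,
fivefold stratified cross-validated SVM accuracy (RBF kernel, C = 1,
per-band standardization fitted on training folds only) as fitness. Two
interpretation choices were open:

* **Mutation.** A single "mutation probability 0.1" is read per
  chromosome — with probability 0.1 one uniformly chosen bit flips. Read
  per bit, 0.1 would flip ~27 of 272 bands in every child, which prevents
  population convergence altogether; per-bit mode remains available via
  `ga_config(mutation_mode = "per_bit")`.
* **Initial density.** Bands start selected with probability 0.3, biasing
  the search toward the parsimonious subsets wavelength selection is
  after (published EW counts are 16 and 37 of 272 bands).

The restart protocol reruns the GA from fresh populations; a run whose
fitness is *strictly* greater than the reference becomes the new reference
and resets the stall counter; after `stall_limit` consecutive
non-improving runs the best subset is returned. The reference
configuration uses 1000; desk-scale runs lower it (the package default is
20). Fitness values are memoized — fitness is a deterministic function of
the band subset given the data and fold seed — and the memo may be shared
across restarts and protocol seeds on the same dataset without changing
any result. The fold assignment is held fixed across restarts so run
fitnesses are comparable. Empty chromosomes are repaired by activating one
random bit; an empty subset scores fitness 0 by convention.

## Reflectance image set

ReliefF (all samples as anchors, k = 10 neighbours, min-max scaling,
Manhattan diffs; guarded against constant features) weights the EWs; the
top-weight band image is the reference. Band-image correlations are Pearson
r between vectorized in-mask pixels. The container scan walks the remaining
EWs in ascending index order and admits an image iff |r| ≤ 0.3 against
*everything* already inside, stopping after four admissions; members are
then ranked by |r| with the reference, ascending. The superposition search
stacks candidates one by one in that order, trains a LeNet-5 per depth,
scores EW-spectra + image features by SVM cross-validation, and keeps the
depth with maximal accuracy (ties to the smaller depth). By default the
correlation matrix is averaged over all calibration samples — more stable
than the single randomly chosen sample of the original protocol, which
`single_sample_corr = TRUE` restores.

## Image features, combination, fusion

LeNet-5 (two 5×5 convolutions with 6 and 16 maps, two 2×2 average pools,
fully connected 120 and 84, 3-class output) is trained as a stress
classifier on calibration stacks only (Adam, softmax cross-entropy,
learning rate 5e-3, batch 16), then frozen. Features are the 84-unit
second fully-connected layer taken *before* its activation; "without the
final activation" could also mean the output layer, which
`feature_tap = "output_preactivation"` provides. Stacks are the
mask-zeroed ROI bounding boxes of the RIS bands, bilinearly resized to
32×32 (16×16 in the desk-scale tests); input geometry is not fixed by the
reference description, so it is a package choice. The convolution and
backpropagation kernels are implemented in vectorized base R (im2col plus
BLAS matrix products); both networks pass finite-difference gradient
checks in the test suite.

Combination standardizes the spectral and image blocks separately (fitted
on calibration rows; zero-variance columns map to 0 with a QC flag) and
concatenates spectral-first, so the two blocks enter the classifier on
comparable scales. Fusion concatenates the young vector then the mature
vector of the same `(plant, replicate)` pair and refuses mismatched labels
or identities.

## Classifiers, split, metrics

The 7:3 split is stratified per class with largest-remainder rounding —
the only rounding that turns 315 pairs of 108/105/102 into exactly
220/95 — and is computed once per experiment at the pair level, so
single-stage and fused models are evaluated on the same plants. Grouped
splitting (whole plants on one side) is available via `groups=`; it is not
the default because three-leaf plant blocks cannot match the per-class 7:3
counts to ±1. The SVM uses an RBF kernel with C = 1 and probability
scores; the random forest uses 500 trees and √d features per split; the
1-D DenseNet uses one dense block (4 layers, growth 12, kernel 3, stem of
16 channels), global average pooling and Adam (learning rate 1e-2, 100
epochs default) — these hyperparameters are declared package defaults, all
configurable. ROC is one-vs-rest per class; a class absent from the
prediction set yields flagged NA metrics rather than a silent number.

## Numerical choices and degenerate inputs

Ties everywhere resolve to the smallest index or smallest k
(`which.max`-first semantics). Zero-variance band images correlate as 0
with a QC flag; constant features contribute zero ReliefF weight;
standardization guards division by zero. SVM fold assignment, GA
populations, network initialization and batch order are all driven by
explicit seeds; every documented entry point is bit-reproducible given its
seed, and the experiment driver derives all stage seeds from one global
seed.

## Desk-scale problem sizes

The test suite and the acceptance script run the full chain at reduced
sizes chosen to exercise every code path while staying desk-scale: 40–80
band simulators on 24–48 px frames, 16×16 CNN inputs, GA populations
10–40 over 8–60 generations with stall limits 1–5, designs of 6–20 leaves
per treatment and stage, and a recovery benchmark of 100 bands with 5
informative ones at unit signal-to-noise. The published operating point
(272 bands, 630 leaves, population 100, 400 generations, stall 1000)
remains the default of the user-facing configuration objects.

## Known limitations

* Headline accuracies of the original study are tied to its private
  630-leaf greenhouse dataset and cannot be reproduced here; the package
  validates directional and structural properties instead.
* The simulator's variance model is uncalibrated to any instrument; see
  above for what it omits.
* The in-package CNNs are deliberately small; they are faithful to the
  described architectures, not performance-tuned deep-learning stacks.
* ReliefF is O(n²) in samples — fine for hundreds of leaves, not for
  pixel-level use.
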