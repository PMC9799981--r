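---
title: "Methods: quantifying paraspeckle-linked translational regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying paraspeckle-linked translational regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speckletools)
library(dplyr)
```

Studies of stress-regulated, cap-independent translation combine four very
different quantitative readouts: counting lncRNA foci (paraspeckles) in
FISH/smiFISH images, differential statistics on an affinity-purification
mass-spectrometry (AP-MS) interactome, 2^-ddCt quantification of mRNA
recruitment into polysomes, and dual-luciferase bicistronic reporter
ratios measuring IRES activity. `speckletools` implements each readout as
a small, tested pipeline, together with seeded simulators that generate
inputs with known ground truth. This vignette explains the models and the
choices behind them; every number shown is computed by the package at
build-test time or reproducible with `scripts/acceptance.R`.

## Spot imaging

**Model.** A diffraction-limited FISH spot is an isotropic 2D Gaussian of
width `spot_sigma` (pixels) on a noisy background. Detection convolves
the channel with a zero-sum negated Laplacian-of-Gaussian (LoG) kernel
and takes strict local maxima (8-connectivity) above a threshold;
plateaus of exactly equal response collapse to their centroid. The kernel
is *amplitude-calibrated*: its response to a Gaussian spot of matching
width equals the spot's peak amplitude, so thresholds are expressed on
the image intensity scale. A useful default is half the expected spot
amplitude; at that setting the response of pure Gaussian noise (standard
deviation about 0.53 x `noise_sd` after filtering at sigma 1.5) is far
below threshold for signal-to-noise ratios of 5 and above.

**Parameters.** `sigma` (default 1.5 px) is the LoG scale and should be
close to the PSF width; the upstream analysis this package re-implements
names the filter but not its scale, so the default is a documented choice,
not a reproduction. The colocalization cutoff `max_dist` (default 0.3 um,
about one PSF width) is likewise a required, documented parameter.

**Nucleus segmentation** is Gaussian smoothing, Otsu thresholding, hole
filling, and watershed declumping on the distance transform, with
components under `min_area` (default 50 px) discarded — the standard
recipe for separating touching interphase nuclei. Per-cell focus counts
include zero-focus cells; spots outside every nucleus keep cell label 0
and are excluded from per-cell statistics (cytoplasmic signal is reported
separately in the assays this mirrors).

**Colocalization** uses greedy one-to-one matching in increasing distance
order. Greedy matching can in principle return one pair fewer than the
maximum-cardinality matching in adversarial geometries; for
diffraction-limited spots at biological densities, where candidate
partners within 0.3 um are nearly always unique, it equals the exhaustive
minimum-total-distance matching (the test suite checks this against a
brute-force oracle on small instances).

**2D versus 3D.** Z-stacks (0.45 um step in the targeted acquisitions)
are maximum-intensity projected before analysis. Per-cell focus counts at
1–5 foci per nucleus do not require z-resolved detection, and projection
keeps the watershed and LoG machinery two-dimensional; truly overlapping
foci in z would be merged, which at these densities is rare.

**What the simulator emulates — and does not.** `simulate_images()`
draws per-cell spot counts from a Poisson distribution, places spots
uniformly inside disk nuclei, renders Gaussian PSFs plus Gaussian noise,
and optionally places a fraction of second-channel spots within a small
offset of first-channel spots. It does not emulate autofluorescence
texture, uneven illumination, chromatic shift, or non-disk nuclei, so
passing tests demonstrate correctness of the detection machinery, not
robustness to every real-microscope artifact. The detection F1 >= 0.95
acceptance condition is evaluated at amplitude/noise >= 5 and
inter-spot spacing >= 4 sigma (`min_spot_separation`), the regime the
detector is specified for; the simulator's default leaves spacing
unconstrained, which is the more realistic condition for counting.

## AP-MS differential interactome

**Pipeline order is fixed and enforced** (each stage checks its
predecessor): protein intensity = sum of unique peptide intensities
(shared peptides are dropped entirely); median normalization (each run
rescaled so its observed median equals the median of run medians);
missing values replaced by the run's 5% quantile (linear interpolation
between order statistics, R type 7); log2 transform; technical-replicate
averaging per biological sample; unpaired two-tailed Student t-test with
pooled (equal) variance per comparison. Enrichment requires
|log2 fold change| > 1 *and* p < 0.05; confidence filters additionally
require a total averaged PSM count strictly greater than 4 and
quantification before imputation in at least two biological replicates of
at least one compared group. No multiple-testing correction gates these
flags; a Benjamini–Hochberg column is emitted for information only.

**Imputation scale.** The 5% quantile is computed on the normalized
linear intensity scale, before the log2 transform, matching the stated
order of the upstream procedure. The alternative reading (impute after
log2) changes nothing about which entries are imputed, only their
interaction with averaging; the linear-scale order is the one
implemented and tested.

**Known biases, by design.** Two properties of this classical pipeline
are worth stating because the test suite deliberately isolates them:

* *Left-censoring bias.* When missingness concentrates at low intensity,
  replacing missing values by a low run quantile biases fold-change
  estimates of partially censored proteins (about +0.14 log2 units at the
  simulator's default censoring level). The unbiasedness and type-I-error
  checks therefore run on complete data, isolating the estimator and test
  calibration; the censoring bias is a property of quantile imputation
  itself.
* *Composition effect.* Median normalization assumes most proteins are
  unchanged. Spiking 2% of proteins by log2FC = 2 already shifts the
  affected runs' medians enough to absorb roughly 0.04 of the spike; the
  bias simulations keep the spiked fraction at this realistic level.

**Paraspeckle overlap.** The package ships a 40-row annotation of
reported paraspeckle components (name, alternative name, class, ITAF
function, presence in the bait interactome), used by
`annotate_paraspeckle()` in fixture mode (counts from the packaged
presence column: 22 of 40 present, 6 of them ITAFs) or analysis mode
(case-insensitive matching of caller-supplied protein names, honouring
alternative names). One documented inconsistency is preserved as
published: hnRNPR is described in the source's prose as one of six
ITAF-functional paraspeckle components of the interactome, while the
annotation table marks its presence as "No"; the fixture reproduces the
table and this vignette records the discrepancy without resolving it.

## Polysome PCR array (2^-ddCt)

Technical replicates are averaged in Ct space (standard qPCR practice);
dCt = Ct(gene) − Ct(reference, default Gapdh) within each sample cancels
plate-level additive shifts; ddCt subtracts the calibrator treatment's
mean dCt; biological replicates are combined by averaging ddCt in log
space before exponentiating, which keeps the calibrator's RQ exactly 1.
Undetermined Ct values are treated as missing — never as Ct 40 — and a
gene with no usable Ct in a cell is dropped with a logged count.

The recruitment metric defaults to `polysomal_over_total` (the RQ of the
polysomal fraction divided by the RQ of total RNA, a translational
efficiency proxy); `polysomal_only` is provided because the upstream
normalization description mentions only the reference gene and
calibrator. Signed fold changes follow the reporting convention
RQ >= 1 -> RQ, RQ < 1 -> −1/RQ, so magnitudes are always >= 1 and
f(RQ) = −f(1/RQ). Class summaries count decreased (RQ < 1) and increased
(RQ > 1) genes with no dead-band; RQ exactly 1 counts as unchanged, and
at zero simulation noise a true-zero effect lands within floating-point
rounding of RQ = 1, so its *signed display* is ±1 while RQ itself is 1 to
12 decimal places.

## Dual-luciferase reporter

Background (mean of the plate's non-transduced wells, per channel) is
subtracted from every sample well; wells that do not exceed background are
invalidated rather than clamped, because a non-positive LucR makes the
ratio meaningless. IRES activity is the per-well LucF/LucR ratio — a
shared per-well gain cancels — averaged over each biological replicate's
technical wells (the targeted design: 9 biological x 3 technical).
Normalization divides by the reference group's *mean* ratio (the
matched-pair alternative is not implemented; the upstream description
does not specify, and mean-division is recorded as the package's choice),
making the reference mean exactly 1. Group comparisons use the
Mann–Whitney test: exact for n1 + n2 <= 20 without ties (equivalent to
full enumeration, as the test suite verifies), otherwise the normal
approximation with tie and continuity corrections, with the method
recorded in the output.

## Simulators as study-condition definitions

Each simulator's defaults encode the targeted experimental designs:
3–4 biological x 2–3 technical replicates per AP-MS group with log-normal
intensities and run-level scale offsets; 2 biological x 3 technical
replicates per PCR-array cell; 9 biological x 3 technical wells per
reporter group. Where the upstream work states no value (spot intensity
distributions, microscope noise, Ct noise), defaults are realistic
placeholders chosen once — e.g. Ct noise 0.2 cycles, reporter gain CV
10%, spot amplitude/noise 5 — and are not fitted to any dataset.
Problem sizes in the tests (50 fields of 10 nuclei for detection scoring,
2000-protein null and 20 spike seeds for the enrichment calibration,
50 seeds for bias) were chosen to give Monte-Carlo error comfortably
below the property bounds being checked.

## Worked example

```{r demo}
out <- run_demo(file.path(tempdir(), "demo"), seed = 1)
out$paraspeckle_overlap
head(out$class_summary)
out$reporter_comparison[, c("group_a", "group_b", "n_a", "U", "p_value")]
```

## Limitations

* No deconvolution, drift or chromatic-aberration correction; detection
  is 2D (projected) only.
* The MS identification layer (search engines, FDR control,
  cross-assignment) is out of scope: the pipeline starts from intensity
  and PSM tables.
* Quantile imputation biases fold changes of left-censored proteins (see
  above); interpret hits near the detection limit with the PSM/replicate
  filters in mind.
* Greedy colocalization is not a guaranteed maximum matching in
  adversarial geometries.
* The exact Mann–Whitney route requires tie-free data; replicate means
  from continuous readouts satisfy this in practice.
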