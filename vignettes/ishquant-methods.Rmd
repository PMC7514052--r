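---
title: "Quantifying dual 5'/3' in situ hybridization of long transcripts with ishquant"
author: "ishquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dual 5'/3' ISH with ishquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ishquant)
```

# The measurement problem

Very long genes take hours to transcribe. Full-length muscle dystrophin
(dp427) spans ~2.3 Mb and, at a constant elongation rate of ~40 bases/s,
takes ~16 h to transcribe. A probe set targeting sequence near the 5' end
of the transcript therefore labels both nascent (still-attached) and
mature transcripts, while a 3' probe set — whose target emerges only
minutes before termination — labels essentially mature transcripts only.
Multiplexed single-molecule in situ hybridization (e.g. RNAscope) with
one probe set per fluorophore turns this asymmetry into a measurement:

* small, punctate foci (~1–3 µm² apparent area) are single transcripts;
* broad, bright, strictly nuclear 5'-only foci (10–100 µm²) are sites of
  concerted nascent transcription;
* sub-micron 5'/3' pairing in the sarcoplasm identifies dual-labelled
  mature transcripts;
* the bulk 5'/3' abundance ratio, combined with the inter-region
  transcription time, yields the mature transcript's mean lifetime.

`ishquant` implements this whole analysis as a tested pipeline: nuclear
segmentation, focus detection and size classification, compartment
(nuclear vs sarcoplasmic) splitting, nearest-neighbour co-localization
against two null models, fluorescence calibration to transcript counts,
and the steady-state kinetic model. Because no public microscopy dataset
accompanies this workflow, the package also contains a synthetic-field generator
with exhaustive ground truth; every stage is validated against it.

# The steady-state kinetic model

At transcriptional steady state, with one transcript initiated every
$\Delta t$ minutes per active locus, the number of transcripts carrying
the 5' probe region is proportional to the time a transcript spends
carrying it: the inter-region transcription time $T_t$ (while nascent)
plus the mature mean lifetime $T_l$. The 3' region, lying just before
termination, is carried for $T_l$ only. Hence

$$\frac{5'}{3'} = \frac{T_t + T_l}{T_l}, \qquad
T_l = \frac{T_t}{\mathrm{ratio} - 1}, \qquad
T_{1/2} = 0.693\, T_l,$$

and the nascent fraction of all transcripts is $1 - 1/\mathrm{ratio}$.
The rounded constant 0.693 is used in place of $\ln 2$ to match
conventional three-figure arithmetic; the difference is below 0.03%. $T_t$ comes from a
`GeneModel`: gene length, total transcription time, and probe-region
offsets, assuming a constant, sequence-independent elongation rate. With
the dp427 defaults (2.3 Mb, 16 h), the 1,550 kbp between the ISH probe
regions takes ~10.8 h and the 1,950 kbp between the qPCR amplicons
~13.6 h.

```{r kinetics}
est <- estimateKinetics(counts_5p = 2500, counts_3p = 780)
est
```

Two readings of the model deserve explicit parameters rather than
constants:

* **Initiation interval.** Occupancy of $N$ nascent transcripts per
  nucleus implies one initiation every $60\,T_r/N$ minutes, where the
  residence time $T_r$ may be read as the full transcription time (16 h)
  or as the ~11 h during which the 5' region is carried; the package
  exposes `residence_time_h` explicitly (`initiationInterval()`).
* **Ratio inputs.** Per-ng qPCR-style abundances and per-field imaging
  counts funnel into the same estimator; `transcriptsPerNg()` converts
  between them using the field geometry (below).

# Field geometry and RNA mass

All pixel measures flow through a `FieldGeometry`: a 1388×1040-pixel
field at ~2 px/µm is 360,880 µm²; at 8 µm section thickness and a muscle
density of 1.06 mg/mm³ one field represents ~3 µg of tissue, i.e.
0.75–1.5 ng of total RNA at typical yields of 0.25–0.5 µg/mg. This is
what justifies reporting imaging counts "per ng RNA".

```{r geometry}
fieldGeometry()
```

# What the synthetic generator emulates

`generateField()` renders three channels (nuclear stain, 5', 3') and
returns a ground-truth table of every planted object. Its defaults are
the conditions of a healthy adult muscle field, and `mdxSceneConfig()`
the dystrophic counterpart:

| parameter | healthy-like | dystrophic-like | basis |
|---|---|---|---|
| nuclei / field | 300 | 700 | dystrophic fields carry more nuclei |
| small 5' foci (mean) | 585 = 260 pairs + 325 orphans | 146 = 15 + 131 | per-field census of the two genotypes |
| small 3' foci (mean) | 714 = 260 + 454 | 126 = 15 + 111 | ditto |
| paired fraction | ~40% within ≤0.8 µm | ~20% | sub-micron 5'/3' pairing of mature transcripts |
| small foci in nuclei | 15% | 60% | nuclear small counts are genotype-stable; sarcoplasmic counts collapse |
| large 5' foci | 80 | 86 | nascent-site counts are genotype-similar |
| transcripts / large focus | 20–40 | 10–20 | nascent occupancy per expressing nucleus |
| unit intensity | 6.0 ± 2.7 AU | same | single-transcript integrated intensity |

Counts are Poisson draws around these means; placement is uniform within
the allowed compartment. Spots are isotropic Gaussians of σ = 0.35 µm,
chosen so single-spot apparent areas fall in the 1–3 µm² mode at the
default threshold. Large foci are 3–6 strongly overlapping tighter
Gaussian blobs (σ 0.55–0.8 µm) placed wholly inside one nucleus: their
thresholded union lies in 10–100 µm² and their per-pixel brightness
exceeds single spots severalfold, so exposure series saturate large foci
first, as real nascent sites do. The camera model applies Poisson shot
noise (200 photons/AU) plus Gaussian read noise (σ 0.1 AU) on a 1 AU
background; at these defaults detection F1 is ≈0.97–0.99. Intensity
draws are truncated at 2 AU: branched-amplification chemistry gives
single molecules a signal floor, and an untruncated normal would plant
physically meaningless near-zero spots.

Deliberate simplifications — the generator does **not** emulate real
optics (diffraction rings, depth-dependent blur), autofluorescence
texture, fibre architecture, macrophage-derived non-specific patches, or
section-to-section registration. Passing tests therefore demonstrate
correctness of the measurement logic under a faithful spatial/statistical
model, not robustness to every imaging artefact of real tissue.

Two placement margins matter for interpretation: sarcoplasmic foci are
planted ≥1.5 µm outside nuclear boundaries and nuclear foci ≥1 µm inside,
so at default settings no planted focus straddles a segmented boundary
and compartment counts conserve exactly. Real data will contain
straddlers; the pipeline reports the resulting discrepancy rather than
hiding it (see below).

# Detection choices

**Nuclear segmentation** follows the classic ImageJ-macro workflow:
automatic thresholding by Huang's fuzzy-entropy or Yen's
maximum-correlation criterion (implemented from the published
algorithms, validated against independent reference implementations),
one binary watershed pass on the distance transform to split touching
nuclei, then connected-component labelling. Objects under 3 µm² are
discarded as debris.

**Probe thresholding.** Macro workflows threshold the probe channels to
remove background and non-specific staining, but no canonical grey
level exists. The default policy is background mean + 3 SD, with
both statistics estimated from the lowest-intensity quartile of the
image and corrected for truncation under a Gaussian model (the kept tail
$z < -0.6745$ has mean $-1.2713\sigma$ and sd $0.4912\sigma$; without
the correction the "mean + 3 SD" of a truncated sample sits at the
background level itself). Fixed values and Otsu's method are available
as overrides; masked-image re-detection reuses the threshold and
background of the unmasked pass.

**Measurement.** Apparent area is the thresholded component's pixel
count converted to µm² — apparent, because fluorescence resolves a
point-spread function, not molecule size; the half-open size bins
[0.5, 10) µm² ("small") and [10, 100] µm² ("large") therefore classify
apparent areas, with a convention required at the touching edge (10 µm²
is "large"). Integrated intensity is the background-subtracted sum over
the component grown by 2 px, so that sub-threshold spot tails are
included; without the growth, a constant ~20% of single-spot flux is
lost below threshold and calibration would be biased low. Components of
a single pixel are indistinguishable from shot noise and are dropped;
larger components outside [0.5, 100] µm² are kept with class
`rejected`. Border-touching components are flagged, not removed.

**Compartments.** Consistent with mask-based macro workflows,
compartment counts
re-run detection on the masked and inverse-masked images rather than
assigning centroids; a straddling focus may then appear in both
compartments, and `compartmentCounts()` reports
|total − (nuclear + sarcoplasmic)| per class instead of forcing
conservation. A centroid-assignment mode is provided (off by default)
for users who prefer exact conservation. Counts are reported per image
and never normalised to nuclei, because dystrophic fields carry more
nuclei and per-nucleus normalisation would bias against them.

# Co-localization nulls

Nearest-neighbour distances are computed per source focus on
sarcoplasmic small foci, in both directions (5'→3' and 3'→5'), reported
separately and pooled for "fraction of foci paired" summaries. No edge
correction is applied, because the empirical null is computed under the
same edge effects. Two nulls are provided:

* **Rotation null**: the 3' channel rotated 90°. On a non-square field,
  coordinates are normalised to the unit square, rotated there, and
  rescaled — every point stays in-field and density is preserved; the
  transform is exactly 4-periodic and preserves the inter-point distance
  multiset up to the axis rescaling.
* **Random null**: both point sets uniform in the field rectangle,
  averaged over 1000 virtual fields (seeded). With 400 points per set in
  the default field, ~5% of pairings lie beyond 30 µm; with 200 points,
  ~25%; with 800, <1%.

A toroidal (wrap-around) variant exists solely as an analytic oracle:
under periodic boundaries the nearest-neighbour survival is exactly
$\exp(-\lambda \pi r^2)$, which the tests verify to within 3 Monte-Carlo
σ; the bounded-field null must lie above it at every radius (edge
effects only lengthen distances). The physical upper bound for
within-transcript 5'–3' separation depends on contested ssRNA
length-per-base values, so the pairing radius is a parameter (1 µm
default in summaries) rather than a constant.

# Intensity calibration

Quantification requires linearity: `checkLinearity()` fits a
through-origin line to the two lowest exposures of an ROI series and
flags the ROI saturated when the highest exposure falls more than 20%
(configurable) below the linear prediction — only non-saturated
exposures are eligible. Small sarcoplasmic foci then calibrate the
single-transcript unit intensity (background-subtracted mean ± SD), and
large-focus intensities divide by the unit mean to estimate nascent
transcripts per nucleus. Estimates are reported unrounded alongside the
nearest integer, and totals use the unrounded values to avoid rounding
bias. Because dystrophic muscle has too few small foci to calibrate
itself, a healthy-tissue reference calibration is applied to dystrophic
large foci by default (overridable), and both per-animal and pooled unit
means are supported. Calibration never compares across fluorophores:
separate dyes for 5' and 3' probes preclude direct 5'-to-3' fluorescence
comparison.

Sample-size adequacy uses the standard normal-approximation rule
$n = (z \cdot \mathrm{CV}/E)^2$ for estimating a mean to relative
precision $E$ at a given confidence; with the observed single-transcript
distributions (means 6–8 AU, SD ~3) it requires ~70–80 foci for ±10% at
95% — the classical Snedecor–Cochran prescription.

# Cohort simulation and statistics

`runPipeline()` maps the full analysis over a simulated multi-genotype
cohort. Biological variation enters at two levels, both multiplicative
lognormal: a per-animal density factor (CV 0.25 on small-focus means,
CV 0.14 on large-focus means) and per-field factors split into a
channel-shared component and per-channel components. In healthy-like
cohorts the shared component dominates (CV 0.30 vs 0.05), so per-image
5' and 3' counts co-vary strongly (Pearson r ≈ 0.95); in dystrophic-like
cohorts the two components are comparable (0.25/0.25), decoupling the
channels — mirroring the patchy pathology (revertant domains, variable
decay) of dystrophic muscle. These CVs were set to reproduce the per-animal
SDs and 5'-vs-3' correlation ranges characteristic of the healthy and
dystrophic cohorts the generator emulates.

Group comparisons use two-tailed Mann–Whitney U tests **on per-animal
means** (never per-image values, which would pseudo-replicate), with
significance at 0.05; correlations (Pearson or Spearman) are computed
within animals. Test problem sizes: 4 animals × 9 images per genotype,
the lower end of the 9–30 images per animal typical of such cohorts,
which keeps the
full cohort analysis at a few minutes on one CPU while preserving every
qualitative contrast (sarcoplasmic small counts separate genotypes,
large-focus counts do not, dystrophic fields have more nuclei).

# Numerical and degenerate-input conventions

* All randomness is locally seeded (`seed` arguments; per-field seeds
  derive from the master seed); the global RNG state is saved and
  restored, and equal seeds give bit-identical fields, tables and
  cohorts.
* A blank image yields zero nuclei / zero foci, not an error; non-finite
  pixels are an error.
* Nucleus placement retries are bounded; an overcrowded scene fails
  explicitly rather than looping.
* A 5'/3' ratio ≤ 1 has no finite steady-state lifetime and raises an
  error at exactly 1 (the no-decay limit).
* Steady-state count draws switch from Poisson to a rounded normal above
  λ = 10⁷ to avoid integer overflow at extreme lifetimes.
* The dp71-like "3'-only nuclei" scene element exists but defaults off.

# Known limitations

* 2-D only: sections are treated as single 8 µm optical planes, as in
  cryosection imaging practice; no z-stacks.
* The threshold policy is a documented default, not a canonical
  constant; absolute counts shift slightly with the
  threshold while all comparative statistics are threshold-stable in our
  tests.
* Centroid-based pairing underestimates co-localization when foci merge
  at separations below the PSF scale (~0.5 µm).
* The kinetic model assumes constant elongation, no premature
  termination, and steady state; violations bias the inferred lifetime
  in proportion to their effect on the 5'/3' ratio.
* No image stitching or whole-section reconstruction; fields are
  analysed independently.
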