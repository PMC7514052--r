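# ishquant

Quantitative analysis of intra-transcript multiplex in situ hybridization
(ISH) images of very long transcripts, built around dual 5'/3' probing of
full-length muscle dystrophin (dp427).

## The problem

A 2.3 Mb gene transcribed at ~40 bases/s takes ~16 hours to finish one
transcript. Probing the same transcript near its 5' and 3' ends with two
fluorophores therefore separates transcript populations by maturity: 5'
probe sequence is carried by nascent *and* mature transcripts, 3'
sequence essentially by mature transcripts only. In tissue sections this
yields three measurable signal classes — small punctate foci (single
transcripts, ~1–3 µm² apparent area), large bright strictly nuclear
5'-only foci (10–100 µm², concerted nascent transcription), and
sub-micron 5'/3' pairs in the sarcoplasm (dual-labelled mature
transcripts) — plus one bulk quantity, the 5'/3' abundance ratio.

`ishquant` is for researchers quantifying such images (or validating the
quantification itself). It implements, as S4 classes and camelCase
functions in Bioconductor style:

* **Nuclear segmentation** — Huang/Yen automatic thresholding, one
  binary watershed pass, connected components (`segmentNuclei`).
* **Focus detection** — background-eliminating threshold, per-component
  apparent area in µm², integrated background-subtracted intensity,
  small/large/rejected size classes (`detectFoci`, `classifyBySize`).
* **Compartment analysis** — nuclear vs sarcoplasmic counts by mask and
  inverse mask, with the boundary-straddling discrepancy reported
  (`compartmentCounts`, `fractionExpressingNuclei`).
* **Co-localization** — per-focus nearest-neighbour distances between
  channels against 90°-rotation and 1000-virtual-field random-point
  nulls, with a toroidal analytic-oracle mode
  (`nearestNeighborDistances`, `rotationNull`, `randomNull`,
  `pairingSummary`).
* **Intensity calibration** — exposure-series linearity/saturation
  checks, single-transcript unit intensity, nascent transcripts per
  nucleus, and the n = (z·CV/E)² sample-size rule (`checkLinearity`,
  `calibrateUnitIntensity`, `estimateNascentCount`,
  `requiredSampleSize`).
* **Steady-state kinetics** — the core model

  ```
  5'/3' = (T_transcript + T_lifetime) / T_lifetime
  T_lifetime = T_transcript / (ratio − 1),   T_1/2 = 0.693 · T_lifetime
  nascent fraction = 1 − 1/ratio
  ```

  with gene-model-derived inter-region transcription times and
  field-to-RNA-mass normalisation (`estimateKinetics`, `geneModel`,
  `fieldRnaMass`, `transcriptsPerNg`).
* **Synthetic fields** — a generator of multi-channel fields with
  exhaustive ground truth emulating healthy and dystrophic muscle, plus
  a steady-state transcript-count generator (`generateField`,
  `wtSceneConfig`, `mdxSceneConfig`, `generateSteadyStateCounts`), and a
  cohort orchestrator with Mann–Whitney/correlation statistics
  (`runPipeline`, `compareCohorts`, `correlateMetrics`).

Images are read/written as 16-bit TIFF with a JSON sidecar
(`writeField`, `readField`); ground truth and cohort tables are plain
CSV. A thin command-line wrapper lives in `inst/scripts/run-pipeline.R`.

## Worked example

Half-life from bulk 5'/3' abundances (2500 and 780 transcripts per ng),
using the default dp427 gene model:

```r
library(ishquant)
estimateKinetics(counts_5p = 2500, counts_3p = 780)
#> KineticEstimate (steady-state 5'/3' model)
#>   5'/3' ratio          : 3.205
#>   transcription time   : 10.78 h (inter-region)
#>   mean lifetime        : 4.89 h
#>   half-life            : 3.39 h
#>   nascent fraction     : 0.69
```

A transcript whose synthesis takes ~16 h persists, once mature, for only
~3.4 h — and ~69% of all its copies are still nascent.

Image analysis on a simulated healthy-muscle field:

```r
cfg <- wtSceneConfig(seed = 1)
field <- generateField(cfg)
mask <- segmentNuclei(field$images$nuclear, cfg@geometry)
compartmentCounts(field$images$p5, field$images$p3, mask, cfg@geometry)
#> FieldSummary: 289 nuclei, 67 large 5' nuclear foci (23.2% of nuclei)
#>  channel size_class  compartment count
#>       5p      small        total   554
#>       5p      small      nuclear    68
#>       5p      small sarcoplasmic   486
#>       5p      large        total    67
#>       5p      large      nuclear    67
#>       5p      large sarcoplasmic     0
#>       3p      small        total   698
#>       3p      small      nuclear   103
#>       3p      small sarcoplasmic   595
#>       3p      large        total     0
#>       3p      large      nuclear     0
#>       3p      large sarcoplasmic     0
```

Every large 5' focus sits in a nucleus (23% of nuclei are actively
expressing), the 3' channel has essentially no large foci, and small
foci of both channels dominate the sarcoplasm — the signature of a
healthy field. The random-point co-localization null on the same
geometry:

```r
rn <- randomNull(400, 400, cfg@geometry, n_fields = 100, seed = 1)
fractionBeyond(rn, 30)
#> [1] 0.053
```

i.e. with 400 random points per channel only ~5% of nearest-neighbour
pairings exceed 30 µm, the baseline against which genuine 5'/3' pairing
(~40% within 1 µm in healthy fields) and its absence in dystrophic
fields are judged.

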