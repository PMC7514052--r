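#' @import methods
#' @importFrom stats rpois rnorm runif rlnorm qnorm sd quantile wilcox.test
#'   cor.test setNames
#' @importFrom utils head write.csv read.csv
NULL

#' FieldGeometry: physical description of one imaging field
#'
#' Captures the pixel grid, pixel scale and section thickness of a single
#' 2-D imaging field, together with tissue density and RNA yield so that
#' pixel measurements can be converted to areas, volumes, tissue mass and
#' RNA mass. Defaults describe a 1388 x 1040 pixel field at 20x
#' magnification (~2 pixels per micron) of an 8 um cryosection of skeletal
#' muscle.
#'
#' @slot width_px,height_px integer pixel dimensions of the field.
#' @slot px_per_um pixels per micron.
#' @slot thickness_um physical section thickness in microns.
#' @slot density_mg_per_mm3 tissue density (muscle: 1.06 mg/mm^3).
#' @slot rna_yield_ug_per_mg numeric length-2, low/high RNA yield per mg of
#'   tissue (typical muscle: 0.25-0.5 ug/mg).
#' @name FieldGeometry-class
#' @rdname FieldGeometry
#' @exportClass FieldGeometry
setClass("FieldGeometry",
  representation(
    width_px = "integer",
    height_px = "integer",
    px_per_um = "numeric",
    thickness_um = "numeric",
    density_mg_per_mm3 = "numeric",
    rna_yield_ug_per_mg = "numeric"
  )
)

setValidity("FieldGeometry", function(object) {
  msg <- character()
  if (object@width_px <= 0L || object@height_px <= 0L)
    msg <- c(msg, "pixel dimensions must be positive")
  if (object@px_per_um <= 0)
    msg <- c(msg, "px_per_um must be positive")
  if (object@thickness_um <= 0)
    msg <- c(msg, "thickness_um must be positive")
  if (object@density_mg_per_mm3 <= 0)
    msg <- c(msg, "density must be positive")
  y <- object@rna_yield_ug_per_mg
  if (length(y) != 2L || any(y <= 0) || y[1] > y[2])
    msg <- c(msg, "rna_yield_ug_per_mg must be (low, high) with 0 < low <= high")
  if (length(msg)) msg else TRUE
})

#' SceneConfig: parameters of a synthetic ISH field
#'
#' Describes one synthetic multiplex ISH field: expected numbers of nuclei,
#' co-localized 5'/3' pairs (mature transcripts), orphan single-channel
#' foci, and large 5'-only nuclear foci (nascent transcription sites),
#' together with the image-formation parameters (point-spread sigma, unit
#' single-transcript intensity, background and noise). All object counts
#' are Poisson means; all randomness is governed by \code{seed}.
#'
#' @slot geometry a \linkS4class{FieldGeometry}.
#' @slot n_nuclei expected nuclei per field.
#' @slot nucleus_radius_um mean and sd of nucleus radius (um).
#' @slot n_pairs expected number of co-localized 5'+3' pairs.
#' @slot pair_offset_um maximum 5'-3' separation within a pair (um).
#' @slot n_orphan_5p,n_orphan_3p expected unpaired small foci per channel.
#' @slot frac_small_in_nucleus fraction of small foci placed inside nuclei.
#' @slot n_large_foci expected 5'-only large nuclear foci.
#' @slot large_focus_area_um2_range admissible large-focus area (um^2).
#' @slot transcripts_per_large_focus min/max ground-truth nascent counts.
#' @slot unit_intensity_au mean and sd of single-transcript integrated
#'   intensity (arbitrary linear units).
#' @slot background_au background mean and Gaussian read-noise sd.
#' @slot psf_sigma_um isotropic Gaussian spot sigma (um).
#' @slot photons_per_au photon-count scale for Poisson shot noise
#'   (\code{Inf} disables shot noise).
#' @slot nuclear_stain_au amplitude of the nuclear stain above background.
#' @slot n_3p_only_nuclei expected dp71-like nuclei carrying 3'-only small
#'   foci (default 0, off).
#' @slot seed integer random seed.
#' @name SceneConfig-class
#' @rdname SceneConfig
#' @exportClass SceneConfig
setClass("SceneConfig",
  representation(
    geometry = "FieldGeometry",
    n_nuclei = "numeric",
    nucleus_radius_um = "numeric",
    n_pairs = "numeric",
    pair_offset_um = "numeric",
    n_orphan_5p = "numeric",
    n_orphan_3p = "numeric",
    frac_small_in_nucleus = "numeric",
    n_large_foci = "numeric",
    large_focus_area_um2_range = "numeric",
    transcripts_per_large_focus = "numeric",
    unit_intensity_au = "numeric",
    background_au = "numeric",
    psf_sigma_um = "numeric",
    photons_per_au = "numeric",
    nuclear_stain_au = "numeric",
    n_3p_only_nuclei = "numeric",
    seed = "integer"
  )
)

setValidity("SceneConfig", function(object) {
  msg <- character()
  cnt <- c(object@n_nuclei, object@n_pairs, object@n_orphan_5p,
           object@n_orphan_3p, object@n_large_foci, object@n_3p_only_nuclei)
  if (any(cnt < 0)) msg <- c(msg, "object counts must be >= 0")
  if (object@frac_small_in_nucleus < 0 || object@frac_small_in_nucleus > 1)
    msg <- c(msg, "frac_small_in_nucleus must lie in [0, 1]")
  if (object@pair_offset_um < 0) msg <- c(msg, "pair_offset_um must be >= 0")
  r <- object@large_focus_area_um2_range
  if (length(r) != 2L || r[1] < 10 || r[2] > 100 || r[1] > r[2])
    msg <- c(msg, "large_focus_area_um2_range must lie within [10, 100]")
  tr <- object@transcripts_per_large_focus
  if (length(tr) != 2L || any(tr <= 0) || tr[1] > tr[2])
    msg <- c(msg, "transcripts_per_large_focus must be (min, max), positive")
  if (object@psf_sigma_um <= 0) msg <- c(msg, "psf_sigma_um must be positive")
  if (length(msg)) msg else TRUE
})

#' NuclearMask: labelled nuclear segmentation of one field
#'
#' @slot labels integer matrix; 0 = background, k = nucleus k.
#' @slot algorithm automatic threshold algorithm used ("huang" or "yen").
#' @slot threshold the grey-level threshold actually applied.
#' @slot watershed_applied logical; whether the single binary watershed
#'   pass was applied.
#' @name NuclearMask-class
#' @rdname NuclearMask
#' @exportClass NuclearMask
setClass("NuclearMask",
  representation(
    labels = "matrix",
    algorithm = "character",
    threshold = "numeric",
    watershed_applied = "logical"
  )
)

#' NNResult: nearest-neighbour distances between two channels
#'
#' One nearest-neighbour distance per source focus, from each focus of the
#' source channel to the closest focus of the target channel.
#'
#' @slot direction "5p_to_3p", "3p_to_5p" or "pooled".
#' @slot distances_um numeric vector of nearest-neighbour distances (um).
#' @name NNResult-class
#' @rdname NNResult
#' @exportClass NNResult
setClass("NNResult",
  representation(
    direction = "character",
    distances_um = "numeric"
  )
)

setValidity("NNResult", function(object) {
  if (any(object@distances_um < 0)) "distances must be >= 0" else TRUE
})

#' GeneModel: genomic layout and transcription timing of a long gene
#'
#' Positions of the 5' and 3' probe regions along the gene (bp from the
#' transcription start), total transcription time, and the inter-region
#' separations used to convert genomic distance into transcription time
#' under a constant elongation rate. Defaults describe dystrophin dp427:
#' a 2.3 Mb gene transcribed in 16 h (~40 bases/s), ISH probe regions
#' separated by 1,550 kbp and qPCR amplicons by 1,950 kbp.
#'
#' @slot gene_length_bp total transcribed length in bases.
#' @slot total_transcription_time_h time to transcribe the full gene.
#' @slot regions data.frame with columns name, start_bp, end_bp giving
#'   probe/amplicon regions as offsets from the transcription start.
#' @slot separation_bp named numeric of inter-region distances (bp), e.g.
#'   \code{c(ish = 1.55e6, qpcr = 1.95e6)}.
#' @name GeneModel-class
#' @rdname GeneModel
#' @exportClass GeneModel
setClass("GeneModel",
  representation(
    gene_length_bp = "numeric",
    total_transcription_time_h = "numeric",
    regions = "data.frame",
    separation_bp = "numeric"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (object@gene_length_bp <= 0) msg <- c(msg, "gene_length_bp must be positive")
  if (object@total_transcription_time_h <= 0)
    msg <- c(msg, "total_transcription_time_h must be positive")
  r <- object@regions
  if (nrow(r)) {
    if (any(r$start_bp < 0) || any(r$end_bp > object@gene_length_bp) ||
        any(r$start_bp > r$end_bp))
      msg <- c(msg, "region offsets must lie within the gene")
  }
  if (any(object@separation_bp < 0) ||
      any(object@separation_bp > object@gene_length_bp))
    msg <- c(msg, "separations must lie within the gene length")
  if (length(msg)) msg else TRUE
})

#' KineticEstimate: steady-state kinetic quantities for one sample
#'
#' @slot ratio_5p_3p observed 5'/3' abundance ratio.
#' @slot t_transcript_h inter-region transcription time (h).
#' @slot mean_lifetime_h mature-transcript mean lifetime (h).
#' @slot half_life_h mature-transcript half-life (h).
#' @slot nascent_fraction fraction of transcripts that are nascent.
#' @name KineticEstimate-class
#' @rdname KineticEstimate
#' @exportClass KineticEstimate
setClass("KineticEstimate",
  representation(
    ratio_5p_3p = "numeric",
    t_transcript_h = "numeric",
    mean_lifetime_h = "numeric",
    half_life_h = "numeric",
    nascent_fraction = "numeric"
  )
)

#' CalibrationResult: single-transcript intensity calibration
#'
#' @slot unit_intensity_mean_au background-subtracted mean integrated
#'   intensity of single-transcript (small sarcoplasmic) foci.
#' @slot unit_intensity_sd_au its standard deviation.
#' @slot n_foci number of foci used.
#' @slot exposures_used_ms exposures accepted as non-saturated.
#' @slot adequacy_n_required sample size required for +/-10% precision at
#'   95% confidence given the observed mean and sd.
#' @name CalibrationResult-class
#' @rdname CalibrationResult
#' @exportClass CalibrationResult
setClass("CalibrationResult",
  representation(
    unit_intensity_mean_au = "numeric",
    unit_intensity_sd_au = "numeric",
    n_foci = "integer",
    exposures_used_ms = "numeric",
    adequacy_n_required = "integer"
  )
)

#' FieldSummary: per-field counts by channel, size class and compartment
#'
#' @slot counts data.frame with columns channel, size_class, compartment
#'   and count, where compartment "total" rows come from detection on the
#'   unmasked image.
#' @slot nuclei_count number of segmented nuclei.
#' @slot large_5p_nuclear_count large 5' foci detected within nuclei.
#' @slot fraction_expressing_nuclei large 5' nuclear foci / nuclei.
#' @slot discrepancy data.frame of |total - (nuclear + sarcoplasmic)| per
#'   channel and size class (boundary-straddling foci).
#' @name FieldSummary-class
#' @rdname FieldSummary
#' @exportClass FieldSummary
setClass("FieldSummary",
  representation(
    counts = "data.frame",
    nuclei_count = "integer",
    large_5p_nuclear_count = "integer",
    fraction_expressing_nuclei = "numeric",
    discrepancy = "data.frame"
  )
)
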