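## Decay constant relating mean lifetime and half-life. The rounded
## constant 0.693 is used rather than log(2) so derived half-lives match
## conventional three-figure arithmetic; the difference is < 0.03%.
DECAY_LOG2 <- 0.693

#' Construct a GeneModel
#'
#' Defaults describe full-length muscle dystrophin (dp427): a 2.3 Mb gene
#' transcribed at a constant rate in 16 h (~40 bases/s), with the 5' ISH
#' probe region at ~190-715 kb from the transcription start, the 3' probe
#' region at ~2,100-2,188 kb (ending ~28 kb before termination), an ISH
#' inter-probe separation of 1,550 kbp and a qPCR inter-amplicon
#' separation of 1,950 kbp.
#'
#' @param gene_length_bp transcribed length (bases).
#' @param total_transcription_time_h hours to transcribe the full gene.
#' @param regions data.frame(name, start_bp, end_bp) of probe/amplicon
#'   regions, offsets from the transcription start.
#' @param separation_bp named numeric of inter-region distances in bp.
#' @return a \linkS4class{GeneModel}.
#' @export
geneModel <- function(gene_length_bp = 2.3e6,
                      total_transcription_time_h = 16,
                      regions = data.frame(
                        name = c("5p", "3p"),
                        start_bp = c(190e3, 2100e3),
                        end_bp = c(715e3, 2188e3),
                        stringsAsFactors = FALSE),
                      separation_bp = c(ish = 1.55e6, qpcr = 1.95e6)) {
  new("GeneModel", gene_length_bp = gene_length_bp,
      total_transcription_time_h = total_transcription_time_h,
      regions = regions, separation_bp = separation_bp)
}

#' Elongation rate implied by a GeneModel
#' @param gene a \linkS4class{GeneModel}.
#' @return bases per second.
#' @export
elongationRateBpSec <- function(gene) {
  stopifnot(is(gene, "GeneModel"))
  gene@gene_length_bp / (gene@total_transcription_time_h * 3600)
}

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel: %.3g bp in %g h (%.1f bases/s)\n",
              object@gene_length_bp, object@total_transcription_time_h,
              elongationRateBpSec(object)))
  for (nm in names(object@separation_bp))
    cat(sprintf("  %s separation %.3g bp -> %.2f h\n", nm,
                object@separation_bp[[nm]],
                transcriptionTimeBetween(object, object@separation_bp[[nm]])))
})

#' Transcription time across a genomic distance
#'
#' Under the constant elongation rate implied by the gene model, the time
#' for the polymerase to traverse \code{distance_bp}. With the dp427
#' defaults, 1,550 kbp (ISH probes) takes ~10.8 h and 1,950 kbp (qPCR
#' amplicons) ~13.6 h.
#'
#' @param gene a \linkS4class{GeneModel}.
#' @param distance_bp genomic distance, 0 <= distance <= gene length.
#' @return time in hours.
#' @export
transcriptionTimeBetween <- function(gene, distance_bp) {
  stopifnot(is(gene, "GeneModel"))
  if (any(distance_bp < 0)) stop2("distance must be non-negative")
  if (any(distance_bp > gene@gene_length_bp))
    stop2("distance exceeds the gene length")
  distance_bp * gene@total_transcription_time_h / gene@gene_length_bp
}

#' Mean lifetime from the steady-state 5'/3' ratio
#'
#' At transcriptional steady state the 5' probe region (carried by both
#' nascent and mature transcripts) and the 3' probe region (mature
#' transcripts only, the region lying just before termination) satisfy
#' 5'/3' = (T_transcript + T_lifetime) / T_lifetime, where T_transcript
#' is the transcription time between the regions. Inverting gives
#' T_lifetime = T_transcript / (ratio - 1).
#'
#' @param ratio_5p_3p observed 5'/3' abundance ratio; must exceed 1 for a
#'   finite lifetime.
#' @param t_transcript_h inter-region transcription time (h), > 0.
#' @return mean lifetime in hours.
#' @examples
#' meanLifetimeFromRatio(2, 11)          # 11 h: nascent = mature
#' meanLifetimeFromRatio(2500 / 780, 11) # ~5 h
#' @export
meanLifetimeFromRatio <- function(ratio_5p_3p, t_transcript_h) {
  if (any(t_transcript_h <= 0)) stop2("t_transcript_h must be positive")
  if (any(ratio_5p_3p <= 1))
    stop2("ratio must exceed 1: no finite steady-state lifetime")
  t_transcript_h / (ratio_5p_3p - 1)
}

#' Half-life and mean lifetime interconversion
#'
#' Exponential decay: T_1/2 = 0.693 x T_lifetime (the rounded constant
#' 0.693 is used in place of ln 2).
#'
#' @param mean_lifetime_h mean lifetime(s), > 0.
#' @return half-life in hours.
#' @rdname halflife
#' @export
halfLife <- function(mean_lifetime_h) {
  if (any(mean_lifetime_h <= 0)) stop2("lifetime must be positive")
  DECAY_LOG2 * mean_lifetime_h
}

#' @param half_life_h half-life value(s), > 0.
#' @rdname halflife
#' @export
meanLifetimeFromHalfLife <- function(half_life_h) {
  if (any(half_life_h <= 0)) stop2("half-life must be positive")
  half_life_h / DECAY_LOG2
}

#' Nascent fraction of total transcripts
#'
#' From the steady-state 5'/3' ratio, the fraction of transcripts that
#' are nascent is 1 - 1/ratio; from direct counts it is
#' nascent / (nascent + mature).
#'
#' @param ratio_5p_3p 5'/3' ratio(s) > 1.
#' @return fraction in (0, 1).
#' @rdname nascent
#' @export
nascentFraction <- function(ratio_5p_3p) {
  if (any(ratio_5p_3p <= 1)) stop2("ratio must exceed 1")
  1 - 1 / ratio_5p_3p
}

#' @param nascent_total,mature_total direct transcript totals (>= 0, not
#'   both zero).
#' @rdname nascent
#' @export
nascentFractionFromCounts <- function(nascent_total, mature_total) {
  stopifnot(all(nascent_total >= 0), all(mature_total >= 0))
  tot <- nascent_total + mature_total
  if (any(tot == 0)) stop2("nascent and mature totals are both zero")
  nascent_total / tot
}

#' Normalize per-field counts to transcripts per ng RNA
#'
#' Divides per-field transcript counts by the RNA mass one field
#' represents. By default the mass must fall within the range implied by
#' the field geometry (~0.75-1.5 ng for the default field); supply
#' \code{check = FALSE} to override.
#'
#' @param counts per-field transcript counts (vectorised).
#' @param geometry a \linkS4class{FieldGeometry}.
#' @param assumed_rna_ng RNA mass per field in ng (default 1).
#' @param check enforce that \code{assumed_rna_ng} lies in the geometry's
#'   computed range.
#' @return counts per ng RNA.
#' @export
transcriptsPerNg <- function(counts, geometry, assumed_rna_ng = 1,
                             check = TRUE) {
  if (assumed_rna_ng <= 0) stop2("RNA mass must be positive")
  if (check) {
    m <- fieldRnaMass(geometry)
    if (assumed_rna_ng < m$rna_ng_low || assumed_rna_ng > m$rna_ng_high)
      stop2("assumed_rna_ng %.3g outside the geometry range %.3g-%.3g (use check = FALSE to override)",
            assumed_rna_ng, m$rna_ng_low, m$rna_ng_high)
  }
  counts / assumed_rna_ng
}

#' Minutes between transcription initiations per active nucleus
#'
#' If an active nucleus holds \code{occupancy_per_nucleus} transcripts
#' carrying the 5' region at steady state, and each transcript carries
#' that region for \code{residence_time_h} hours, initiations occur every
#' residence_time * 60 / occupancy minutes. The residence time is an
#' explicit parameter: the full transcription time and the 5'-labelled
#' residence (~11 h for dp427) are both defensible readings.
#'
#' @param occupancy_per_nucleus nascent transcripts per nucleus (> 0).
#' @param residence_time_h time each transcript carries the probed region
#'   (> 0).
#' @return minutes between initiations.
#' @examples
#' initiationInterval(30, 11)  # 22 min
#' @export
initiationInterval <- function(occupancy_per_nucleus, residence_time_h) {
  if (any(occupancy_per_nucleus <= 0) || any(residence_time_h <= 0))
    stop2("occupancy and residence time must be positive")
  residence_time_h * 60 / occupancy_per_nucleus
}

#' Full steady-state kinetic estimate from a 5'/3' ratio
#'
#' Combines the steady-state relations into one record: mean lifetime,
#' half-life and nascent fraction from an observed 5'/3' abundance ratio
#' and the inter-region transcription time. Ratio inputs may come from
#' imaging counts per field or per-ng abundances; both funnel into the
#' same estimator.
#'
#' @param ratio_5p_3p observed 5'/3' ratio (> 1), or NULL to compute it
#'   from \code{counts_5p / counts_3p}.
#' @param gene a \linkS4class{GeneModel}.
#' @param separation which entry of the gene's \code{separation_bp} to
#'   use (default "ish"); ignored when \code{t_transcript_h} is given.
#' @param t_transcript_h explicit inter-region transcription time,
#'   overriding the gene-model value.
#' @param counts_5p,counts_3p optional abundances used when
#'   \code{ratio_5p_3p} is NULL (means are taken if vectors).
#' @return a \linkS4class{KineticEstimate}.
#' @examples
#' estimateKinetics(counts_5p = 2500, counts_3p = 780)
#' @export
estimateKinetics <- function(ratio_5p_3p = NULL, gene = geneModel(),
                             separation = "ish", t_transcript_h = NULL,
                             counts_5p = NULL, counts_3p = NULL) {
  if (is.null(ratio_5p_3p)) {
    if (is.null(counts_5p) || is.null(counts_3p))
      stop2("supply either ratio_5p_3p or counts_5p and counts_3p")
    ratio_5p_3p <- mean(counts_5p) / mean(counts_3p)
  }
  if (is.null(t_transcript_h)) {
    if (!separation %in% names(gene@separation_bp))
      stop2("unknown separation '%s'", separation)
    t_transcript_h <-
      transcriptionTimeBetween(gene, gene@separation_bp[[separation]])
  }
  life <- meanLifetimeFromRatio(ratio_5p_3p, t_transcript_h)
  new("KineticEstimate", ratio_5p_3p = ratio_5p_3p,
      t_transcript_h = t_transcript_h, mean_lifetime_h = life,
      half_life_h = halfLife(life),
      nascent_fraction = nascentFraction(ratio_5p_3p))
}

setMethod("show", "KineticEstimate", function(object) {
  cat("KineticEstimate (steady-state 5'/3' model)\n")
  cat(sprintf("  5'/3' ratio          : %.3f\n", object@ratio_5p_3p))
  cat(sprintf("  transcription time   : %.2f h (inter-region)\n",
              object@t_transcript_h))
  cat(sprintf("  mean lifetime        : %.2f h\n", object@mean_lifetime_h))
  cat(sprintf("  half-life            : %.2f h\n", object@half_life_h))
  cat(sprintf("  nascent fraction     : %.2f\n", object@nascent_fraction))
})
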