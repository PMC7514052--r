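#' Flag saturation in an ROI exposure series
#'
#' Fits a through-origin line to the two lowest exposures and compares
#' the highest-exposure observation with its linear prediction: if it
#' falls below \code{(1 - tolerance)} times the prediction the ROI is
#' flagged "saturated", otherwise "linear". Only non-saturated exposures
#' are eligible for quantification.
#'
#' @param exposures_ms strictly increasing exposure times, length >= 3.
#' @param intensities mean ROI intensity at each exposure.
#' @param tolerance fractional shortfall tolerated before flagging
#'   (default 0.2).
#' @return list: \code{flag} ("linear" or "saturated"), \code{slope} (AU
#'   per ms, through origin, from the two lowest exposures),
#'   \code{usable_ms} (exposures whose observation is within tolerance of
#'   the linear prediction).
#' @export
checkLinearity <- function(exposures_ms, intensities, tolerance = 0.2) {
  if (length(exposures_ms) < 3L)
    stop2("need at least 3 exposures to assess linearity")
  stopifnot(length(intensities) == length(exposures_ms),
            all(diff(exposures_ms) > 0), all(intensities >= 0))
  lo <- order(exposures_ms)[1:2]
  slope <- sum(intensities[lo] * exposures_ms[lo]) /
    sum(exposures_ms[lo]^2)
  pred <- slope * exposures_ms
  ok <- intensities >= (1 - tolerance) * pred
  hi <- which.max(exposures_ms)
  list(flag = if (ok[hi]) "linear" else "saturated",
       slope = slope,
       usable_ms = exposures_ms[ok])
}

#' Sample size for a mean at given precision and confidence
#'
#' Normal-approximation sample size n = ceil((z * sd / (precision *
#' mean))^2), i.e. n = (z * CV / E)^2 with E the relative precision. For
#' the single-transcript intensity distributions observed in healthy
#' muscle (means 6-8 AU, SD ~3) this gives 70-80 foci for +/-10%
#' precision at 95% confidence.
#'
#' @param mean observed mean (> 0).
#' @param sd observed standard deviation (>= 0).
#' @param precision relative half-width of the confidence interval.
#' @param confidence confidence level (two-sided).
#' @return required sample size (integer >= 1).
#' @examples
#' requiredSampleSize(6.0, 2.7)  # 78
#' @export
requiredSampleSize <- function(mean, sd, precision = 0.10,
                               confidence = 0.95) {
  if (mean <= 0) stop2("mean must be positive")
  stopifnot(sd >= 0, precision > 0, confidence > 0, confidence < 1)
  z <- qnorm(1 - (1 - confidence) / 2)
  max(1L, as.integer(ceiling((z * sd / (precision * mean))^2)))
}

#' Calibrate single-transcript unit intensity from small foci
#'
#' Small sarcoplasmic foci represent single transcripts; their
#' background-subtracted integrated intensities calibrate the
#' fluorescence scale. Returns the mean +/- SD together with the sample
#' size required for +/-10% precision at 95% confidence.
#'
#' @param small_foci_au integrated intensities of small sarcoplasmic
#'   foci (>= 2 values, from non-saturated exposures).
#' @param background_au background ROI intensities at the matched
#'   exposure (their mean is subtracted); default 0 for inputs that are
#'   already background-subtracted.
#' @param exposures_used_ms exposures the values came from (metadata).
#' @param saturated logical vector flagging saturated inputs; any TRUE is
#'   an error.
#' @return a \linkS4class{CalibrationResult}.
#' @export
calibrateUnitIntensity <- function(small_foci_au, background_au = 0,
                                   exposures_used_ms = numeric(),
                                   saturated = FALSE) {
  if (any(saturated)) stop2("saturated inputs are not usable for calibration")
  if (length(small_foci_au) < 2L)
    stop2("need at least 2 small foci to calibrate")
  net <- small_foci_au - mean(background_au)
  m <- mean(net); s <- sd(net)
  if (m <= 0) stop2("background-subtracted mean is not positive")
  new("CalibrationResult",
      unit_intensity_mean_au = m, unit_intensity_sd_au = s,
      n_foci = length(net), exposures_used_ms = exposures_used_ms,
      adequacy_n_required = requiredSampleSize(m, s))
}

#' @rdname CalibrationResult
#' @param object a \linkS4class{CalibrationResult}.
#' @export
setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult: unit intensity %.2f +/- %.2f AU (n = %d foci)\n",
              object@unit_intensity_mean_au, object@unit_intensity_sd_au,
              object@n_foci))
  cat(sprintf("  adequacy: %d foci required for +/-10%% at 95%%; %s\n",
              object@adequacy_n_required,
              if (object@n_foci >= object@adequacy_n_required)
                "sample adequate" else "sample NOT adequate"))
})

#' Estimate nascent transcripts in a large nuclear focus
#'
#' Divides the background-subtracted integrated intensity of a large
#' nuclear 5' focus by the calibrated single-transcript unit intensity.
#' The continuous estimate is reported alongside the nearest integer;
#' downstream totals should use the continuous value to avoid rounding
#' bias.
#'
#' @param intensity_au integrated intensity (AU) of the large focus
#'   (vectorised).
#' @param calibration a \linkS4class{CalibrationResult} (for dystrophic
#'   samples, a healthy-muscle reference calibration is typically
#'   supplied, small foci being too scarce there).
#' @return data.frame with intensity_au, count (continuous) and
#'   count_rounded.
#' @examples
#' cal <- calibrateUnitIntensity(c(5, 6, 7))
#' estimateNascentCount(240, cal)  # 40 transcripts
#' @export
estimateNascentCount <- function(intensity_au, calibration) {
  stopifnot(is(calibration, "CalibrationResult"),
            all(intensity_au >= 0))
  m <- calibration@unit_intensity_mean_au
  if (m <= 0) stop2("calibration mean must be positive")
  cnt <- intensity_au / m
  data.frame(intensity_au = intensity_au, count = cnt,
             count_rounded = round(cnt))
}
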