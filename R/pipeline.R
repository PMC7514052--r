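#' Analyse one field end to end
#'
#' Segments nuclei, detects foci per channel with and without compartment
#' masking, and (optionally) computes the sarcoplasmic 5'/3'
#' nearest-neighbour pairing fraction. This is the per-field worker that
#' \code{\link{runPipeline}} maps over a cohort; it accepts either a
#' synthetic field from \code{\link{generateField}} or images read from
#' disk via \code{\link{readField}}.
#'
#' @param images named list of channel matrices (\code{nuclear},
#'   \code{p5}, \code{p3}).
#' @param geometry a \linkS4class{FieldGeometry}.
#' @param nuclear_algorithm threshold algorithm for the nuclear stain.
#' @param threshold probe-channel threshold policy (see
#'   \code{\link{detectFoci}}).
#' @param coloc compute the nearest-neighbour pairing summary on
#'   sarcoplasmic small foci.
#' @param nn_threshold_um pairing radius reported in the metrics.
#' @return list: \code{mask} (NuclearMask), \code{summary}
#'   (FieldSummary), \code{foci} (per-channel detection tables),
#'   \code{nn} (pooled \linkS4class{NNResult} or NULL) and \code{metrics}
#'   (named numeric vector of per-field quantities).
#' @export
analyzeField <- function(images, geometry,
                         nuclear_algorithm = c("huang", "yen"),
                         threshold = "auto", coloc = TRUE,
                         nn_threshold_um = 1) {
  nuclear_algorithm <- match.arg(nuclear_algorithm)
  mask <- segmentNuclei(images$nuclear, geometry, nuclear_algorithm)
  cc <- compartmentCounts(images$p5, images$p3, mask, geometry,
                          threshold = threshold, detail = TRUE)
  summ <- cc$summary
  nn <- NULL
  frac_paired <- NA_real_
  if (coloc) {
    s5 <- cc$foci$`5p`$sarcoplasmic
    s3 <- cc$foci$`3p`$sarcoplasmic
    s5 <- s5[s5$size_class == "small", c("x_um", "y_um"), drop = FALSE]
    s3 <- s3[s3$size_class == "small", c("x_um", "y_um"), drop = FALSE]
    if (nrow(s5) > 0L && nrow(s3) > 0L) {
      nn <- poolNN(nearestNeighborDistances(s5, s3, "5p_to_3p"),
                   nearestNeighborDistances(s3, s5, "3p_to_5p"))
      frac_paired <- fractionWithin(nn, nn_threshold_um)
    }
  }
  metrics <- c(
    nuclei = summ@nuclei_count,
    small_5p_total = fieldCount(summ, "5p", "small", "total"),
    small_3p_total = fieldCount(summ, "3p", "small", "total"),
    large_5p_total = fieldCount(summ, "5p", "large", "total"),
    large_3p_total = fieldCount(summ, "3p", "large", "total"),
    small_5p_nuclear = fieldCount(summ, "5p", "small", "nuclear"),
    small_3p_nuclear = fieldCount(summ, "3p", "small", "nuclear"),
    small_5p_sarcoplasmic = fieldCount(summ, "5p", "small", "sarcoplasmic"),
    small_3p_sarcoplasmic = fieldCount(summ, "3p", "small", "sarcoplasmic"),
    large_5p_nuclear = fieldCount(summ, "5p", "large", "nuclear"),
    large_5p_sarcoplasmic = fieldCount(summ, "5p", "large", "sarcoplasmic"),
    fraction_expressing = summ@fraction_expressing_nuclei,
    frac_paired = frac_paired)
  list(mask = mask, summary = summ, foci = cc$foci, nn = nn,
       metrics = metrics)
}

# Scale the focus means of a SceneConfig by per-field/animal factors.
scale_config <- function(config, f_shared, f5, f3, seed, f_large = 1) {
  sceneConfig(geometry = config@geometry,
              n_nuclei = config@n_nuclei,
              nucleus_radius_um = config@nucleus_radius_um,
              n_pairs = config@n_pairs * f_shared,
              pair_offset_um = config@pair_offset_um,
              n_orphan_5p = config@n_orphan_5p * f_shared * f5,
              n_orphan_3p = config@n_orphan_3p * f_shared * f3,
              frac_small_in_nucleus = config@frac_small_in_nucleus,
              n_large_foci = config@n_large_foci * f_large,
              large_focus_area_um2_range = config@large_focus_area_um2_range,
              transcripts_per_large_focus = config@transcripts_per_large_focus,
              unit_intensity_au = config@unit_intensity_au,
              background_au = config@background_au,
              psf_sigma_um = config@psf_sigma_um,
              photons_per_au = config@photons_per_au,
              nuclear_stain_au = config@nuclear_stain_au,
              n_3p_only_nuclei = config@n_3p_only_nuclei,
              seed = seed)
}

#' Simulate and analyse a multi-genotype cohort
#'
#' Orchestrates the full pipeline over a simulated cohort: for each
#' genotype and animal, fields are generated from the genotype's scene
#' configuration with animal- and field-level biological variation
#' (multiplicative lognormal factors on the small-focus densities: a
#' factor shared by both channels plus per-channel factors), then each
#' field is analysed with \code{\link{analyzeField}}. Fully reproducible
#' from the configuration and seed.
#'
#' @param configs named list of \linkS4class{SceneConfig}, one per
#'   genotype (e.g. \code{list(WT = wtSceneConfig(), mdx =
#'   mdxSceneConfig())}); must be nonempty.
#' @param n_animals animals per genotype.
#' @param fields_per_animal images per animal.
#' @param seed master seed; all per-field seeds derive from it.
#' @param animal_cv CV of the per-animal small-focus density factor.
#' @param animal_cv_large CV of the per-animal large-focus (expressing
#'   nucleus) density factor; per-animal large means vary by ~15% in both
#'   genotypes.
#' @param field_cv_shared per-genotype named (or single) CV of the
#'   per-field factor shared by both channels.
#' @param field_cv_channel per-genotype named (or single) CV of the
#'   per-field per-channel factors.
#' @param coloc compute per-field pairing fractions.
#' @param ... further arguments to \code{\link{analyzeField}}.
#' @return data.frame (cohort table), one row per field: genotype,
#'   animal, field, seed and all per-field metrics.
#' @export
runPipeline <- function(configs, n_animals = 4L, fields_per_animal = 9L,
                        seed = 1L, animal_cv = 0.25,
                        animal_cv_large = 0.14,
                        field_cv_shared = c(WT = 0.3, mdx = 0.25),
                        field_cv_channel = c(WT = 0.05, mdx = 0.25),
                        coloc = TRUE, ...) {
  if (length(configs) == 0L) stop2("empty cohort: no scene configurations")
  if (is.null(names(configs)) || any(!nzchar(names(configs))))
    stop2("configs must be a named list (one entry per genotype)")
  stopifnot(n_animals >= 1L, fields_per_animal >= 1L)
  get_cv <- function(cvs, g) {
    if (length(cvs) == 1L && is.null(names(cvs))) return(cvs)
    if (g %in% names(cvs)) cvs[[g]] else mean(cvs)
  }
  ln_factor <- function(n, cv) {
    sdl <- sqrt(log(1 + rep_len(cv, n)^2))
    rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
  }
  rows <- list()
  k <- 0L
  for (g in names(configs)) {
    cfg <- configs[[g]]
    stopifnot(is(cfg, "SceneConfig"))
    cv_s <- get_cv(field_cv_shared, g)
    cv_c <- get_cv(field_cv_channel, g)
    for (a in seq_len(n_animals)) {
      k <- k + 1L
      aseed <- child_seed(seed, k * 1000L)
      afac <- with_seed(aseed, ln_factor(2L, c(animal_cv, animal_cv_large)))
      for (f in seq_len(fields_per_animal)) {
        fseed <- child_seed(aseed, f)
        facs <- with_seed(child_seed(fseed, 1L),
                          c(ln_factor(1L, cv_s), ln_factor(2L, cv_c)))
        fcfg <- scale_config(cfg, afac[1] * facs[1], facs[2], facs[3],
                             fseed, f_large = afac[2])
        field <- generateField(fcfg)
        res <- analyzeField(field$images, cfg@geometry, coloc = coloc, ...)
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = g, animal = sprintf("%s_%d", g, a), field = f,
          seed = fseed, t(res$metrics), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare two cohorts by Mann-Whitney U test on per-animal means
#'
#' Per-field values are first averaged per animal (tests on per-image
#' values would pseudo-replicate), then the two groups of per-animal
#' means are compared with a two-tailed Mann-Whitney U (Wilcoxon
#' rank-sum) test.
#'
#' @param cohort cohort table from \code{\link{runPipeline}}.
#' @param metric column to compare.
#' @param groups length-2 character vector of genotype labels.
#' @return list: \code{p_value}, \code{statistic} (U), and
#'   \code{group_means} (named per-animal means by group).
#' @export
compareCohorts <- function(cohort, metric, groups) {
  stopifnot(length(groups) == 2L, metric %in% names(cohort))
  per_animal <- function(g) {
    d <- cohort[cohort$genotype == g, , drop = FALSE]
    if (nrow(d) == 0L) stop2("no fields for group '%s'", g)
    tapply(d[[metric]], d$animal, mean, na.rm = TRUE)
  }
  x <- per_animal(groups[1]); y <- per_animal(groups[2])
  if (length(x) < 3L || length(y) < 3L)
    stop2("need >= 3 animals per group (have %d and %d)",
          length(x), length(y))
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       group_means = setNames(list(x, y), groups))
}

#' Per-animal correlation between two per-field metrics
#'
#' Pearson or Spearman correlation of two per-field metrics, computed
#' within each animal (e.g. small 5' vs 3' counts per image).
#'
#' @param cohort cohort table from \code{\link{runPipeline}}.
#' @param x_metric,y_metric columns to correlate.
#' @param method "pearson" or "spearman".
#' @return data.frame: animal, genotype, n, estimate, p_value.
#' @export
correlateMetrics <- function(cohort, x_metric, y_metric,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(x_metric %in% names(cohort), y_metric %in% names(cohort))
  out <- lapply(split(cohort, cohort$animal), function(d) {
    x <- d[[x_metric]]; y <- d[[y_metric]]
    if (length(x) < 3L) stop2("need >= 3 paired observations per animal")
    if (sd(x) == 0 || sd(y) == 0)
      stop2("constant input: cannot correlate '%s' vs '%s'",
            x_metric, y_metric)
    ct <- suppressWarnings(cor.test(x, y, method = method))
    data.frame(animal = d$animal[1], genotype = d$genotype[1],
               n = length(x), estimate = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
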