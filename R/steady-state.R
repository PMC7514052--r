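# Poisson count draw that stays safe for very large means.
rcount <- function(n, lambda) {
  big <- lambda > 1e7
  out <- numeric(length(lambda) * n)
  lam <- rep(lambda, length.out = length(out))
  out[!big] <- rpois(sum(!big), lam[!big])
  if (any(big))
    out[big] <- round(rnorm(sum(big), lam[big], sqrt(lam[big])))
  pmax(out, 0)
}

#' Simulate steady-state probe-region transcript counts
#'
#' Simulates the transcript census a qPCR or imaging experiment would
#' sample at transcriptional steady state. Each active nucleus initiates
#' a transcript every \code{initiation_interval_min} minutes; a
#' transcript carries the 5' region for the inter-region transcription
#' time plus the mature lifetime, carries an intermediate region for a
#' fraction of that transcription time, and carries the 3' region (which
#' lies just before termination) only once mature. Region totals are
#' Poisson draws around these steady-state means, aggregated over nuclei,
#' with optional multiplicative lognormal noise of the given CV per
#' replicate and region. The expected 5'/3' ratio equals
#' (T_transcript + T_lifetime) / T_lifetime exactly.
#'
#' @param gene a \linkS4class{GeneModel}; supplies the inter-region time
#'   unless \code{t_transcript_h} is given.
#' @param lifetime_h mature-transcript mean lifetime (> 0).
#' @param initiation_interval_min minutes between initiations per nucleus
#'   (> 0).
#' @param n_nuclei active nuclei aggregated per replicate.
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal noise (0 disables it).
#' @param seed integer seed.
#' @param n_replicates replicates (e.g. animals) to simulate.
#' @param t_transcript_h explicit inter-region transcription time (h).
#' @param mid_fraction position of the intermediate region as a fraction
#'   of the way from the 5' to the 3' region.
#' @param assumed_rna_ng RNA mass each replicate represents; counts are
#'   also reported per ng.
#' @return data.frame with replicate, region ("5p", "mid", "3p"), counts
#'   and counts_per_ng. Positional expectations are non-increasing from
#'   5' to 3'.
#' @examples
#' tab <- generateSteadyStateCounts(lifetime_h = 5, t_transcript_h = 11,
#'   noise_cv = 0, n_nuclei = 2000, seed = 1)
#' sum(tab$counts[tab$region == "5p"]) / sum(tab$counts[tab$region == "3p"])
#' @export
generateSteadyStateCounts <- function(gene = geneModel(), lifetime_h,
                                      initiation_interval_min = 25,
                                      n_nuclei = 1000, noise_cv = 0.1,
                                      seed = 1L, n_replicates = 1L,
                                      t_transcript_h = NULL,
                                      mid_fraction = 0.5,
                                      assumed_rna_ng = 1) {
  if (lifetime_h <= 0) stop2("lifetime_h must be positive")
  if (initiation_interval_min <= 0)
    stop2("initiation_interval_min must be positive")
  stopifnot(n_nuclei >= 1, noise_cv >= 0, mid_fraction >= 0,
            mid_fraction <= 1, assumed_rna_ng > 0)
  if (is.null(t_transcript_h))
    t_transcript_h <- transcriptionTimeBetween(gene,
                                               gene@separation_bp[["ish"]])
  rate_per_h <- 60 / initiation_interval_min      # initiations/nucleus/h
  mu_mature <- n_nuclei * rate_per_h * lifetime_h
  mu_n5 <- n_nuclei * rate_per_h * t_transcript_h
  mu_nmid <- n_nuclei * rate_per_h * (1 - mid_fraction) * t_transcript_h
  mu <- c(`5p` = mu_mature + mu_n5, mid = mu_mature + mu_nmid,
          `3p` = mu_mature)
  sdlog <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    out <- lapply(seq_len(n_replicates), function(rep) {
      fac <- if (noise_cv > 0)
        rlnorm(3L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      else rep(1, 3L)
      cnt <- rcount(1L, mu * fac)
      data.frame(replicate = rep, region = names(mu), counts = cnt,
                 counts_per_ng = cnt / assumed_rna_ng,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Observed 5'/3' ratio from a steady-state count table
#'
#' @param counts data.frame as returned by
#'   \code{\link{generateSteadyStateCounts}} (or with columns region and
#'   counts).
#' @return ratio of mean 5' counts to mean 3' counts.
#' @export
ratioFromCounts <- function(counts) {
  c5 <- counts$counts[counts$region == "5p"]
  c3 <- counts$counts[counts$region == "3p"]
  if (!length(c5) || !length(c3)) stop2("counts must contain 5p and 3p rows")
  mean(c5) / mean(c3)
}
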