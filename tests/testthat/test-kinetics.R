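test_that("transcription times scale linearly with genomic distance", {
  g <- geneModel()
  expect_equal(transcriptionTimeBetween(g, 0), 0)
  expect_equal(transcriptionTimeBetween(g, 1.55e6), 1.55 / 2.3 * 16)
  expect_equal(transcriptionTimeBetween(g, 1.55e6), 10.78, tolerance = 0.01)
  expect_equal(transcriptionTimeBetween(g, 1.95e6), 13.57, tolerance = 0.01)
  expect_error(transcriptionTimeBetween(g, -1))
  expect_error(transcriptionTimeBetween(g, 3e6))
  ## the default model implies ~40 bases per second
  expect_equal(elongationRateBpSec(g), 40, tolerance = 0.05 * 40)
})

test_that("gene model rejects regions outside the gene", {
  expect_error(geneModel(regions = data.frame(
    name = "x", start_bp = -1, end_bp = 10)))
  expect_error(geneModel(separation_bp = c(ish = 5e6)))
})

test_that("mean lifetime inverts the steady-state ratio relation", {
  expect_equal(meanLifetimeFromRatio(2, 11), 11)
  expect_equal(meanLifetimeFromRatio(2500 / 780, 11), 4.988, tolerance = 1e-3)
  expect_equal(halfLife(meanLifetimeFromRatio(2500 / 780, 11)), 3.457,
               tolerance = 1e-3)
  expect_error(meanLifetimeFromRatio(1, 11))
  expect_error(meanLifetimeFromRatio(0.5, 11))
  expect_error(meanLifetimeFromRatio(2, 0))
  ## strictly decreasing in ratio, linear in transcription time
  r <- seq(1.2, 6, by = 0.4)
  expect_true(all(diff(meanLifetimeFromRatio(r, 11)) < 0))
  expect_equal(meanLifetimeFromRatio(2.5, 22),
               2 * meanLifetimeFromRatio(2.5, 11))
})

test_that("half-life and mean lifetime interconvert with 0.693", {
  expect_equal(halfLife(1), 0.693)
  expect_equal(halfLife(4.99), 3.458, tolerance = 1e-3)
  x <- c(0.3, 1, 4.99, 16)
  expect_equal(halfLife(meanLifetimeFromHalfLife(x)), x)
  expect_error(halfLife(0))
  expect_error(meanLifetimeFromHalfLife(-2))
})

test_that("ratio round-trips through lifetime to machine precision", {
  for (Tt in c(5, 10.78, 13.57)) for (L in c(1, 5, 20)) {
    ratio <- (Tt + L) / L
    expect_equal(meanLifetimeFromRatio(ratio, Tt), L)
    ## nascent fraction consistency: f = T/(T+L)
    expect_equal(nascentFraction(ratio), Tt / (Tt + L))
  }
})

test_that("nascent fractions from ratios and counts agree", {
  expect_equal(nascentFraction(2), 0.5)
  expect_equal(nascentFraction(4), 0.75)
  expect_error(nascentFraction(1))
  expect_equal(nascentFractionFromCounts(30, 10), 0.75)
  expect_equal(nascentFractionFromCounts(5, 0), 1)
  expect_error(nascentFractionFromCounts(0, 0))
})

test_that("per-field counts normalise to transcripts per ng", {
  geom <- fieldGeometry()
  expect_equal(transcriptsPerNg(1000, geom, 1), 1000)
  expect_equal(transcriptsPerNg(1000, geom, 0.8), 1250)
  expect_error(transcriptsPerNg(1000, geom, 3))     # outside 0.75-1.5 ng
  expect_equal(transcriptsPerNg(1000, geom, 3, check = FALSE), 1000 / 3)
  expect_error(transcriptsPerNg(1000, geom, 0))
})

test_that("initiation intervals follow occupancy and residence time", {
  expect_equal(initiationInterval(1, 1), 60)
  expect_equal(initiationInterval(30, 11), 22)
  expect_equal(initiationInterval(11, 11), 60)
  expect_error(initiationInterval(0, 1))
  expect_error(initiationInterval(1, -1))
})

test_that("estimateKinetics combines the relations end to end", {
  est <- estimateKinetics(counts_5p = 2500, counts_3p = 780)
  tt <- 1.55 / 2.3 * 16
  expect_equal(est@t_transcript_h, tt)
  expect_equal(est@mean_lifetime_h, tt / (2500 / 780 - 1))
  expect_equal(est@half_life_h, 0.693 * tt / (2500 / 780 - 1))
  expect_equal(est@nascent_fraction, 1 - 780 / 2500)
  expect_output(show(est), "half-life")
  est2 <- estimateKinetics(ratio_5p_3p = 2, t_transcript_h = 11)
  expect_equal(est2@mean_lifetime_h, 11)
  expect_error(estimateKinetics())
  expect_error(estimateKinetics(counts_5p = 2500, counts_3p = 780,
                                separation = "nope"))
})

test_that("steady-state counts reproduce the closed-form ratio", {
  ## lifetime 5 h against an 11 h inter-region time: ratio 3.2
  tab <- generateSteadyStateCounts(lifetime_h = 5, t_transcript_h = 11,
                                   initiation_interval_min = 25,
                                   n_nuclei = 3000, noise_cv = 0,
                                   seed = 2)
  expect_equal(ratioFromCounts(tab), 3.2, tolerance = 0.02)
  ## positional counts are non-increasing from 5' to 3'
  expect_true(tab$counts[tab$region == "5p"] >=
                tab$counts[tab$region == "mid"])
  expect_true(tab$counts[tab$region == "mid"] >=
                tab$counts[tab$region == "3p"])

  ## no decay: the ratio collapses to 1
  tab_inf <- generateSteadyStateCounts(lifetime_h = 1e5,
                                       t_transcript_h = 11,
                                       n_nuclei = 500, noise_cv = 0,
                                       seed = 3)
  expect_equal(ratioFromCounts(tab_inf), 1, tolerance = 0.02)

  ## equal times: nascent equals mature, ratio 2
  tab2 <- generateSteadyStateCounts(lifetime_h = 11, t_transcript_h = 11,
                                    n_nuclei = 3000, noise_cv = 0,
                                    seed = 4)
  expect_equal(ratioFromCounts(tab2), 2, tolerance = 0.02)

  expect_error(generateSteadyStateCounts(lifetime_h = 0))
  expect_error(generateSteadyStateCounts(lifetime_h = 5,
                                         initiation_interval_min = 0))
})

test_that("steady-state tables are reproducible and noise follows the CV", {
  t1 <- generateSteadyStateCounts(lifetime_h = 5, t_transcript_h = 11,
                                  noise_cv = 0.1, seed = 11,
                                  n_replicates = 4)
  t2 <- generateSteadyStateCounts(lifetime_h = 5, t_transcript_h = 11,
                                  noise_cv = 0.1, seed = 11,
                                  n_replicates = 4)
  expect_identical(t1, t2)
  ## replicate-to-replicate spread reflects the configured CV
  c5 <- t1$counts[t1$region == "5p"]
  expect_gt(sd(c5) / mean(c5), 0.01)
})
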