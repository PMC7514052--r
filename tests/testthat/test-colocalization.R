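test_that("nearest-neighbour distances are Euclidean per source focus", {
  pts <- cbind(c(0, 3, 10), c(0, 4, 10))
  nn <- nearestNeighborDistances(pts, pts)
  expect_equal(nnDistances(nn), c(0, 0, 0))
  nn2 <- nearestNeighborDistances(cbind(0, 0), cbind(3, 4))
  expect_equal(nnDistances(nn2), 5)
  expect_length(nnDistances(nearestNeighborDistances(pts, cbind(1, 1))), 3)
  expect_error(nearestNeighborDistances(pts, pts[0, , drop = FALSE]))
})

test_that("fractionWithin is a CDF in the radius", {
  nn <- new("NNResult", direction = "pooled",
            distances_um = c(0.2, 0.9, 1, 3, 12, 40))
  r <- c(0.5, 1, 2, 5, 30, 100)
  fw <- fractionWithin(nn, r)
  expect_true(all(diff(fw) >= 0))
  expect_true(all(fw >= 0 & fw <= 1))
  expect_equal(fractionWithin(nn, Inf), 1)
  expect_equal(fractionWithin(nn, 1), 0.5)  # within is inclusive
  expect_equal(fractionBeyond(nn, r), 1 - fw)
})

test_that("rotation null fixes the centre and is 4-periodic", {
  geom <- fieldGeometry()
  ctr <- matrix(unname(fieldDimUm(geom)) / 2, 1)
  expect_equal(rotationNull(ctr, geom), ctr)
  set.seed(3)
  xy <- cbind(runif(50, 0, 694), runif(50, 0, 520))
  r4 <- rotationNull(rotationNull(rotationNull(rotationNull(xy, geom),
                                               geom), geom), geom)
  expect_equal(r4, xy)
  expect_identical(nrow(rotationNull(xy, geom)), 50L)
  ## all rotated points stay in-field
  r1 <- rotationNull(xy, geom)
  expect_true(all(r1[, 1] >= 0 & r1[, 1] <= 694))
  expect_true(all(r1[, 2] >= 0 & r1[, 2] <= 520))
  expect_error(rotationNull(cbind(-5, 10), geom))
})

test_that("rotation preserves the inter-point distance multiset on a square field", {
  geom <- fieldGeometry(width_px = 500L, height_px = 500L)
  set.seed(4)
  xy <- cbind(runif(30, 0, 250), runif(30, 0, 250))
  rot <- rotationNull(xy, geom)
  expect_equal(sort(dist(xy)), sort(dist(rot)))
})

test_that("toroidal random null matches the Poisson closed form", {
  geom <- fieldGeometry()
  lam <- 200 / areaUm2(geom)
  rn <- randomNull(200, 200, geom, n_fields = 150L, seed = 5L,
                   boundary = "toroidal")
  d <- nnDistances(rn)
  per_field <- matrix(d > 10, nrow = 400)  # 2n distances per field
  fracs <- colMeans(per_field)
  expected <- exp(-lam * pi * 100)
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - expected), 3 * se)
})

test_that("bounded-field edge effects lengthen nearest-neighbour distances", {
  geom <- fieldGeometry()
  bounded <- randomNull(400, 400, geom, n_fields = 150L, seed = 6L)
  torus <- randomNull(400, 400, geom, n_fields = 150L, seed = 6L,
                      boundary = "toroidal")
  expect_gt(fractionBeyond(bounded, 30), fractionBeyond(torus, 30))
})

test_that("dense target sets drive all neighbour distances to zero", {
  set.seed(8)
  src <- cbind(runif(50, 0, 50), runif(50, 0, 50))
  tgt <- cbind(runif(20000, 0, 50), runif(20000, 0, 50))
  nn <- nearestNeighborDistances(src, tgt)
  expect_gt(fractionWithin(nn, 1), 0.99)
})

test_that("paired planted foci are recovered as sub-micron neighbours", {
  ## healthy-muscle field: ~40% of sarcoplasmic foci planted as pairs
  cfg <- wtSceneConfig(seed = 29)
  f <- generateField(cfg)
  geom <- cfg@geometry
  mask <- segmentNuclei(f$images$nuclear, geom)
  cc <- compartmentCounts(f$images$p5, f$images$p3, mask, geom,
                          detail = TRUE)
  s5 <- cc$foci$`5p`$sarcoplasmic
  s3 <- cc$foci$`3p`$sarcoplasmic
  s5 <- as.matrix(s5[s5$size_class == "small", c("x_um", "y_um")])
  s3 <- as.matrix(s3[s3$size_class == "small", c("x_um", "y_um")])
  obs <- poolNN(nearestNeighborDistances(s5, s3, "5p_to_3p"),
                nearestNeighborDistances(s3, s5, "3p_to_5p"))
  expect_equal(fractionWithin(obs, 1), 0.40, tolerance = 0.12)

  ## rotating the 3' channel destroys pairing down to the random level
  rot <- poolNN(nearestNeighborDistances(s5, rotationNull(s3, geom)),
                nearestNeighborDistances(rotationNull(s3, geom), s5))
  rand <- randomNull(nrow(s5), nrow(s3), geom, n_fields = 50L, seed = 9L)
  expect_lt(fractionWithin(rot, 1), 0.05)
  expect_lt(abs(fractionWithin(rot, 1) - fractionWithin(rand, 1)), 0.02)

  summ <- pairingSummary(obs, list(rotation = rot, random = rand))
  ex1 <- summ$excess_within[summ$model == "random" &
                              summ$threshold_um == 1]
  expect_gt(ex1, 0.25)
})

test_that("unpaired sparse fields look like the matched random null", {
  ## dystrophic-like sarcoplasm: ~100 foci per channel, no pairing
  cfg <- wtSceneConfig(seed = 51, n_pairs = 0, n_orphan_5p = 100,
                       n_orphan_3p = 100, frac_small_in_nucleus = 0,
                       n_large_foci = 0, n_nuclei = 0)
  f <- generateField(cfg)
  geom <- cfg@geometry
  d5 <- detectFoci(f$images$p5, geom)
  d3 <- detectFoci(f$images$p3, geom, channel = "3p")
  s5 <- as.matrix(d5[d5$size_class == "small", c("x_um", "y_um")])
  s3 <- as.matrix(d3[d3$size_class == "small", c("x_um", "y_um")])
  obs <- poolNN(nearestNeighborDistances(s5, s3),
                nearestNeighborDistances(s3, s5))
  rand <- randomNull(nrow(s5), nrow(s3), geom, n_fields = 100L,
                     seed = 10L)
  expect_lt(abs(fractionBeyond(obs, 30) - fractionBeyond(rand, 30)), 0.1)
  summ <- pairingSummary(obs, list(random = rand))
  expect_lt(max(abs(summ$excess_within), na.rm = TRUE), 0.1)
})
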