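# synthetic nuclear-stain image of soft disks on a dim background
disk_image <- function(centers, radius, nr = 120L, nc = 160L,
                       amp = 5, bg = 0.2) {
  img <- matrix(bg, nr, nc)
  rr <- row(img); cc <- col(img)
  for (k in seq_len(nrow(centers))) {
    d <- sqrt((rr - centers[k, 2])^2 + (cc - centers[k, 1])^2)
    img <- img + amp / (1 + exp((d - radius) / 0.6))
  }
  img
}

test_that("nuclear segmentation counts disjoint and touching nuclei", {
  geom <- fieldGeometry(width_px = 160L, height_px = 120L)
  expect_equal(nucleusCount(segmentNuclei(matrix(0.2, 120, 160), geom)), 0)

  two <- disk_image(rbind(c(40, 60), c(120, 60)), radius = 14)
  for (alg in c("huang", "yen"))
    expect_equal(nucleusCount(segmentNuclei(two, geom, alg)), 2)

  ## centres 20 px apart at radius 14: overlap less than one radius,
  ## resolvable only by the watershed pass
  touching <- disk_image(rbind(c(70, 60), c(90, 60)), radius = 14)
  expect_equal(nucleusCount(segmentNuclei(touching, geom, "huang")), 2)
  expect_equal(nucleusCount(segmentNuclei(touching, geom, "huang",
                                          watershed_pass = FALSE)), 1)
})

test_that("nucleus counts on synthetic fields match planted numbers", {
  f <- generateField(small_scene(seed = 13, n_nuclei = 30))
  mask <- segmentNuclei(f$images$nuclear, small_geom())
  planted <- nrow(f$nuclei)
  expect_lte(abs(nucleusCount(mask) - planted), max(1, 0.05 * planted))
})

test_that("size classification uses half-open 0.5/10/100 bins", {
  expect_identical(classifyBySize(c(1.5, 50, 0.4, 10, 0.5, 100, 101)),
                   c("small", "large", "rejected", "large", "small",
                     "large", "rejected"))
})

test_that("a blank probe channel yields no foci", {
  geom <- fieldGeometry(width_px = 160L, height_px = 120L)
  d <- detectFoci(matrix(1, 120, 160), geom)
  expect_identical(nrow(d), 0L)
  expect_error(detectFoci(matrix(c(1, Inf), 120, 160), geom))
})

test_that("detection is exact on noise-free fields with isolated spots", {
  cfg <- noisefree(small_scene(seed = 32, n_nuclei = 0, n_pairs = 0,
                               n_orphan_5p = 30, n_orphan_3p = 0,
                               n_large_foci = 0,
                               frac_small_in_nucleus = 0))
  f <- generateField(cfg)
  tr <- f$truth[f$truth$channel == "5p", ]
  ## isolated: no two planted spots closer than 3 um
  nn <- nn_dists_same(tr)
  expect_gt(min(nn), 3)
  det <- detectFoci(f$images$p5, small_geom())
  expect_identical(nrow(det), nrow(tr))
  ## at a background-level threshold the component is the whole rendered
  ## patch; border clipping can shift its unweighted centroid, so the
  ## match radius tests identity, not sub-pixel localisation
  m <- match_foci(as.matrix(tr[, c("x_um", "y_um")]),
                  as.matrix(det[, c("x_um", "y_um")]), tol_um = 2)
  expect_identical(m$tp, nrow(tr))  # precision = recall = 1
  expect_identical(m$fp, 0L)
})

test_that("detection at default noise recovers nearly all planted spots", {
  f <- generateField(small_scene(seed = 17, n_nuclei = 0, n_pairs = 0,
                                 n_orphan_5p = 100, n_orphan_3p = 0,
                                 n_large_foci = 0,
                                 frac_small_in_nucleus = 0))
  pr <- small_focus_pr(f, small_geom())
  f1 <- 2 * pr$precision * pr$recall / (pr$precision + pr$recall)
  expect_gte(f1, 0.95)
  expect_gte(pr$recall, 0.95)
})

test_that("recovered per-field means match the configured census within 10%", {
  ## healthy-muscle configuration; per-field 5' small mean 585, 3' 714
  cfg <- wtSceneConfig(seed = 19)
  f <- generateField(cfg)
  geom <- cfg@geometry
  d5 <- detectFoci(f$images$p5, geom, channel = "5p")
  d3 <- detectFoci(f$images$p3, geom, channel = "3p")
  expect_lt(abs(sum(d5$size_class == "small") - 585) / 585, 0.10)
  expect_lt(abs(sum(d3$size_class == "small") - 714) / 714, 0.10)
  expect_lt(abs(sum(d5$size_class == "large") - 80) / 80, 0.25)
})

test_that("measured intensities are background-subtracted spot integrals", {
  ## isolated 10-AU spots on flat background, noise-free
  cfg <- noisefree(small_scene(seed = 1, n_nuclei = 0, n_pairs = 0,
                               n_orphan_5p = 5, n_orphan_3p = 0,
                               n_large_foci = 0,
                               frac_small_in_nucleus = 0,
                               unit_intensity_au = c(10, 0)))
  f <- generateField(cfg)
  det <- detectFoci(f$images$p5, small_geom(), threshold = 1.3)
  expect_identical(nrow(det), nrow(f$truth))
  expect_equal(det$integrated_intensity_au, rep(10, nrow(det)),
               tolerance = 0.05)
})

test_that("size distributions are normalised over non-rejected foci", {
  foci <- data.frame(area_um2 = rep(1, 7), size_class = "small")
  d <- sizeDistribution(foci, bin_edges = c(0.5, 2, 10))
  expect_equal(d$fraction, c(1, 0))
  expect_error(sizeDistribution(foci[0, ]))

  f <- generateField(small_scene(seed = 23))
  det <- detectFoci(f$images$p3, small_geom(), channel = "3p")
  d2 <- sizeDistribution(det)
  expect_equal(sum(d2$fraction), 1)
  ## the 3' channel is essentially devoid of large foci
  large_bins <- d2$bin_low >= 10
  expect_lt(sum(d2$fraction[large_bins]), 0.03)
})
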