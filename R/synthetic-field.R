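#' Construct a SceneConfig
#'
#' Parameters of one synthetic multiplex ISH field. Defaults emulate a
#' healthy (wild-type-like) muscle field: ~585 small 5' foci and ~714
#' small 3' foci per field of which ~40% belong to sub-micron 5'/3' pairs
#' (mature transcripts), ~80 large 5'-only nuclear foci of 20-40 nascent
#' transcripts each, ~300 nuclei, single-transcript integrated intensity
#' 6.0 +/- 2.7 AU, and large-focus apparent areas within 10-100 um^2.
#'
#' @param geometry a \linkS4class{FieldGeometry}.
#' @param n_nuclei expected nuclei per field (Poisson mean).
#' @param nucleus_radius_um c(mean, sd) nucleus radius in um.
#' @param n_pairs expected co-localized 5'+3' pairs (mature transcripts).
#' @param pair_offset_um maximum 5'-3' separation within a pair (um).
#' @param n_orphan_5p,n_orphan_3p expected unpaired small foci per channel.
#' @param frac_small_in_nucleus fraction of small foci placed inside
#'   nuclei.
#' @param n_large_foci expected large 5'-only nuclear foci.
#' @param large_focus_area_um2_range admissible large-focus area (um^2).
#' @param transcripts_per_large_focus c(min, max) ground-truth nascent
#'   transcript counts per large focus.
#' @param unit_intensity_au c(mean, sd) single-transcript integrated
#'   intensity in arbitrary linear units.
#' @param background_au c(mean, sd): background level and Gaussian read
#'   noise sd.
#' @param psf_sigma_um isotropic Gaussian spot sigma; the default 0.35 um
#'   puts thresholded apparent areas of single spots in the 1-3 um^2 mode.
#' @param photons_per_au photon scale for Poisson shot noise; \code{Inf}
#'   disables shot noise.
#' @param nuclear_stain_au nuclear stain amplitude above background.
#' @param n_3p_only_nuclei expected dp71-like nuclei with 3'-only small
#'   foci (default 0).
#' @param seed integer seed; equal seeds give bit-identical fields.
#' @return a \linkS4class{SceneConfig}.
#' @export
sceneConfig <- function(geometry = fieldGeometry(),
                        n_nuclei = 300,
                        nucleus_radius_um = c(4.0, 0.4),
                        n_pairs = 260,
                        pair_offset_um = 0.8,
                        n_orphan_5p = 325,
                        n_orphan_3p = 454,
                        frac_small_in_nucleus = 0.15,
                        n_large_foci = 80,
                        large_focus_area_um2_range = c(10, 100),
                        transcripts_per_large_focus = c(20, 40),
                        unit_intensity_au = c(6.0, 2.7),
                        background_au = c(1.0, 0.1),
                        psf_sigma_um = 0.35,
                        photons_per_au = 200,
                        nuclear_stain_au = 5,
                        n_3p_only_nuclei = 0,
                        seed = 1L) {
  new("SceneConfig",
      geometry = geometry,
      n_nuclei = n_nuclei,
      nucleus_radius_um = as.numeric(nucleus_radius_um),
      n_pairs = n_pairs,
      pair_offset_um = pair_offset_um,
      n_orphan_5p = n_orphan_5p,
      n_orphan_3p = n_orphan_3p,
      frac_small_in_nucleus = frac_small_in_nucleus,
      n_large_foci = n_large_foci,
      large_focus_area_um2_range = as.numeric(large_focus_area_um2_range),
      transcripts_per_large_focus = as.numeric(transcripts_per_large_focus),
      unit_intensity_au = as.numeric(unit_intensity_au),
      background_au = as.numeric(background_au),
      psf_sigma_um = psf_sigma_um,
      photons_per_au = photons_per_au,
      nuclear_stain_au = nuclear_stain_au,
      n_3p_only_nuclei = n_3p_only_nuclei,
      seed = as.integer(seed))
}

#' Preset scene configurations for healthy-like and dystrophic-like fields
#'
#' \code{wtSceneConfig} reproduces the per-field structure of healthy
#' muscle (abundant paired sarcoplasmic 5'/3' foci, ~80 large nuclear foci
#' of 20-40 transcripts among ~300 nuclei). \code{mdxSceneConfig}
#' reproduces dystrophic muscle: small sarcoplasmic foci depleted, small
#' nuclear foci preserved, more nuclei per field, and weaker large foci
#' (~6-20 nascent transcripts).
#'
#' @param seed integer seed.
#' @param ... further arguments overriding \code{\link{sceneConfig}}
#'   defaults.
#' @return a \linkS4class{SceneConfig}.
#' @rdname presets
#' @export
wtSceneConfig <- function(seed = 1L, ...) sceneConfig(seed = seed, ...)

#' @rdname presets
#' @export
mdxSceneConfig <- function(seed = 1L, ...) {
  sceneConfig(n_nuclei = 700, n_pairs = 15, n_orphan_5p = 131,
              n_orphan_3p = 111, frac_small_in_nucleus = 0.6,
              n_large_foci = 86, transcripts_per_large_focus = c(10, 20),
              seed = seed, ...)
}

# ---- internal helpers -------------------------------------------------

empty_truth <- function() {
  data.frame(kind = character(), channel = character(), x_um = numeric(),
             y_um = numeric(), area_um2 = numeric(), radius_um = numeric(),
             pair_id = integer(), compartment = character(),
             transcripts = numeric(), intensity_au = numeric(),
             stringsAsFactors = FALSE)
}

truth_row <- function(kind, channel = NA_character_, x = NA_real_,
                      y = NA_real_, area = NA_real_, radius = NA_real_,
                      pair = NA_integer_, compartment = NA_character_,
                      transcripts = NA_real_, intensity = NA_real_) {
  list(kind = kind, channel = channel, x_um = x, y_um = y,
       area_um2 = area, radius_um = radius, pair_id = pair,
       compartment = compartment, transcripts = transcripts,
       intensity_au = intensity)
}

bind_truth <- function(rows) {
  if (!length(rows)) return(empty_truth())
  pull <- function(fld, mode) {
    v <- vapply(rows, function(r) r[[fld]], mode)
    v
  }
  data.frame(kind = pull("kind", character(1)),
             channel = pull("channel", character(1)),
             x_um = pull("x_um", numeric(1)),
             y_um = pull("y_um", numeric(1)),
             area_um2 = pull("area_um2", numeric(1)),
             radius_um = pull("radius_um", numeric(1)),
             pair_id = pull("pair_id", integer(1)),
             compartment = pull("compartment", character(1)),
             transcripts = pull("transcripts", numeric(1)),
             intensity_au = pull("intensity_au", numeric(1)),
             stringsAsFactors = FALSE)
}

# Distance-based membership test against the planted nuclei.
in_any_nucleus <- function(x, y, nuc, margin = 0) {
  if (nrow(nuc) == 0L) return(FALSE)
  any((x - nuc$x_um)^2 + (y - nuc$y_um)^2 <= (nuc$radius_um + margin)^2)
}

# Place nuclei with bounded retries; error when the field is too crowded.
place_nuclei <- function(n, dims, r_mean, r_sd, max_tries = 200L) {
  xs <- ys <- rs <- numeric(n)
  if (n == 0L)
    return(data.frame(x_um = xs, y_um = ys, radius_um = rs))
  for (k in seq_len(n)) {
    r <- rnorm_trunc(1L, r_mean, r_sd, lo = max(1, r_mean / 3))
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      x <- runif(1L, r, dims[1] - r)
      y <- runif(1L, r, dims[2] - r)
      if (k == 1L ||
          all((x - xs[seq_len(k - 1L)])^2 + (y - ys[seq_len(k - 1L)])^2 >
              (r + rs[seq_len(k - 1L)] + 0.5)^2)) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop2("nucleus placement failed after %d tries: field too crowded (n = %d)",
            max_tries, n)
    xs[k] <- x; ys[k] <- y; rs[k] <- r
  }
  data.frame(x_um = xs, y_um = ys, radius_um = rs)
}

# Sample one point in the requested compartment, margin um away from all
# nuclear boundaries (outside) or inside one nucleus with an interior
# margin.
sample_point <- function(nuc, dims, nuclear, margin = 1.0,
                         max_tries = 500L) {
  if (nuclear) {
    if (nrow(nuc) == 0L)
      stop2("cannot place a nuclear focus: no nuclei in the scene")
    for (try in seq_len(max_tries)) {
      k <- sample.int(nrow(nuc), 1L)
      rmax <- nuc$radius_um[k] - margin
      if (rmax <= 0.2) next
      a <- runif(1L, 0, 2 * pi); d <- sqrt(runif(1L)) * rmax
      return(c(nuc$x_um[k] + d * cos(a), nuc$y_um[k] + d * sin(a)))
    }
    stop2("failed to place a nuclear focus (nuclei too small for margin)")
  }
  for (try in seq_len(max_tries)) {
    x <- runif(1L, 0, dims[1]); y <- runif(1L, 0, dims[2])
    if (!in_any_nucleus(x, y, nuc, margin = margin)) return(c(x, y))
  }
  stop2("failed to place a sarcoplasmic focus: field too crowded")
}

# Additively render isotropic Gaussian spots (integrated AU each) into
# one image. Batched so the image is modified in place rather than
# copied once per spot.
render_spots <- function(img, x_um, y_um, sigma_um, total_au, px_per_um) {
  nr <- nrow(img); nc <- ncol(img)
  sx <- x_um * px_per_um + 0.5  # pixel-centre coordinates
  sy <- y_um * px_per_um + 0.5
  sig <- rep_len(sigma_um, length(sx)) * px_per_um
  for (k in seq_along(sx)) {
    w <- ceiling(4 * sig[k]) + 1L
    rows <- max(1L, floor(sy[k] - w)):min(nr, ceiling(sy[k] + w))
    cols <- max(1L, floor(sx[k] - w)):min(nc, ceiling(sx[k] + w))
    if (!length(rows) || !length(cols)) next
    amp <- total_au[k] / (2 * pi * sig[k]^2)
    gy <- exp(-((rows - sy[k])^2) / (2 * sig[k]^2))
    gx <- exp(-((cols - sx[k])^2) / (2 * sig[k]^2))
    img[rows, cols] <- img[rows, cols] + amp * outer(gy, gx)
  }
  img
}

# Render nuclei as soft-edged disks (logistic edge profile), batched.
render_nuclei <- function(img, nuc, amp, px_per_um, edge_um = 0.25) {
  nr <- nrow(img); nc <- ncol(img)
  e <- max(edge_um * px_per_um, 0.3)
  for (k in seq_len(nrow(nuc))) {
    sx <- nuc$x_um[k] * px_per_um + 0.5
    sy <- nuc$y_um[k] * px_per_um + 0.5
    r <- nuc$radius_um[k] * px_per_um
    w <- ceiling(r + 4 * e)
    rows <- max(1L, floor(sy - w)):min(nr, ceiling(sy + w))
    cols <- max(1L, floor(sx - w)):min(nc, ceiling(sx + w))
    d <- sqrt(outer((rows - sy)^2, (cols - sx)^2, "+"))
    img[rows, cols] <- img[rows, cols] + amp / (1 + exp((d - r) / e))
  }
  img
}

# Camera model: optional Poisson shot noise at photons_per_au, then
# additive Gaussian read noise, clamped at zero.
apply_noise <- function(base, photons_per_au, read_sd) {
  img <- base
  if (is.finite(photons_per_au) && photons_per_au > 0) {
    img <- matrix(rpois(length(base), pmax(base, 0) * photons_per_au) /
                    photons_per_au,
                  nrow = nrow(base))
  }
  if (read_sd > 0)
    img <- img + matrix(rnorm(length(img), 0, read_sd), nrow = nrow(img))
  pmax(img, 0)
}

# ---- field generation -------------------------------------------------

#' Generate one synthetic multiplex ISH field with ground truth
#'
#' Renders three channel images (nuclear stain, 5' probe, 3' probe) for
#' one field and returns, alongside them, a ground-truth table that
#' enumerates every planted object: nuclei, small single-transcript foci
#' (paired or orphan, nuclear or sarcoplasmic) and large multi-transcript
#' nuclear 5' foci built from 2-6 overlapping Gaussian blobs. Object
#' counts are Poisson draws around the configured means; identical seeds
#' give bit-identical output.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @return list with elements \code{images} (named list of numeric
#'   matrices \code{nuclear}, \code{p5}, \code{p3}, row = y, column = x),
#'   \code{truth} (data.frame, one row per planted object), \code{nuclei}
#'   (data.frame of nucleus centres and radii) and \code{config}.
#' @examples
#' f <- generateField(sceneConfig(n_nuclei = 20, n_pairs = 15,
#'   n_orphan_5p = 10, n_orphan_3p = 12, n_large_foci = 4, seed = 7))
#' table(f$truth$kind)
#' @export
generateField <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  with_seed(config@seed, generate_field_impl(config))
}

# Lay out all objects of a scene (no rendering, no noise): returns the
# truth table, the nucleus table and the per-channel spot lists.
layout_scene <- function(config) {
  geom <- config@geometry
  dims <- unname(fieldDimUm(geom))
  ui <- config@unit_intensity_au
  psf <- config@psf_sigma_um
  truth <- list()
  spots <- list(`5p` = list(x = numeric(), y = numeric(),
                            sigma = numeric(), au = numeric()),
                `3p` = list(x = numeric(), y = numeric(),
                            sigma = numeric(), au = numeric()))
  add_spot <- function(ch, x, y, sigma, au) {
    sp <- spots[[ch]]
    sp$x <- c(sp$x, x); sp$y <- c(sp$y, y)
    sp$sigma <- c(sp$sigma, sigma); sp$au <- c(sp$au, au)
    spots[[ch]] <<- sp
  }

  ## nuclei
  n_nuc <- rpois(1L, config@n_nuclei)
  nuc <- place_nuclei(n_nuc, dims, config@nucleus_radius_um[1],
                      config@nucleus_radius_um[2])
  for (k in seq_len(nrow(nuc)))
    truth[[length(truth) + 1L]] <-
      truth_row("nucleus", x = nuc$x_um[k], y = nuc$y_um[k],
                area = pi * nuc$radius_um[k]^2, radius = nuc$radius_um[k])

  draw_intensity <- function(n) rnorm_trunc(n, ui[1], ui[2], lo = 2.0)
  nominal_area <- pi * (2 * psf)^2

  ## paired small foci (mature transcripts carrying both probe regions)
  n_pairs <- rpois(1L, config@n_pairs)
  for (p in seq_len(n_pairs)) {
    nuclear <- runif(1L) < config@frac_small_in_nucleus
    mid <- sample_point(nuc, dims, nuclear,
                        margin = if (nuclear) 1.0 else 1.5)
    d <- runif(1L, 0.05, max(config@pair_offset_um, 0.051))
    a <- runif(1L, 0, 2 * pi)
    off <- c(cos(a), sin(a)) * d / 2
    p5 <- mid - off; p3 <- mid + off
    comp <- if (nuclear) "nuclear" else "sarcoplasmic"
    i5 <- draw_intensity(1L); i3 <- draw_intensity(1L)
    add_spot("5p", p5[1], p5[2], psf, i5)
    add_spot("3p", p3[1], p3[2], psf, i3)
    truth[[length(truth) + 1L]] <-
      truth_row("small_focus", "5p", p5[1], p5[2], nominal_area,
                pair = p, compartment = comp, intensity = i5)
    truth[[length(truth) + 1L]] <-
      truth_row("small_focus", "3p", p3[1], p3[2], nominal_area,
                pair = p, compartment = comp, intensity = i3)
  }

  ## orphan small foci
  for (ch in c("5p", "3p")) {
    lam <- if (ch == "5p") config@n_orphan_5p else config@n_orphan_3p
    n_o <- rpois(1L, lam)
    for (k in seq_len(n_o)) {
      nuclear <- runif(1L) < config@frac_small_in_nucleus
      pt <- sample_point(nuc, dims, nuclear,
                         margin = if (nuclear) 1.0 else 1.5)
      comp <- if (nuclear) "nuclear" else "sarcoplasmic"
      ii <- draw_intensity(1L)
      add_spot(ch, pt[1], pt[2], psf, ii)
      truth[[length(truth) + 1L]] <-
        truth_row("small_focus", ch, pt[1], pt[2], nominal_area,
                  compartment = comp, intensity = ii)
    }
  }

  ## dp71-like 3'-only nuclei (optional, default off)
  n_dp71 <- rpois(1L, config@n_3p_only_nuclei)
  if (n_dp71 > 0L && nrow(nuc) > 0L) {
    for (k in seq_len(n_dp71)) {
      for (j in seq_len(3L)) {
        pt <- sample_point(nuc, dims, TRUE)
        ii <- draw_intensity(1L)
        add_spot("3p", pt[1], pt[2], psf, ii)
        truth[[length(truth) + 1L]] <-
          truth_row("small_focus", "3p", pt[1], pt[2], nominal_area,
                    compartment = "nuclear", intensity = ii)
      }
    }
  }

  ## large 5'-only nuclear foci (nascent transcription sites), rendered
  ## as 2-6 overlapping Gaussian blobs wholly inside one nucleus
  n_large <- rpois(1L, config@n_large_foci)
  if (n_large > nrow(nuc))
    stop2("cannot place %d large foci in %d nuclei", n_large, nrow(nuc))
  host <- if (n_large > 0L) sample.int(nrow(nuc), n_large) else integer()
  tr_rng <- config@transcripts_per_large_focus
  for (k in seq_len(n_large)) {
    h <- host[k]
    tr_vals <- seq(round(tr_rng[1]), round(tr_rng[2]))
    transcripts <- tr_vals[sample.int(length(tr_vals), 1L)]
    total <- sum(draw_intensity(transcripts))
    n_blobs <- sample(3:6, 1L)
    ## tight, strongly overlapping blobs keep per-pixel brightness well
    ## above single spots, as in real nascent-site signals, while the
    ## thresholded union stays >= 10 um^2
    sig_b <- runif(1L, 0.55, 0.8)
    spread <- min(1.5, max(nuc$radius_um[h] - 2.5 * sig_b, 0.3))
    a <- runif(n_blobs, 0, 2 * pi); d <- sqrt(runif(n_blobs)) * spread
    bx <- nuc$x_um[h] + d * cos(a); by <- nuc$y_um[h] + d * sin(a)
    for (b in seq_len(n_blobs))
      add_spot("5p", bx[b], by[b], sig_b, total / n_blobs)
    ## ground-truth apparent area: analytic blob sum above 0.3 AU on a
    ## fine local grid around the focus
    gw <- nuc$radius_um[h] + 3 * sig_b
    gx <- seq(nuc$x_um[h] - gw, nuc$x_um[h] + gw, by = 0.25)
    gy <- seq(nuc$y_um[h] - gw, nuc$y_um[h] + gw, by = 0.25)
    val <- matrix(0, length(gy), length(gx))
    amp <- (total / n_blobs) / (2 * pi * sig_b^2)
    for (b in seq_len(n_blobs))
      val <- val + amp * exp(-(outer((gy - by[b])^2, (gx - bx[b])^2, "+")) /
                               (2 * sig_b^2))
    area <- sum(val > 0.3) * 0.25^2
    truth[[length(truth) + 1L]] <-
      truth_row("large_focus", "5p", nuc$x_um[h], nuc$y_um[h], area,
                compartment = "nuclear", transcripts = transcripts,
                intensity = total)
  }

  list(truth = bind_truth(truth), nuclei = nuc, spots = spots)
}

# Noise-free channel composites of a laid-out scene, in AU.
compose_scene <- function(config, scene) {
  geom <- config@geometry
  s <- geom@px_per_um
  nr <- geom@height_px; nc <- geom@width_px
  bg <- config@background_au[1]
  base_nuc <- render_nuclei(matrix(bg, nr, nc), scene$nuclei,
                            config@nuclear_stain_au, s)
  sp5 <- scene$spots$`5p`; sp3 <- scene$spots$`3p`
  base_p5 <- render_spots(matrix(bg, nr, nc), sp5$x, sp5$y, sp5$sigma,
                          sp5$au, s)
  base_p3 <- render_spots(matrix(bg, nr, nc), sp3$x, sp3$y, sp3$sigma,
                          sp3$au, s)
  list(nuclear = base_nuc, p5 = base_p5, p3 = base_p3)
}

generate_field_impl <- function(config) {
  scene <- layout_scene(config)
  base <- compose_scene(config, scene)
  read_sd <- config@background_au[2]
  images <- lapply(base, apply_noise, photons_per_au = config@photons_per_au,
                   read_sd = read_sd)
  list(images = images, truth = scene$truth, nuclei = scene$nuclei,
       config = config)
}

#' Generate a 5'-channel exposure series with saturation
#'
#' Produces the 5' probe channel of one synthetic field at a series of
#' exposure times. Pixel intensity scales linearly with exposure relative
#' to \code{reference_exposure_ms}, then clips at \code{saturation_au}
#' (camera full well), so bright large foci attenuate at high exposures
#' while background and small foci remain linear.
#'
#' @param config a \linkS4class{SceneConfig}; its intensities are defined
#'   at the reference exposure.
#' @param exposures_ms strictly increasing exposure times (ms).
#' @param saturation_au clip level in AU (default \code{Inf}: no clipping).
#' @param reference_exposure_ms exposure at which the configured AU values
#'   apply.
#' @return list with \code{exposures_ms}, \code{images} (one 5' matrix per
#'   exposure, named by exposure), \code{truth}, \code{nuclei},
#'   \code{config}, \code{saturation_au}.
#' @export
generateExposureSeries <- function(config, exposures_ms,
                                   saturation_au = Inf,
                                   reference_exposure_ms = 100) {
  stopifnot(is(config, "SceneConfig"))
  if (length(exposures_ms) == 0L)
    stop2("exposure list must not be empty")
  if (any(diff(exposures_ms) <= 0))
    stop2("exposures must be strictly increasing")
  with_seed(config@seed, {
    scene <- layout_scene(config)
    geom <- config@geometry
    sp5 <- scene$spots$`5p`
    base <- render_spots(matrix(config@background_au[1], geom@height_px,
                                geom@width_px),
                         sp5$x, sp5$y, sp5$sigma, sp5$au, geom@px_per_um)
    images <- lapply(exposures_ms, function(e) {
      img <- pmin(base * e / reference_exposure_ms, saturation_au)
      apply_noise(img, config@photons_per_au, config@background_au[2])
    })
    names(images) <- as.character(exposures_ms)
    list(exposures_ms = exposures_ms, images = images, truth = scene$truth,
         nuclei = scene$nuclei, config = config,
         saturation_au = saturation_au)
  })
}

#' Mean intensity of circular ROIs across an exposure series
#'
#' Mirrors the ROI workflow used for intensity calibration: regions of
#' interest are fixed (here: supplied centres), then the mean pixel
#' intensity inside each ROI is measured at every exposure.
#'
#' @param series result of \code{\link{generateExposureSeries}}, or any
#'   list with \code{images} (list of matrices) and \code{exposures_ms}.
#' @param centers_um two-column matrix (x_um, y_um) of ROI centres.
#' @param radius_um ROI radius in um.
#' @param geometry a \linkS4class{FieldGeometry}.
#' @return numeric matrix, one row per ROI, one column per exposure.
#' @export
measureRoiSeries <- function(series, centers_um, radius_um, geometry) {
  centers_um <- as.matrix(centers_um)
  s <- geometry@px_per_um
  nr <- geometry@height_px; nc <- geometry@width_px
  out <- matrix(NA_real_, nrow(centers_um), length(series$images),
                dimnames = list(NULL, names(series$images)))
  r_px <- radius_um * s
  for (i in seq_len(nrow(centers_um))) {
    cx <- centers_um[i, 1] * s + 0.5; cy <- centers_um[i, 2] * s + 0.5
    rows <- max(1L, floor(cy - r_px)):min(nr, ceiling(cy + r_px))
    cols <- max(1L, floor(cx - r_px)):min(nc, ceiling(cx + r_px))
    sel <- outer((rows - cy)^2, (cols - cx)^2, "+") <= r_px^2
    for (j in seq_along(series$images))
      out[i, j] <- mean(series$images[[j]][rows, cols][sel])
  }
  out
}
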