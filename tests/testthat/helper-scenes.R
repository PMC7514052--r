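# Shared fixtures: small-field configurations keep unit tests fast; the
# full-size cohort used by the end-to-end checks is computed once and
# cached for the whole run.

.cache <- new.env(parent = emptyenv())

small_geom <- function() fieldGeometry(width_px = 400L, height_px = 300L)

# a small field with the same object densities as the default scene
small_scene <- function(seed = 1L, ...) {
  args <- list(geometry = small_geom(), n_nuclei = 25, n_pairs = 22,
               n_orphan_5p = 27, n_orphan_3p = 38,
               frac_small_in_nucleus = 0.15, n_large_foci = 7,
               seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sceneConfig, args)
}

# noise-free imaging: no shot noise, no read noise
noisefree <- function(cfg) {
  initialize(cfg, photons_per_au = Inf,
             background_au = c(cfg@background_au[1], 0))
}

# greedy nearest matching of detections to planted objects: truth rows
# are visited in order of their closest detection; each detection is
# used at most once
match_foci <- function(truth_xy, det_xy, tol_um = 1.0) {
  nt <- nrow(truth_xy); nd <- nrow(det_xy)
  if (nt == 0L || nd == 0L)
    return(list(tp = 0L, fp = nd, fn = nt))
  d <- sqrt(outer(truth_xy[, 1], det_xy[, 1], "-")^2 +
              outer(truth_xy[, 2], det_xy[, 2], "-")^2)
  used <- logical(nd)
  tp <- 0L
  for (i in order(apply(d, 1L, min))) {
    row <- d[i, ]
    row[used] <- Inf
    j <- which.min(row)
    if (row[j] <= tol_um) {
      tp <- tp + 1L
      used[j] <- TRUE
    }
  }
  list(tp = tp, fp = nd - tp, fn = nt - tp)
}

# detection precision/recall on the small foci of one generated field
small_focus_pr <- function(field, geometry, channel = "5p",
                           tol_um = 1.0, ...) {
  det <- detectFoci(field$images[[if (channel == "5p") "p5" else "p3"]],
                    geometry, channel = channel, ...)
  det <- det[det$size_class == "small", c("x_um", "y_um"), drop = FALSE]
  tr <- field$truth
  tr <- tr[tr$kind == "small_focus" & tr$channel == channel,
           c("x_um", "y_um"), drop = FALSE]
  m <- match_foci(as.matrix(tr), as.matrix(det), tol_um)
  list(precision = if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else NA,
       recall = if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else NA,
       tp = m$tp, fp = m$fp, fn = m$fn)
}

# minimum same-set nearest-neighbour distance among truth rows
nn_dists_same <- function(tr) {
  xy <- as.matrix(tr[, c("x_um", "y_um")])
  d <- sqrt(outer(xy[, 1], xy[, 1], "-")^2 +
              outer(xy[, 2], xy[, 2], "-")^2)
  diag(d) <- Inf
  apply(d, 1, min)
}

# full-size WT vs mdx cohort (4 animals x 9 fields per genotype), cached
wt_mdx_cohort <- function() {
  if (is.null(.cache$cohort)) {
    .cache$cohort <- runPipeline(
      configs = list(WT = wtSceneConfig(), mdx = mdxSceneConfig()),
      n_animals = 4L, fields_per_animal = 9L, seed = 20L)
  }
  .cache$cohort
}
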