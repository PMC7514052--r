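#' Write a synthetic field to disk (TIFF + JSON sidecar + truth CSV)
#'
#' Each channel is written as a single-channel 16-bit TIFF, linearly
#' scaled to the sample range, with the AU scale recorded in a sidecar
#' JSON (\code{field.json}) alongside the field geometry and channel
#' names. The ground-truth table, when present, is written as
#' \code{truth.csv} with one row per planted object.
#'
#' @param field list as returned by \code{\link{generateField}} (elements
#'   \code{images}, \code{config} and optionally \code{truth}), or any
#'   list with \code{images} and a \code{geometry} element.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeField <- function(field, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geom <- if (!is.null(field$config)) field$config@geometry
          else field$geometry
  stopifnot(is(geom, "FieldGeometry"))
  channels <- list()
  for (ch in names(field$images)) {
    img <- field$images[[ch]]
    mx <- max(img, 1e-9)
    fn <- sprintf("%s.tif", ch)
    tiff::writeTIFF(pmin(img / mx, 1), file.path(dir, fn),
                    bits.per.sample = 16L)
    channels[[ch]] <- list(file = fn, max_au = mx)
  }
  meta <- list(
    geometry = list(width_px = geom@width_px, height_px = geom@height_px,
                    px_per_um = geom@px_per_um,
                    thickness_um = geom@thickness_um,
                    density_mg_per_mm3 = geom@density_mg_per_mm3,
                    rna_yield_ug_per_mg = geom@rna_yield_ug_per_mg),
    channels = channels)
  if (!is.null(field$config)) meta$seed <- field$config@seed
  jsonlite::write_json(meta, file.path(dir, "field.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(field$truth))
    write.csv(field$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a field written by \code{\link{writeField}}
#'
#' @param dir directory containing \code{field.json}, channel TIFFs and
#'   optionally \code{truth.csv}.
#' @return list with \code{images} (AU-scaled matrices), \code{geometry}
#'   (a \linkS4class{FieldGeometry}) and \code{truth} (data.frame or
#'   NULL).
#' @export
readField <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "field.json"),
                              simplifyVector = TRUE)
  g <- meta$geometry
  geom <- fieldGeometry(g$width_px, g$height_px, g$px_per_um,
                        g$thickness_um, g$density_mg_per_mm3,
                        g$rna_yield_ug_per_mg)
  images <- list()
  for (ch in names(meta$channels)) {
    info <- meta$channels[[ch]]
    img <- tiff::readTIFF(file.path(dir, info$file))
    images[[ch]] <- img * info$max_au
  }
  truth_fn <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_fn))
    read.csv(truth_fn, stringsAsFactors = FALSE) else NULL
  list(images = images, geometry = geom, truth = truth)
}
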