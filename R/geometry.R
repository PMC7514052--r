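#' Construct a FieldGeometry
#'
#' Defaults describe 20x imaging of skeletal muscle cryosections: a 1388 x 1040 pixel field at ~2 pixels per micron,
#' 8 um section thickness, muscle density 1.06 mg/mm^3 and RNA yields of
#' 0.25-0.5 ug per mg tissue.
#'
#' @param width_px,height_px field dimensions in pixels.
#' @param px_per_um pixels per micron.
#' @param thickness_um section thickness (um).
#' @param density_mg_per_mm3 tissue density (mg per mm^3; 1 g/ml = 1).
#' @param rna_yield_ug_per_mg length-2 numeric, low and high RNA yield per
#'   mg of tissue.
#' @return a \linkS4class{FieldGeometry}.
#' @examples
#' geom <- fieldGeometry()
#' areaUm2(geom)   # 360880
#' @export
fieldGeometry <- function(width_px = 1388L, height_px = 1040L,
                          px_per_um = 2, thickness_um = 8,
                          density_mg_per_mm3 = 1.06,
                          rna_yield_ug_per_mg = c(0.25, 0.5)) {
  new("FieldGeometry",
      width_px = as.integer(width_px), height_px = as.integer(height_px),
      px_per_um = as.numeric(px_per_um),
      thickness_um = as.numeric(thickness_um),
      density_mg_per_mm3 = as.numeric(density_mg_per_mm3),
      rna_yield_ug_per_mg = as.numeric(rna_yield_ug_per_mg))
}

#' Field area in square microns
#'
#' @param geometry a \linkS4class{FieldGeometry}.
#' @return area of the imaging field in um^2.
#' @export
areaUm2 <- function(geometry) {
  stopifnot(is(geometry, "FieldGeometry"))
  geometry@width_px * geometry@height_px / geometry@px_per_um^2
}

#' Field width and height in microns
#'
#' @param geometry a \linkS4class{FieldGeometry}.
#' @return named numeric c(width_um, height_um).
#' @export
fieldDimUm <- function(geometry) {
  stopifnot(is(geometry, "FieldGeometry"))
  c(width_um = geometry@width_px / geometry@px_per_um,
    height_um = geometry@height_px / geometry@px_per_um)
}

#' Convert a pixel area to square microns
#'
#' Apparent particle areas measured in pixels are converted to um^2 using
#' the square of the pixel scale.
#'
#' @param pixel_count number of pixels (vectorised, must be >= 0).
#' @param geometry a \linkS4class{FieldGeometry}.
#' @return area(s) in um^2.
#' @examples
#' pixelAreaToUm2(4, fieldGeometry())  # 1 um^2 at 2 px/um
#' @export
pixelAreaToUm2 <- function(pixel_count, geometry) {
  stopifnot(is(geometry, "FieldGeometry"), all(pixel_count >= 0))
  pixel_count / geometry@px_per_um^2
}

#' Tissue mass and RNA content represented by one imaging field
#'
#' Converts the field's area, section thickness and tissue density into
#' the represented tissue mass, then applies the RNA yield range to bound
#' total RNA per field. With the default geometry one field represents
#' ~3 ug of muscle, i.e. roughly 0.75-1.5 ng of total RNA.
#'
#' @param geometry a \linkS4class{FieldGeometry}.
#' @return named list: \code{volume_um3}, \code{tissue_mass_ug},
#'   \code{rna_ng_low}, \code{rna_ng_high}.
#' @export
fieldRnaMass <- function(geometry) {
  stopifnot(is(geometry, "FieldGeometry"))
  vol_um3 <- areaUm2(geometry) * geometry@thickness_um
  vol_mm3 <- vol_um3 / 1e9
  mass_mg <- vol_mm3 * geometry@density_mg_per_mm3
  mass_ug <- mass_mg * 1e3
  rna_ug <- mass_mg * geometry@rna_yield_ug_per_mg
  list(volume_um3 = vol_um3,
       tissue_mass_ug = mass_ug,
       rna_ng_low = rna_ug[1] * 1e3,
       rna_ng_high = rna_ug[2] * 1e3)
}

setMethod("show", "FieldGeometry", function(object) {
  d <- fieldDimUm(object)
  cat(sprintf("FieldGeometry: %d x %d px (%.1f x %.1f um), %.2f px/um\n",
              object@width_px, object@height_px, d[1], d[2],
              object@px_per_um))
  cat(sprintf("  area %.0f um^2, thickness %g um, density %g mg/mm^3\n",
              areaUm2(object), object@thickness_um,
              object@density_mg_per_mm3))
  m <- fieldRnaMass(object)
  cat(sprintf("  tissue %.2f ug/field, RNA %.2f-%.2f ng/field\n",
              m$tissue_mass_ug, m$rna_ng_low, m$rna_ng_high))
})
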