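#' Write a float image as TIFF with a JSON sidecar
#'
#' Values are stored in a 32-bit TIFF normalized by `scale = max(value, 1)`
#' (TIFF payload in `[0, 1]`); the sidecar `<path>.json` records the scale,
#' units, material/energy tags and geometry id so [read_image_tiff()] can
#' restore the physical values.
#'
#' @param img Numeric matrix, [material_thickness_image()], `mono_image`, or
#'   `pan_image` (its attenuation view is written).
#' @param path Output `.tiff`/`.tif` path.
#' @param units Physical units recorded in the sidecar (`"mm"` for PETIs).
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path, units = NULL) {
  meta <- list()
  if (inherits(img, "pan_image")) {
    meta$kind <- "pan"; meta$n0 <- img$n0
    meta$geometry_id <- img$geometry_id
    img2 <- img$attenuation
    if (is.null(units)) units <- "attenuation"
  } else {
    img2 <- unclass(img)
    if (inherits(img, "material_thickness_image")) {
      meta$kind <- "peti"; meta$material <- attr(img, "material")
      if (is.null(units)) units <- "mm"
    } else if (inherits(img, "mono_image")) {
      meta$kind <- "pvmi"; meta$energy_kev <- attr(img, "energy")
      if (is.null(units)) units <- "attenuation"
    } else meta$kind <- "image"
    meta$geometry_id <- attr(img, "geometry_id")
  }
  if (min(img2) < 0) stop("negative values cannot be stored; window first")
  scale <- max(max(img2), 1)
  meta$scale <- scale
  meta$units <- if (is.null(units)) "arbitrary" else units
  tiff::writeTIFF(img2 / scale, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an image written by [write_image_tiff()]
#'
#' @param path `.tiff` path with its `.json` sidecar alongside.
#' @return Numeric matrix with the sidecar metadata in attribute `meta`.
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list(scale = 1)
  out <- img * meta$scale
  attr(out, "meta") <- meta
  out
}

#' Export a windowed 8-bit PNG for viewing
#'
#' @param img Image accepted by [window_image()].
#' @param path Output `.png` path.
#' @param level,width Optional window (auto percentiles when `NULL`).
#' @param invert Flip the gray scale (counts images are conventionally shown
#'   inverted so dense structures appear bright).
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path, level = NULL, width = NULL,
                            invert = FALSE) {
  w <- window_image(img, level, width)
  if (invert) w <- 255L - w
  png::writePNG(w / 255, path)
  invisible(path)
}
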