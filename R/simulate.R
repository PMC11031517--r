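#' Simulate the full spectral panoramic image set from a head volume
#'
#' End-to-end pipeline: segmentation (unless ground-truth labels are given),
#' dental-arch fit, panoramic sweep construction, forward projection of the
#' basis materials to bone/soft PETIs, and spectral synthesis of the
#' conventional PAN plus PVMIs at the requested energies.
#'
#' @param volume An [hu_volume()] (ignored if `labels` given and
#'   `seg_config` unused).
#' @param labels Optional [label_volume()]; when `NULL`, `volume` is
#'   segmented with `seg_config`.
#' @param seg_config A [segmentation_config()].
#' @param energies PVMI energies in keV (study presets: 40 and 60).
#' @param spectrum A [xray_spectrum()] for the PAN synthesis.
#' @param tables An [attenuation_table()].
#' @param n_cols,n_rows,source_to_arch,arch_to_detector,vertical_field
#'   Geometry parameters, see [build_trajectory()].
#' @param arch_args Extra arguments for [fit_dental_arch()].
#' @return List with `labels`, `arch`, `geometry`, `peti` (list `bone`,
#'   `soft`), `pan`, and `pvmi` (named list by energy).
#' @export
simulate_panoramic <- function(volume = NULL, labels = NULL,
                               seg_config = segmentation_config(),
                               energies = c(40, 60),
                               spectrum = tungsten_spectrum(),
                               tables = attenuation_table(),
                               n_cols = 700, n_rows = 500,
                               source_to_arch = 400, arch_to_detector = 100,
                               vertical_field = 100, arch_args = list()) {
  if (is.null(labels)) {
    if (is.null(volume)) stop("either 'volume' or 'labels' is required")
    labels <- segment_volume(volume, seg_config)
  }
  arch <- do.call(fit_dental_arch, c(list(labels), arch_args))
  geom <- build_trajectory(arch, n_cols = n_cols, n_rows = n_rows,
                           source_to_arch = source_to_arch,
                           arch_to_detector = arch_to_detector,
                           vertical_field = vertical_field)
  proj <- project_all_materials(labels, geom)
  pan <- synthesize_pan(proj$bone, proj$soft, spectrum, tables)
  pvmi <- lapply(energies, function(e)
    synthesize_pvmi(proj$bone, proj$soft, e, tables))
  names(pvmi) <- paste0("pvmi_", energies)
  list(labels = labels, arch = arch, geometry = geom,
       peti = list(bone = proj$bone, soft = proj$soft),
       pan = pan, pvmi = pvmi)
}

#' Write the five standard output images of a simulation
#'
#' @param sim Result of [simulate_panoramic()].
#' @param dir Output directory (created if needed).
#' @param png Also write windowed 8-bit PNG previews.
#' @return Invisible character vector of written TIFF paths.
#' @export
write_simulation <- function(sim, dir, png = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    write_image_tiff(sim$pan, file.path(dir, "pan.tiff")),
    write_image_tiff(sim$peti$bone, file.path(dir, "peti_bone.tiff")),
    write_image_tiff(sim$peti$soft, file.path(dir, "peti_soft.tiff")))
  for (nm in names(sim$pvmi))
    paths <- c(paths, write_image_tiff(sim$pvmi[[nm]],
                                       file.path(dir, paste0(nm, ".tiff"))))
  if (png) {
    write_image_png(sim$pan, file.path(dir, "pan.png"))
    write_image_png(sim$peti$bone, file.path(dir, "peti_bone.png"))
    write_image_png(sim$peti$soft, file.path(dir, "peti_soft.png"))
    for (nm in names(sim$pvmi))
      write_image_png(sim$pvmi[[nm]], file.path(dir, paste0(nm, ".png")))
  }
  invisible(paths)
}
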