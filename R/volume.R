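#' Label codes for the three-material head model
#'
#' The framework works with exactly three materials: air, soft tissue and
#' bone (teeth are treated as bone, the second basis material). Labels are
#' stored as integers.
#'
#' @return Named integer vector `c(air = 0L, soft = 1L, bone = 2L)`.
#' @export
label_codes <- function() c(air = 0L, soft = 1L, bone = 2L)

#' Construct a Hounsfield-unit volume
#'
#' @param voxels 3-D numeric array of CT numbers in Hounsfield units (HU).
#' @param spacing Numeric length-3, voxel spacing `(dx, dy, dz)` in mm.
#' @param origin Numeric length-3, world coordinate (mm) of the center of
#'   voxel `[1, 1, 1]`. Axes are patient-like: x = left-right,
#'   y = posterior-anterior, z = inferior-superior.
#' @return An object of class `hu_volume`.
#' @export
hu_volume <- function(voxels, spacing = c(1, 1, 1), origin = NULL) {
  voxels <- check_voxels(voxels)
  spacing <- check_spacing(spacing)
  if (is.null(origin)) origin <- -(dim(voxels) - 1) / 2 * spacing
  stopifnot(length(origin) == 3, all(is.finite(origin)))
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = c("hu_volume", "panospec_volume"))
}

#' Construct a label volume
#'
#' @param labels 3-D integer array with values from [label_codes()].
#' @inheritParams hu_volume
#' @param ground_truth Logical flag: labels are generator ground truth (as
#'   opposed to a segmentation result).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1), origin = NULL,
                         ground_truth = FALSE) {
  if (!is.array(labels) || length(dim(labels)) != 3)
    stop("'labels' must be a 3-D array")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(label_codes()))
  if (length(bad))
    stop("labels contain values outside {air, soft, bone}: ",
         paste(bad, collapse = ", "))
  spacing <- check_spacing(spacing)
  if (is.null(origin)) origin <- -(dim(labels) - 1) / 2 * spacing
  structure(list(voxels = labels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 ground_truth = isTRUE(ground_truth)),
            class = c("label_volume", "panospec_volume"))
}

check_voxels <- function(voxels) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("'voxels' must be a 3-D array")
  if (length(voxels) == 0) stop("volume grid is empty")
  if (!all(is.finite(voxels))) stop("volume contains non-finite values")
  storage.mode(voxels) <- "double"
  voxels
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (mm)")
  spacing
}

#' @export
print.panospec_volume <- function(x, ...) {
  kind <- if (inherits(x, "label_volume")) "label volume" else "HU volume"
  cat(sprintf("panospec %s: %s voxels @ (%s) mm\n", kind,
              paste(dim(x$voxels), collapse = " x "),
              paste(format(x$spacing), collapse = ", ")))
  if (inherits(x, "label_volume")) {
    tab <- table(factor(x$voxels, levels = unname(label_codes()),
                        labels = names(label_codes())))
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  } else {
    cat(sprintf("  HU range: [%.1f, %.1f]\n", min(x$voxels), max(x$voxels)))
  }
  invisible(x)
}

#' World coordinates of voxel centers along one axis
#'
#' @param vol A `panospec_volume`.
#' @param axis 1, 2 or 3.
#' @return Numeric vector of mm coordinates (voxel centers).
#' @export
voxel_coords <- function(vol, axis) {
  n <- dim(vol$voxels)[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$spacing[axis]
}
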