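#' Segmentation configuration
#'
#' Controls the air/soft/bone segmentation of an HU volume. Air is split off
#' by a plain HU threshold. The remaining voxels are scored by blending the
#' HU value with a multi-scale sheetness bone-enhancement response
#' (`score = (1 - w) * HU + w * gain * sheetness`); voxels whose score
#' reaches `bone_threshold` become bone. With `blend_weight = 0` the
#' segmentation degrades to pure HU thresholding, which is exact on
#' noise-free phantoms with well-separated tissue HU.
#'
#' @param air_threshold HU below which a voxel is air (default -400).
#' @param bone_threshold Blended-score threshold for bone (default 300;
#'   HU units when `blend_weight = 0`).
#' @param scales Sheetness filter scales (Gaussian sigma, mm).
#' @param blend_weight Weight in `[0, 1]` of the enhancement response.
#' @param enhancement_gain Scale mapping the unit-normalized sheetness
#'   response onto the HU-like score axis (default 1000).
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(air_threshold = -400, bone_threshold = 300,
                                scales = c(1, 2), blend_weight = 0,
                                enhancement_gain = 1000) {
  if (air_threshold >= bone_threshold)
    stop("air_threshold must be below bone_threshold")
  if (any(scales <= 0)) stop("enhancement scales must be positive")
  if (blend_weight < 0 || blend_weight > 1)
    stop("blend_weight must lie in [0, 1]")
  structure(list(air_threshold = air_threshold,
                 bone_threshold = bone_threshold,
                 scales = as.numeric(scales),
                 blend_weight = blend_weight,
                 enhancement_gain = enhancement_gain),
            class = "segmentation_config")
}

#' Multi-scale sheetness bone-enhancement filter
#'
#' Hessian-eigenvalue sheetness measure for bright plate-like structures
#' (cortical bone appears as thin bright sheets in CT). At each scale the
#' volume is convolved with Gaussian-derivative kernels to obtain the
#' scale-normalized Hessian (gamma = 2); with eigenvalues sorted
#' `|l1| <= |l2| <= |l3|`, the response is
#' `exp(-Rsheet^2 / (2 alpha^2)) * (1 - exp(-Rblob^2 / (2 beta^2))) *
#'  (1 - exp(-Rnoise^2 / (2 c^2)))` for `l3 < 0` (bright sheet), 0 otherwise,
#' where `Rsheet = |l2| / |l3|`, `Rblob = |2 |l3| - |l2| - |l1|| / |l3|` and
#' `Rnoise` is the Frobenius norm of the Hessian. The final map is the
#' maximum response over scales, in `[0, 1]`.
#'
#' @param vol An [hu_volume()].
#' @param scales Gaussian scales sigma in mm (converted to voxels via the
#'   volume spacing); at least one, all positive.
#' @param alpha,beta Sheetness/blobness sensitivity parameters.
#' @param noise_scale Structure-strength cutoff `c` as a fraction of the
#'   volume's maximum Hessian norm at that scale (data-driven, so a constant
#'   volume yields an identically zero response).
#' @return 3-D array, same shape as the input, values in `[0, 1]`.
#' @export
bone_enhancement_filter <- function(vol, scales = c(1, 2), alpha = 0.5,
                                    beta = 0.5, noise_scale = 0.25) {
  stopifnot(inherits(vol, "hu_volume"))
  if (length(scales) < 1 || any(scales <= 0))
    stop("at least one positive scale (mm) is required")
  d <- dim(vol$voxels)
  best <- array(0, dim = d)
  orders <- list(xx = c(2L, 0L, 0L), yy = c(0L, 2L, 0L), zz = c(0L, 0L, 2L),
                 xy = c(1L, 1L, 0L), xz = c(1L, 0L, 1L), yz = c(0L, 1L, 1L))
  for (sg in scales) {
    sig_vox <- pmax(sg / vol$spacing, 0.3)
    h <- lapply(orders, function(o) {
      g <- gauss_deriv3d_cpp(vol$voxels, as.integer(d), sig_vox, o)
      # derivatives are per voxel; convert to per mm, then gamma-normalize
      g / prod(vol$spacing^o) * sg^2
    })
    ev <- eig3_sym_cpp(h$xx, h$yy, h$zz, h$xy, h$xz, h$yz)
    a1 <- abs(ev$l1); a2 <- abs(ev$l2); a3 <- abs(ev$l3)
    rnoise <- sqrt(ev$l1^2 + ev$l2^2 + ev$l3^2)
    cmax <- max(rnoise)
    if (cmax <= 0) next
    cc <- noise_scale * cmax
    safe3 <- pmax(a3, .Machine$double.xmin)
    rsheet <- a2 / safe3
    rblob <- abs(2 * a3 - a2 - a1) / safe3
    resp <- exp(-rsheet^2 / (2 * alpha^2)) *
      (1 - exp(-rblob^2 / (2 * beta^2))) *
      (1 - exp(-rnoise^2 / (2 * cc^2)))
    resp[ev$l3 >= 0 | a3 == 0] <- 0
    best <- pmax(best, array(resp, dim = d))
  }
  best
}

#' Segment an HU volume into air, soft tissue and bone
#'
#' Voxels below the air threshold are air. The rest are scored by blending
#' HU with the bone-enhancement response (see [segmentation_config()]);
#' scores at or above the bone threshold become bone, the remainder soft
#' tissue. Teeth are labeled bone: the forward model has exactly two
#' attenuating basis materials.
#'
#' @param vol An [hu_volume()].
#' @param config A [segmentation_config()].
#' @return A [label_volume()] carrying the input's spacing and origin.
#' @export
segment_volume <- function(vol, config = segmentation_config()) {
  stopifnot(inherits(vol, "hu_volume"), inherits(config, "segmentation_config"))
  hu <- vol$voxels
  codes <- label_codes()
  score <- if (config$blend_weight > 0) {
    enh <- bone_enhancement_filter(vol, config$scales)
    (1 - config$blend_weight) * hu +
      config$blend_weight * config$enhancement_gain * enh
  } else hu
  lab <- array(codes[["soft"]], dim = dim(hu))
  lab[score >= config$bone_threshold] <- codes[["bone"]]
  lab[hu < config$air_threshold] <- codes[["air"]]
  label_volume(lab, vol$spacing, vol$origin)
}
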