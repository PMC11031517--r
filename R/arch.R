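#' Construct a dental arch curve
#'
#' An arch curve is an ordered planar curve `(x(s), y(s))` in an axial plane
#' at height `z_arch`, resampled to (approximately) equal arc length, with
#' outward (buccal / anterior-pointing) unit normals per point.
#'
#' @param x,y Ordered planar coordinates (mm), left to right.
#' @param z_arch Height (mm) of the arch plane (occlusal plane).
#' @param normals Optional n x 2 matrix of outward unit normals; if missing,
#'   normals are computed from central-difference tangents and oriented
#'   anteriorly (+y on average).
#' @param coef Optional quartic coefficients the curve was fitted
#'   from, kept for provenance.
#' @return An `arch_curve` object with fields `s`, `x`, `y`, `nx`, `ny`,
#'   `z_arch`, `coef`.
#' @export
arch_curve <- function(x, y, z_arch = 0, normals = NULL, coef = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  ds <- sqrt(diff(x)^2 + diff(y)^2)
  if (any(ds <= 0)) stop("arch points must be strictly ordered")
  s <- c(0, cumsum(ds))
  if (is.null(normals)) {
    n <- length(x)
    if (n == 2) {
      tx <- rep(x[2] - x[1], 2); ty <- rep(y[2] - y[1], 2)
    } else {
      # central differences; second-order one-sided stencils at the ends
      tx <- c(-3 * x[1] + 4 * x[2] - x[3], x[3:n] - x[1:(n - 2)],
              3 * x[n] - 4 * x[n - 1] + x[n - 2])
      ty <- c(-3 * y[1] + 4 * y[2] - y[3], y[3:n] - y[1:(n - 2)],
              3 * y[n] - 4 * y[n - 1] + y[n - 2])
    }
    nt <- sqrt(tx^2 + ty^2)
    # left normal of the tangent; flip so normals point anteriorly on average
    nrmx <- -ty / nt; nrmy <- tx / nt
    if (mean(nrmy) < 0) { nrmx <- -nrmx; nrmy <- -nrmy }
    normals <- cbind(nrmx, nrmy)
  } else {
    stopifnot(nrow(normals) == length(x))
    nrm <- sqrt(rowSums(normals^2))
    normals <- normals / nrm
  }
  structure(list(s = s, x = as.numeric(x), y = as.numeric(y),
                 nx = normals[, 1], ny = normals[, 2],
                 z_arch = z_arch, coef = coef),
            class = "arch_curve")
}

#' @export
print.arch_curve <- function(x, ...) {
  cat(sprintf("arch curve: %d points, arc length %.1f mm, z = %.1f mm\n",
              length(x$x), max(x$s), x$z_arch))
  invisible(x)
}

#' Fit the dental arch from a label volume
#'
#' Finds the occlusal plane as the z slab with maximum bone cross-section
#' (within an optional jaw window), collapses the bone occupancy of the slab
#' along z, estimates the arch midline per x column as the midpoint of the
#' bone extent in y, fits the symmetric quartic
#' `y(x) = a0 + a2 (x - xc)^2 + a4 (x - xc)^4` by least squares, and
#' resamples the fit to `n_points` equal arc-length stations with outward
#' normals.
#'
#' @param labels A [label_volume()] containing bone voxels.
#' @param slab_halfwidth Half thickness (mm) of the axial slab around the
#'   detected occlusal plane.
#' @param z_window Optional length-2 mm range restricting the occlusal-plane
#'   search; default: whole volume.
#' @param z_fixed Optional fixed occlusal-plane height (mm), bypassing
#'   auto-detection.
#' @param n_points Number of equal arc-length samples of the fitted curve.
#' @return An [arch_curve()].
#' @export
fit_dental_arch <- function(labels, slab_halfwidth = 6, z_window = NULL,
                            z_fixed = NULL, n_points = 200) {
  stopifnot(inherits(labels, "label_volume"))
  bone <- labels$voxels == label_codes()[["bone"]]
  if (!any(bone)) stop("no bone voxels in volume; cannot fit a dental arch")
  zs <- voxel_coords(labels, 3)
  if (is.null(z_fixed)) {
    area <- apply(bone, 3, sum)
    keep <- rep(TRUE, length(zs))
    if (!is.null(z_window)) keep <- zs >= z_window[1] & zs <= z_window[2]
    if (!any(keep & area > 0)) stop("no bone voxels inside the jaw window")
    area[!keep] <- -1
    z_occ <- zs[which.max(area)]
  } else z_occ <- z_fixed

  slab <- abs(zs - z_occ) <= slab_halfwidth
  occ <- apply(bone[, , slab, drop = FALSE], c(1, 2), any)
  xs <- voxel_coords(labels, 1)
  ys <- voxel_coords(labels, 2)
  sup <- which(rowSums(occ) > 0)
  if (length(sup) < 3)
    stop("fewer bone support columns than quartic coefficients")
  ymid <- vapply(sup, function(i) {
    j <- which(occ[i, ])
    (ys[min(j)] + ys[max(j)]) / 2
  }, numeric(1))
  xv <- xs[sup]
  xc <- (min(xv) + max(xv)) / 2
  X2 <- (xv - xc)^2
  fit <- stats::lm.fit(cbind(1, X2, X2^2), ymid)
  coef <- fit$coefficients
  halfspan <- (max(xv) - min(xv)) / 2

  # resample the fitted quartic to equal arc length
  xf <- seq(-halfspan, halfspan, length.out = 4001)
  yf <- coef[1] + coef[2] * xf^2 + coef[3] * xf^4
  ds <- sqrt(diff(xf)^2 + diff(yf)^2)
  sf <- c(0, cumsum(ds))
  st <- seq(0, max(sf), length.out = n_points)
  xi <- stats::approx(sf, xf, xout = st)$y
  yi <- coef[1] + coef[2] * xi^2 + coef[3] * xi^4
  dy <- 2 * coef[2] * xi + 4 * coef[3] * xi^3
  nt <- sqrt(1 + dy^2)
  normals <- cbind(-dy / nt, 1 / nt)  # anterior-pointing (+y) by construction
  arch_curve(xi + xc, yi, z_arch = z_occ, normals = normals,
             coef = c(a0 = unname(coef[1]), a2 = unname(coef[2]),
                      a4 = unname(coef[3]), xc = xc))
}

#' Build the panoramic source/detector sweep
#'
#' For each of `n_cols` equally spaced arc-length stations along the arch,
#' the central ray runs along the outward arch normal: the source sits
#' `source_to_arch` mm behind the arch point (lingual side), the detector
#' column base `arch_to_detector` mm in front (buccal side). Rows form a
#' vertical fan from the source point through `n_rows` detector pixels
#' centered on the occlusal plane. Image columns run left to right along the
#' arch.
#'
#' @param arch An [arch_curve()].
#' @param n_cols,n_rows Detector columns (sweep stations) and rows.
#' @param source_to_arch,arch_to_detector Distances (mm), both positive.
#' @param row_pitch Detector row pitch (mm) at the detector; default spans
#'   `vertical_field` mm.
#' @param vertical_field Vertical detector field (mm), used when `row_pitch`
#'   is `NULL`.
#' @return A `pan_geometry` object.
#' @export
build_trajectory <- function(arch, n_cols = 700, n_rows = 500,
                             source_to_arch = 400, arch_to_detector = 100,
                             row_pitch = NULL, vertical_field = 100) {
  stopifnot(inherits(arch, "arch_curve"))
  if (n_cols < 1 || n_rows < 1) stop("n_cols and n_rows must be >= 1")
  if (source_to_arch <= 0 || arch_to_detector <= 0)
    stop("source_to_arch and arch_to_detector must be positive")
  if (is.null(row_pitch)) row_pitch <- vertical_field / n_rows
  if (row_pitch <= 0) stop("row_pitch must be positive")

  st <- seq(0, max(arch$s), length.out = n_cols)
  ax <- stats::approx(arch$s, arch$x, xout = st)$y
  ay <- stats::approx(arch$s, arch$y, xout = st)$y
  nx <- stats::approx(arch$s, arch$nx, xout = st)$y
  ny <- stats::approx(arch$s, arch$ny, xout = st)$y
  nn <- sqrt(nx^2 + ny^2)
  nx <- nx / nn; ny <- ny / nn

  arch_pts <- cbind(ax, ay, rep(arch$z_arch, n_cols))
  src <- cbind(ax - source_to_arch * nx, ay - source_to_arch * ny,
               rep(arch$z_arch, n_cols))
  det <- cbind(ax + arch_to_detector * nx, ay + arch_to_detector * ny,
               rep(arch$z_arch, n_cols))
  structure(list(stations = st, arch_points = arch_pts, normals = cbind(nx, ny),
                 source_points = src, detector_base = det,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 row_pitch = row_pitch, source_to_arch = source_to_arch,
                 arch_to_detector = arch_to_detector, z_arch = arch$z_arch,
                 id = sprintf("pan-%dx%d-sa%g-ad%g-p%g-L%.3f", n_cols, n_rows,
                              source_to_arch, arch_to_detector, row_pitch,
                              max(arch$s))),
            class = "pan_geometry")
}

#' @export
print.pan_geometry <- function(x, ...) {
  cat(sprintf(paste0("panoramic geometry: %d cols x %d rows, ",
                     "source-arch %g mm, arch-detector %g mm, pitch %g mm\n"),
              x$n_cols, x$n_rows, x$source_to_arch, x$arch_to_detector,
              x$row_pitch))
  invisible(x)
}

#' All rays of a panoramic geometry
#'
#' Expands the per-column vertical fans into explicit ray origins and unit
#' directions, ordered like the image pixels (row fastest, column-major:
#' element `(r, c)` is ray `(c - 1) * n_rows + r`). Row 1 is the top of the
#' image (superior).
#'
#' @param geom A `pan_geometry`.
#' @return List with `origins` and `directions`, both `(n_rows * n_cols) x 3`.
#' @export
geometry_rays <- function(geom) {
  stopifnot(inherits(geom, "pan_geometry"))
  R <- geom$n_rows; C <- geom$n_cols
  dz <- (((R:1) - (R + 1) / 2)) * geom$row_pitch  # row 1 = superior
  # detector pixel positions: base + dz * z-hat, per (row, col)
  px <- rep(geom$detector_base[, 1], each = R)
  py <- rep(geom$detector_base[, 2], each = R)
  pz <- rep(geom$detector_base[, 3], each = R) + rep(dz, times = C)
  ox <- rep(geom$source_points[, 1], each = R)
  oy <- rep(geom$source_points[, 2], each = R)
  oz <- rep(geom$source_points[, 3], each = R)
  dx <- px - ox; dy <- py - oy; dzr <- pz - oz
  nrm <- sqrt(dx^2 + dy^2 + dzr^2)
  list(origins = cbind(ox, oy, oz),
       directions = cbind(dx / nrm, dy / nrm, dzr / nrm))
}

#' Serialize a panoramic geometry to JSON
#'
#' @param geom A `pan_geometry`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_geometry_json <- function(geom, path) {
  stopifnot(inherits(geom, "pan_geometry"))
  doc <- list(id = geom$id, n_cols = geom$n_cols, n_rows = geom$n_rows,
              row_pitch = geom$row_pitch, z_arch = geom$z_arch,
              source_to_arch = geom$source_to_arch,
              arch_to_detector = geom$arch_to_detector,
              stations = geom$stations,
              arch_points = geom$arch_points,
              source_points = geom$source_points,
              detector_base = geom$detector_base,
              normals = geom$normals)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
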