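#' Parameters for the synthetic labeled head phantom
#'
#' The phantom emulates the structure classes a panoramic simulation needs:
#' an ellipsoidal soft-tissue head, a U-shaped dental arch of bone following
#' a symmetric quartic `y(x) = a0 + a2 x^2 + a4 x^4`, individual teeth placed
#' at equal arc-length intervals along the arch with soft-tissue root canals,
#' mandible and maxilla bone bands, and an air gap behind the arch mimicking
#' the pharynx / tongue-palate gap. All lengths are mm; coordinates are
#' relative to the head center (x left-right, y posterior-anterior,
#' z inferior-superior).
#'
#' @param dim Grid shape (voxels), default `c(160, 160, 120)`.
#' @param spacing Voxel spacing in mm, default 1 mm isotropic.
#' @param head_semiaxes Ellipsoid semi-axes (mm) of the head.
#' @param arch_coef Quartic coefficients `c(a0, a2, a4)` of the dental arch
#'   midline, y as a function of x (mm).
#' @param arch_halfspan Half extent of the arch in x (mm).
#' @param arch_wall_halfwidth Half thickness of the bony arch wall (mm).
#' @param mandible_z,maxilla_z z bands (mm, relative to head center) of the
#'   mandibular and maxillary bone walls; the tooth band sits between them.
#' @param tooth_count Number of teeth (>= 0), equally spaced in arc length.
#' @param tooth_radius Tooth cylinder radius (mm).
#' @param tooth_height Tooth cylinder height (mm); teeth span the occlusal
#'   band between mandible and maxilla.
#' @param root_canal_radius Radius (mm) of the soft-tissue canal inside each
#'   tooth (0 disables canals).
#' @param air_gap_thickness Thickness (mm) of the retro-arch air gap
#'   (0 disables it).
#' @param air_gap_offset Distance (mm) behind the arch midline at which the
#'   air gap starts.
#' @param air_gap_halfspan Half extent in x (mm) of the air gap.
#' @param hu Named numeric: noise-free HU per tissue
#'   (`air`, `soft`, `bone`, `tooth`); must satisfy air < soft < bone.
#' @param jitter_sd Standard deviation (HU) of optional Gaussian noise added
#'   to the HU volume (0 = noise free).
#' @param seed Integer seed controlling the jitter; phantoms are
#'   deterministic for a fixed seed.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(dim = c(160, 160, 120),
                           spacing = c(1, 1, 1),
                           head_semiaxes = c(70, 80, 55),
                           arch_coef = c(a0 = 40, a2 = -0.020, a4 = -1e-6),
                           arch_halfspan = 42,
                           arch_wall_halfwidth = 4,
                           mandible_z = c(-16, -2),
                           maxilla_z = c(10, 22),
                           tooth_count = 14,
                           tooth_radius = 3,
                           tooth_height = 12,
                           root_canal_radius = 0.8,
                           air_gap_thickness = 6,
                           air_gap_offset = 10,
                           air_gap_halfspan = 30,
                           hu = c(air = -1000, soft = 40, bone = 1200, tooth = 1800),
                           jitter_sd = 0,
                           seed = 1L) {
  p <- list(dim = as.integer(dim), spacing = check_spacing(spacing),
            head_semiaxes = as.numeric(head_semiaxes),
            arch_coef = as.numeric(arch_coef),
            arch_halfspan = arch_halfspan,
            arch_wall_halfwidth = arch_wall_halfwidth,
            mandible_z = as.numeric(mandible_z), maxilla_z = as.numeric(maxilla_z),
            tooth_count = as.integer(tooth_count), tooth_radius = tooth_radius,
            tooth_height = tooth_height, root_canal_radius = root_canal_radius,
            air_gap_thickness = air_gap_thickness,
            air_gap_offset = air_gap_offset,
            air_gap_halfspan = air_gap_halfspan,
            hu = hu, jitter_sd = jitter_sd, seed = as.integer(seed))
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  stopifnot(length(p$dim) == 3, all(p$dim >= 1))
  if (p$tooth_count < 0) stop("tooth_count must be >= 0")
  lens <- c(p$head_semiaxes, p$arch_wall_halfwidth, p$tooth_radius,
            p$tooth_height, p$arch_halfspan)
  if (any(lens <= 0)) stop("all lengths must be positive")
  if (p$root_canal_radius < 0 || p$air_gap_thickness < 0)
    stop("radii and thicknesses must be non-negative")
  if (p$root_canal_radius >= p$tooth_radius)
    stop("root_canal_radius must be smaller than tooth_radius")
  need <- c("air", "soft", "bone", "tooth")
  if (!all(need %in% names(p$hu))) stop("hu must name air, soft, bone, tooth")
  if (!(p$hu["air"] < p$hu["soft"] && p$hu["soft"] < p$hu["bone"]))
    stop("HU ordering must satisfy air < soft < bone")
  fov <- p$dim * p$spacing
  if (any(2 * p$head_semiaxes > fov))
    stop("head semi-axes exceed the field of view; enlarge the grid")
  invisible(p)
}

arch_y <- function(x, coef) coef[1] + coef[2] * x^2 + coef[3] * x^4
arch_dy <- function(x, coef) 2 * coef[2] * x + 4 * coef[3] * x^3

#' Arc length along the phantom arch
#'
#' Cumulative arc length of the quartic arch midline, by fine trapezoidal
#' integration of `sqrt(1 + y'(x)^2)`.
#'
#' @param coef Quartic coefficients `c(a0, a2, a4)`.
#' @param halfspan Half extent in x (mm).
#' @param n Number of integration samples.
#' @return List with `x`, `s` (cumulative arc length from the left end) and
#'   `total` length (mm).
#' @export
arch_arc_length <- function(coef, halfspan, n = 4001) {
  x <- seq(-halfspan, halfspan, length.out = n)
  g <- sqrt(1 + arch_dy(x, coef)^2)
  ds <- diff(x) * (g[-1] + g[-n]) / 2
  list(x = x, s = c(0, cumsum(ds)), total = sum(ds))
}

# x positions of tooth centers: equal arc-length intervals, centered
tooth_centers_x <- function(p) {
  if (p$tooth_count == 0) return(numeric(0))
  al <- arch_arc_length(p$arch_coef, p$arch_halfspan)
  s_target <- (seq_len(p$tooth_count) - 0.5) / p$tooth_count * al$total
  stats::approx(al$s, al$x, xout = s_target)$y
}

#' Generate a synthetic labeled head phantom
#'
#' Builds a paired HU volume and ground-truth label volume from
#' [phantom_params()]. Voxels are classified by their center coordinate.
#' Structures, from back to front of the painting order: soft-tissue head
#' ellipsoid, retro-arch air gap, bony arch walls (mandible and maxilla
#' bands), teeth (labeled bone, HU `hu["tooth"]`), root canals (soft).
#' Noise-free HU equals the configured HU of each tissue; optional Gaussian
#' jitter is seeded and reproducible.
#'
#' @param params A [phantom_params()] object.
#' @return List with elements `hu` ([hu_volume()]) and
#'   `labels` ([label_volume()], `ground_truth = TRUE`).
#' @export
generate_head_phantom <- function(params = phantom_params()) {
  p <- validate_phantom_params(params)
  nx <- p$dim[1]; ny <- p$dim[2]; nz <- p$dim[3]
  # world coords relative to head center (head centered in the grid)
  xs <- (seq_len(nx) - (nx + 1) / 2) * p$spacing[1]
  ys <- (seq_len(ny) - (ny + 1) / 2) * p$spacing[2]
  zs <- (seq_len(nz) - (nz + 1) / 2) * p$spacing[3]

  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)

  # xy masks shared by all z slices of a band
  r2xy <- (X / p$head_semiaxes[1])^2 + (Y / p$head_semiaxes[2])^2

  # distance in the axial plane to the arch midline (sampled curve)
  cs <- seq(-p$arch_halfspan, p$arch_halfspan, by = 0.25)
  cy <- arch_y(cs, p$arch_coef)
  d2 <- matrix(Inf, nx, ny)
  for (k in seq_along(cs)) {
    dk <- (X - cs[k])^2 + (Y - cy[k])^2
    d2 <- pmin(d2, dk)
  }
  wall_xy <- d2 <= p$arch_wall_halfwidth^2

  tooth_xy <- matrix(FALSE, nx, ny)
  canal_xy <- matrix(FALSE, nx, ny)
  tx <- tooth_centers_x(p)
  ty <- arch_y(tx, p$arch_coef)
  for (k in seq_along(tx)) {
    dk <- (X - tx[k])^2 + (Y - ty[k])^2
    tooth_xy <- tooth_xy | (dk <= p$tooth_radius^2)
    if (p$root_canal_radius > 0)
      canal_xy <- canal_xy | (dk <= p$root_canal_radius^2)
  }

  gap_xy <- matrix(FALSE, nx, ny)
  if (p$air_gap_thickness > 0) {
    ycurve <- matrix(arch_y(as.vector(X), p$arch_coef), nx, ny)
    gap_xy <- abs(X) <= p$air_gap_halfspan &
      Y <= ycurve - p$air_gap_offset &
      Y > ycurve - p$air_gap_offset - p$air_gap_thickness
  }

  tooth_z <- c(p$mandible_z[2], p$mandible_z[2] + p$tooth_height)

  codes <- label_codes()
  labels <- array(codes[["air"]], dim = p$dim)
  hu <- array(p$hu[["air"]], dim = p$dim)

  for (iz in seq_len(nz)) {
    z <- zs[iz]
    head <- r2xy + (z / p$head_semiaxes[3])^2 <= 1
    lab <- matrix(codes[["air"]], nx, ny)
    huz <- matrix(p$hu[["air"]], nx, ny)
    lab[head] <- codes[["soft"]]; huz[head] <- p$hu[["soft"]]
    in_tooth_band <- z >= tooth_z[1] && z < tooth_z[2]
    if (in_tooth_band && p$air_gap_thickness > 0) {
      m <- head & gap_xy
      lab[m] <- codes[["air"]]; huz[m] <- p$hu[["air"]]
    }
    in_wall <- (z >= p$mandible_z[1] && z < p$mandible_z[2]) ||
      (z >= p$maxilla_z[1] && z < p$maxilla_z[2])
    if (in_wall) {
      m <- head & wall_xy
      lab[m] <- codes[["bone"]]; huz[m] <- p$hu[["bone"]]
    }
    if (in_tooth_band && p$tooth_count > 0) {
      m <- head & tooth_xy
      lab[m] <- codes[["bone"]]; huz[m] <- p$hu[["tooth"]]
      if (p$root_canal_radius > 0) {
        m <- head & canal_xy
        lab[m] <- codes[["soft"]]; huz[m] <- p$hu[["soft"]]
      }
    }
    labels[, , iz] <- lab
    hu[, , iz] <- huz
  }

  if (p$jitter_sd > 0) {
    hu <- hu + with_local_seed(p$seed,
      array(stats::rnorm(length(hu), sd = p$jitter_sd), dim = dim(hu)))
  }

  origin <- -(p$dim + 1) / 2 * p$spacing + p$spacing  # center of voxel [1,1,1]
  list(hu = hu_volume(hu, p$spacing, origin),
       labels = label_volume(labels, p$spacing, origin, ground_truth = TRUE))
}

# evaluate expr with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Analytic volumes (mm^3) of the phantom's constituent solids
#'
#' Closed-form (up to 1-D quadrature for the arc length) volumes of the
#' solids making up the default phantom construction, used to sanity-check
#' voxelization: the dilated arch walls (`L * 2w + pi w^2` per band times the
#' band height), tooth and canal cylinders, the retro-arch air slab and the
#' head ellipsoid.
#'
#' @param params A [phantom_params()] object.
#' @return Named list of volumes in mm^3: `ellipsoid`, `arch_wall`, `teeth`,
#'   `canals`, `air_gap`, and the expected net per-label volumes `bone`,
#'   `soft`, `air_inside_grid`.
#' @export
phantom_analytic_volumes <- function(params = phantom_params()) {
  p <- validate_phantom_params(params)
  a <- p$head_semiaxes
  v_ell <- 4 / 3 * pi * a[1] * a[2] * a[3]
  L <- arch_arc_length(p$arch_coef, p$arch_halfspan)$total
  w <- p$arch_wall_halfwidth
  band_h <- diff(p$mandible_z) + diff(p$maxilla_z)
  v_wall <- (L * 2 * w + pi * w^2) * band_h
  v_teeth <- p$tooth_count * pi * p$tooth_radius^2 * p$tooth_height
  v_canal <- p$tooth_count * pi * p$root_canal_radius^2 * p$tooth_height
  v_gap <- p$air_gap_thickness * 2 * p$air_gap_halfspan * p$tooth_height
  grid <- prod(p$dim * p$spacing)
  list(ellipsoid = v_ell, arch_wall = v_wall, teeth = v_teeth,
       canals = v_canal, air_gap = v_gap,
       bone = v_wall + v_teeth - v_canal,
       soft = v_ell - v_wall - v_teeth + v_canal - v_gap,
       air_inside_grid = grid - v_ell + v_gap)
}
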