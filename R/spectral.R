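# Embedded mass-attenuation data (cm^2/g) at standard node energies (keV),
# ICRU-44-style soft tissue and cortical bone, plus elemental aluminium for
# tube filtration. Nodes follow the usual published grids (NIST-style);
# linear attenuation is mass attenuation times density, converted to mm^-1.
.att_energies <- c(20, 30, 40, 50, 60, 80, 100, 150)
.att_data <- list(
  soft = list(mu_rho = c(0.8205, 0.3783, 0.2685, 0.2262,
                         0.2048, 0.1823, 0.1693, 0.1492),
              density = 1.06),
  bone = list(mu_rho = c(4.001, 1.331, 0.6655, 0.4242,
                         0.3148, 0.2229, 0.1855, 0.1480),
              density = 1.92),
  aluminium = list(mu_rho = c(3.441, 1.128, 0.5685, 0.3681,
                              0.2778, 0.2018, 0.1704, 0.1378),
                   density = 2.699))

#' Attenuation table for the two basis materials
#'
#' Linear attenuation coefficients mu(E) in mm^-1 for soft tissue
#' (density 1.06 g/cm^3) and cortical bone (1.92 g/cm^3) on the embedded
#' 20-150 keV node grid, interpolated log-log between nodes.
#'
#' @param materials Materials to include (default the two basis materials).
#' @return An `attenuation_table`: list of per-material node energies (keV)
#'   and mu (mm^-1).
#' @export
attenuation_table <- function(materials = c("soft", "bone")) {
  stopifnot(all(materials %in% names(.att_data)))
  tabs <- lapply(materials, function(m) {
    d <- .att_data[[m]]
    list(energies = .att_energies, mu = d$mu_rho * d$density / 10)  # mm^-1
  })
  names(tabs) <- materials
  structure(tabs, class = "attenuation_table")
}

#' Linear attenuation coefficient of a material
#'
#' Log-log interpolation of the embedded attenuation nodes; exact at nodes.
#'
#' @param material `"soft"`, `"bone"` or `"aluminium"`.
#' @param energies Energies in keV, all within the 20-150 keV table span.
#' @param tables An [attenuation_table()] containing the material (defaults
#'   to the embedded tables).
#' @return Numeric vector of mu in mm^-1.
#' @export
attenuation_mu <- function(material, energies,
                           tables = attenuation_table(names(.att_data))) {
  if (!material %in% names(tables)) stop("unknown material: ", material)
  tab <- tables[[material]]
  if (any(energies < min(tab$energies) | energies > max(tab$energies)))
    stop(sprintf("energy outside table span [%g, %g] keV",
                 min(tab$energies), max(tab$energies)))
  exp(stats::approx(log(tab$energies), log(tab$mu), xout = log(energies))$y)
}

#' Filtered tungsten tube spectrum
#'
#' Kramers bremsstrahlung model: fluence proportional to `(kvp - E) / E` on
#' bin centers over `[e_min, kvp]`, attenuated by `filtration_mm_al` mm of
#' aluminium via the embedded Al attenuation curve, clipped at zero above the
#' tube voltage, and renormalized to sum 1. Characteristic lines are not
#' modeled. A single-bin call yields a monoenergetic spectrum at the bin
#' center.
#'
#' @param kvp Tube voltage in kV (40-150).
#' @param filtration_mm_al Aluminium filtration thickness in mm (>= 0).
#' @param n_bins Number of energy bins (>= 1).
#' @param e_min Lower end of the sampled energy range (keV, default 20, the
#'   attenuation table floor).
#' @param n0 Reference incident photon count per detector pixel.
#' @return A `spectrum`: list with `energies` (bin centers, keV), `weights`
#'   (sum 1), `n0`, `kvp`.
#' @export
tungsten_spectrum <- function(kvp = 120, filtration_mm_al = 2.5, n_bins = 64,
                              e_min = 20, n0 = 1e5) {
  if (kvp < 40 || kvp > 150) stop("kvp must lie in [40, 150]")
  if (filtration_mm_al < 0) stop("filtration must be non-negative")
  if (n_bins < 1) stop("n_bins must be >= 1")
  edges <- seq(e_min, kvp, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w <- pmax(kvp - centers, 0) / centers
  if (filtration_mm_al > 0)
    w <- w * exp(-attenuation_mu("aluminium", centers) * filtration_mm_al)
  if (sum(w) <= 0) stop("degenerate spectrum: all weights zero")
  xray_spectrum(centers, w / sum(w), n0 = n0, kvp = kvp)
}

#' Construct an X-ray spectrum from tabulated energies and weights
#'
#' Escape hatch for measured tube spectra (e.g. read from a two-column
#' `energy,weight` CSV via [read_spectrum_csv()]).
#'
#' @param energies Strictly increasing bin centers (keV).
#' @param weights Non-negative fluence weights; renormalized to sum 1.
#' @param n0 Reference incident photon count per pixel.
#' @param kvp Nominal tube voltage (keV); defaults to `max(energies)`.
#' @return A `spectrum` object.
#' @export
xray_spectrum <- function(energies, weights, n0 = 1e5, kvp = max(energies)) {
  stopifnot(length(energies) == length(weights), length(energies) >= 1)
  if (is.unsorted(energies, strictly = TRUE))
    stop("energies must be strictly increasing")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (any(energies > kvp + 1e-9)) stop("energies must not exceed the tube voltage")
  s <- sum(weights)
  if (s <= 0) stop("weights must not all be zero")
  structure(list(energies = as.numeric(energies),
                 weights = as.numeric(weights) / s,
                 n0 = n0, kvp = kvp), class = "spectrum")
}

#' Read a tabulated spectrum from CSV
#'
#' @param path CSV with columns `energy` (keV) and `weight`.
#' @inheritParams xray_spectrum
#' @return A `spectrum` object.
#' @export
read_spectrum_csv <- function(path, n0 = 1e5) {
  df <- utils::read.csv(path)
  if (!all(c("energy", "weight") %in% names(df)))
    stop("spectrum CSV needs 'energy' and 'weight' columns")
  xray_spectrum(df$energy, df$weight, n0 = n0)
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("spectrum: %d bins, %.0f-%.0f keV, mean %.1f keV, N0 = %g\n",
              length(x$energies), min(x$energies), max(x$energies),
              sum(x$energies * x$weights), x$n0))
  invisible(x)
}

# plain numeric matrix: drop class and image attributes
as_plain_matrix <- function(m) {
  m <- unclass(m)
  attributes(m) <- list(dim = dim(m))
  m
}

check_peti_pair <- function(t_b, t_s) {
  if (!identical(dim(t_b), dim(t_s)))
    stop("bone and soft thickness images have mismatched shapes")
  ga <- attr(t_b, "geometry_id"); gb <- attr(t_s, "geometry_id")
  if (!is.null(ga) && !is.null(gb) && !is.na(ga) && !is.na(gb) &&
      !identical(ga, gb))
    stop("thickness images come from different geometries: ", ga, " vs ", gb)
  invisible(NULL)
}

#' Synthesize a conventional polychromatic panoramic radiograph (PAN)
#'
#' Beer-Lambert expected photon counts per pixel:
#' `N = N0 * sum_j w_j exp(-mu_bone(E_j) t_b - mu_soft(E_j) t_s)`,
#' with the companion attenuation view `-log(N / N0)` (dense structures
#' bright, as in a radiograph). No noise is sampled: counts are expectations
#' under an ideal detector.
#'
#' @param t_b,t_s Bone and soft-tissue [material_thickness_image()]s (mm),
#'   same shape and geometry.
#' @param spectrum A [xray_spectrum()] or [tungsten_spectrum()].
#' @param tables An [attenuation_table()] with `bone` and `soft`.
#' @return A `pan_image`: list with `counts`, `attenuation`, `n0`,
#'   `geometry_id`.
#' @export
synthesize_pan <- function(t_b, t_s, spectrum = tungsten_spectrum(),
                           tables = attenuation_table()) {
  check_peti_pair(t_b, t_s)
  mu_b <- attenuation_mu("bone", spectrum$energies, tables)
  mu_s <- attenuation_mu("soft", spectrum$energies, tables)
  counts <- matrix(0, nrow(t_b), ncol(t_b))
  tb <- as_plain_matrix(t_b); ts <- as_plain_matrix(t_s)
  for (j in seq_along(spectrum$energies))
    counts <- counts + spectrum$weights[j] * exp(-mu_b[j] * tb - mu_s[j] * ts)
  counts <- spectrum$n0 * counts
  structure(list(counts = counts,
                 attenuation = pmax(-log(counts / spectrum$n0), 0),
                 n0 = spectrum$n0,
                 geometry_id = attr(t_b, "geometry_id")),
            class = "pan_image")
}

#' @export
print.pan_image <- function(x, ...) {
  cat(sprintf("PAN: %d x %d px, counts %.3g-%.3g (N0 = %g)\n",
              nrow(x$counts), ncol(x$counts), min(x$counts), max(x$counts),
              x$n0))
  invisible(x)
}

#' Synthesize a panoramic virtual monoenergetic image (PVMI)
#'
#' Monoenergetic attenuation line integrals
#' `A = mu_bone(E0) t_b + mu_soft(E0) t_s` — the image as if acquired with a
#' monochromatic source at `E0`. The study's preset evaluation energies are
#' 40 and 60 keV.
#'
#' @inheritParams synthesize_pan
#' @param energy Virtual energy E0 in keV (within the table span).
#' @return A `mono_image`: matrix of A (dimensionless) with attributes
#'   `energy` and `geometry_id`.
#' @export
synthesize_pvmi <- function(t_b, t_s, energy, tables = attenuation_table()) {
  check_peti_pair(t_b, t_s)
  a <- attenuation_mu("bone", energy, tables) * as_plain_matrix(t_b) +
    attenuation_mu("soft", energy, tables) * as_plain_matrix(t_s)
  structure(a, energy = energy, geometry_id = attr(t_b, "geometry_id"),
            class = c("mono_image", "matrix", "array"))
}

#' @export
print.mono_image <- function(x, ...) {
  cat(sprintf("PVMI @ %g keV: %d x %d px, A in [%.3g, %.3g]\n",
              attr(x, "energy"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Recover basis-material thicknesses from two monoenergetic images
#'
#' Exact inverse of the two-energy PVMI forward model: solves the per-pixel
#' 2x2 linear system
#' `[A(E1); A(E2)] = [[mu_b(E1), mu_s(E1)]; [mu_b(E2), mu_s(E2)]] [t_b; t_s]`.
#'
#' @param mono_a,mono_b `mono_image`s at two different energies.
#' @param tables An [attenuation_table()].
#' @return List with `bone` and `soft` [material_thickness_image()]s (mm).
#' @export
recover_thickness <- function(mono_a, mono_b, tables = attenuation_table()) {
  ea <- attr(mono_a, "energy"); eb <- attr(mono_b, "energy")
  if (!identical(dim(mono_a), dim(mono_b))) stop("mono image shapes differ")
  m11 <- attenuation_mu("bone", ea, tables)
  m12 <- attenuation_mu("soft", ea, tables)
  m21 <- attenuation_mu("bone", eb, tables)
  m22 <- attenuation_mu("soft", eb, tables)
  det <- m11 * m22 - m12 * m21
  if (abs(det) < 1e-12 * max(abs(c(m11 * m22, m12 * m21))) || ea == eb)
    stop("singular decomposition matrix: energies ", ea, " and ", eb,
         " keV do not separate the basis materials")
  a1 <- as_plain_matrix(mono_a); a2 <- as_plain_matrix(mono_b)
  tb <- (m22 * a1 - m12 * a2) / det
  ts <- (-m21 * a1 + m11 * a2) / det
  gid <- attr(mono_a, "geometry_id")
  list(bone = structure(tb, material = "bone", geometry_id = gid,
                        class = c("material_thickness_image", "matrix", "array")),
       soft = structure(ts, material = "soft", geometry_id = gid,
                        class = c("material_thickness_image", "matrix", "array")))
}

#' Window an image for 8-bit display
#'
#' Linear map of `[level - width/2, level + width/2]` to 0..255 with
#' clipping. In auto mode the window is taken from the 1st and 99th
#' percentiles; a degenerate (constant) window is widened to 1 so a constant
#' image maps to mid-gray.
#'
#' @param img Numeric matrix (or `pan_image` attenuation / `mono_image`).
#' @param level,width Window center and width; both `NULL` for auto mode.
#' @return Integer matrix of display values in 0..255.
#' @export
window_image <- function(img, level = NULL, width = NULL) {
  if (inherits(img, "pan_image")) img <- img$attenuation
  img <- unclass(img)
  if (!all(is.finite(img))) stop("image must be finite")
  if (is.null(level) || is.null(width)) {
    q <- stats::quantile(img, c(0.01, 0.99), names = FALSE)
    level <- (q[1] + q[2]) / 2
    width <- q[2] - q[1]
    if (width <= 0) width <- 1
  }
  if (width <= 0) stop("window width must be positive")
  out <- round((img - (level - width / 2)) / width * 255)
  out[out < 0] <- 0L
  out[out > 255] <- 255L
  storage.mode(out) <- "integer"
  out
}
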