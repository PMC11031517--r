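# A smaller phantom used by most tests; same structure classes as the
# default, scaled to desk size for speed.
tiny_phantom_params <- function(...) {
  defaults <- list(dim = c(100, 100, 80), spacing = c(1, 1, 1),
                   head_semiaxes = c(42, 46, 34),
                   arch_coef = c(a0 = 24, a2 = -0.025, a4 = -2e-6),
                   arch_halfspan = 26, arch_wall_halfwidth = 3,
                   mandible_z = c(-12, -2), maxilla_z = c(8, 16),
                   tooth_count = 10, tooth_radius = 2.2, tooth_height = 10,
                   root_canal_radius = 0.7,
                   air_gap_thickness = 4, air_gap_offset = 7,
                   air_gap_halfspan = 18)
  do.call(phantom_params, utils::modifyList(defaults, list(...)))
}

tiny_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_head_phantom(tiny_phantom_params())
    cache
  }
})

# single-material box volume: labels `inside` within the index ranges
box_labels <- function(dim = c(20, 20, 20), spacing = c(1, 1, 1),
                       inside = "bone", xr = NULL, yr = NULL, zr = NULL) {
  codes <- label_codes()
  lab <- array(codes[["air"]], dim = dim)
  xr <- if (is.null(xr)) seq_len(dim[1]) else xr
  yr <- if (is.null(yr)) seq_len(dim[2]) else yr
  zr <- if (is.null(zr)) seq_len(dim[3]) else zr
  lab[xr, yr, zr] <- codes[[inside]]
  label_volume(lab, spacing)
}

# geometry with a single explicit ray (for projector fixtures)
single_ray_geometry <- function(origin, direction) {
  direction <- direction / sqrt(sum(direction^2))
  g <- list(stations = 0, arch_points = matrix(origin, 1, 3),
            normals = matrix(c(1, 0), 1, 2),
            source_points = matrix(origin, 1, 3),
            detector_base = matrix(origin + direction, 1, 3),
            n_cols = 1L, n_rows = 1L, row_pitch = 1,
            source_to_arch = 1, arch_to_detector = 1, z_arch = origin[3],
            id = "single-ray")
  class(g) <- "pan_geometry"
  rays <- list(origins = matrix(origin, 1, 3),
               directions = matrix(direction, 1, 3))
  attr(g, "rays") <- rays
  g
}

# thickness image pair on a shared fake geometry id
peti_pair <- function(tb, ts, id = "fixture") {
  list(bone = material_thickness_image(tb, "bone", id),
       soft = material_thickness_image(ts, "soft", id))
}
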