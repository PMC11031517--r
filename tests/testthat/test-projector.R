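# independent analytic chord length of a ray through an axis-aligned box
box_chord <- function(origin, direction, bmin, bmax) {
  direction <- direction / sqrt(sum(direction^2))
  tmin <- -Inf; tmax <- Inf
  for (a in 1:3) {
    if (abs(direction[a]) < 1e-14) {
      if (origin[a] <= bmin[a] || origin[a] >= bmax[a]) return(0)
    } else {
      tt <- sort(c((bmin[a] - origin[a]) / direction[a],
                   (bmax[a] - origin[a]) / direction[a]))
      tmin <- max(tmin, tt[1]); tmax <- min(tmax, tt[2])
    }
  }
  max(tmax - tmin, 0)
}

test_that("empty volumes project to zero thickness", {
  lab <- box_labels(c(10, 10, 10), inside = "air")
  g <- single_ray_geometry(c(-50, 0, 0), c(1, 0, 0))
  expect_equal(as.vector(forward_project(lab, g, "bone")), 0)
  expect_equal(as.vector(forward_project(lab, g, "soft")), 0)
  expect_error(forward_project(lab, g, "enamel"), "unknown material")
})

test_that("perpendicular ray through a homogeneous slab measures its exact width", {
  # 7 mm bone slab (indices 3..9 at 1 mm) inside a 20 mm cube of air
  lab <- box_labels(c(20, 20, 20), inside = "bone", xr = 3:9)
  g <- single_ray_geometry(c(-100, 0, 0), c(1, 0, 0))
  t <- forward_project(lab, g, "bone")
  expect_equal(as.vector(t), 7, tolerance = 1e-6)
  # anisotropic spacing scales the chord
  lab2 <- box_labels(c(20, 20, 20), spacing = c(0.67, 1, 1),
                     inside = "bone", xr = 3:9)
  t2 <- forward_project(lab2, g, "bone")
  expect_equal(as.vector(t2), 7 * 0.67, tolerance = 1e-6)
})

test_that("Siddon projection equals analytic chords for oblique rays through boxes", {
  spacing <- c(1, 0.8, 1.25)
  lab <- box_labels(c(12, 15, 9), spacing = spacing, inside = "soft",
                    xr = 4:9, yr = 3:12, zr = 2:7)
  origin <- -(dim(lab$voxels) - 1) / 2 * spacing
  # analytic box of the soft region (voxel index range to world extents)
  bmin <- origin + (c(4, 3, 2) - 1) * spacing - spacing / 2
  bmax <- origin + (c(9, 12, 7) - 1) * spacing + spacing / 2
  set.seed(7)
  for (k in 1:25) {
    src <- c(-80, runif(1, -6, 6), runif(1, -4, 4))
    tgt <- c(80, runif(1, -6, 6), runif(1, -4, 4))
    d <- (tgt - src) / sqrt(sum((tgt - src)^2))
    g <- single_ray_geometry(src, d)
    got <- as.vector(forward_project(lab, g, "soft"))
    expect_equal(got, box_chord(src, d, bmin, bmax), tolerance = 1e-6)
  }
})

test_that("exact intersections on a 3-voxel grid match hand-computed chords", {
  lab <- label_volume(array(c(2L, 1L, 0L), dim = c(3, 1, 1)), c(2, 2, 2))
  # voxels span x in [-3,-1], [-1,1], [1,3]; bone, soft, air
  g <- single_ray_geometry(c(-10, 0, 0), c(1, 0, 0))
  pr <- project_all_materials(lab, g)
  expect_equal(as.vector(pr$bone), 2, tolerance = 1e-9)
  expect_equal(as.vector(pr$soft), 2, tolerance = 1e-9)
  expect_equal(as.vector(pr$air), 2, tolerance = 1e-9)
  # 45-degree ray in xy misses the single-voxel-thick y extent partly
  d <- c(1, 1, 0) / sqrt(2)
  g2 <- single_ray_geometry(c(-4, -4 , 0), d)
  got <- project_all_materials(lab, g2)
  tot <- as.vector(got$air) + as.vector(got$soft) + as.vector(got$bone)
  expect_equal(tot, box_chord(c(-4, -4, 0), d, c(-3, -1, -1), c(3, 1, 1)),
               tolerance = 1e-9)
})

test_that("path length is conserved across materials on random phantoms", {
  ph <- tiny_phantom()
  arch <- fit_dental_arch(ph$labels)
  geom <- build_trajectory(arch, n_cols = 60, n_rows = 40)
  pr <- project_all_materials(ph$labels, geom)
  tot <- unclass(pr$air) + unclass(pr$soft) + unclass(pr$bone)
  chord <- ray_chord_lengths(ph$labels, geom)
  expect_lt(max(abs(tot - chord)), 1e-8)
  expect_true(all(unclass(pr$bone) >= 0))
  expect_true(all(tot <= max(chord) + 1e-8))
})

test_that("projection is additive over disjoint masks", {
  # split the phantom's bone into two disjoint halves; thicknesses add
  ph <- tiny_phantom()
  lab <- ph$labels$voxels
  bone <- label_codes()[["bone"]]; soft <- label_codes()[["soft"]]
  half <- dim(lab)[3] %/% 2
  labA <- lab; labA[, , seq_len(half)][labA[, , seq_len(half)] == bone] <- soft
  labB <- lab; labB[, , -seq_len(half)][labB[, , -seq_len(half)] == bone] <- soft
  vA <- label_volume(labA, ph$labels$spacing, ph$labels$origin)
  vB <- label_volume(labB, ph$labels$spacing, ph$labels$origin)
  arch <- fit_dental_arch(ph$labels)
  geom <- build_trajectory(arch, n_cols = 40, n_rows = 30)
  t_all <- forward_project(ph$labels, geom, "bone")
  t_A <- forward_project(vA, geom, "bone")
  t_B <- forward_project(vB, geom, "bone")
  expect_equal(unclass(t_A) + unclass(t_B), unclass(t_all), tolerance = 1e-9)
})

test_that("a symmetric phantom yields a left-right mirrored bone PETI", {
  p <- tiny_phantom_params()
  ph <- generate_head_phantom(p)
  # symmetric analytic arch (generator curve), symmetric trajectory
  xs <- seq(-p$arch_halfspan, p$arch_halfspan, by = 0.1)
  arch <- arch_curve(xs, p$arch_coef[1] + p$arch_coef[2] * xs^2 +
                       p$arch_coef[3] * xs^4, z_arch = -7)
  geom <- build_trajectory(arch, n_cols = 81, n_rows = 41)
  tb <- forward_project(ph$labels, geom, "bone")
  mirrored <- tb[, rev(seq_len(ncol(tb)))]
  expect_lt(max(abs(tb - mirrored)), 0.35)
  expect_gt(max(tb), 1)
})
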