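test_that("spectra are normalized, bounded by the tube voltage, and degenerate cleanly", {
  s <- tungsten_spectrum(kvp = 120, filtration_mm_al = 2.5, n_bins = 64)
  expect_equal(sum(s$weights), 1, tolerance = 1e-12)
  expect_true(all(s$weights >= 0))
  expect_true(all(s$energies < 120))
  expect_true(!is.unsorted(s$energies, strictly = TRUE))

  # single bin centered at 60 keV for a 100 kV tube sampled from 20 keV
  s1 <- tungsten_spectrum(kvp = 100, filtration_mm_al = 0, n_bins = 1)
  expect_equal(s1$energies, 60)
  expect_equal(s1$weights, 1)

  expect_error(tungsten_spectrum(kvp = 30), "kvp")
  expect_error(tungsten_spectrum(kvp = 120, filtration_mm_al = -1), "negative")
  expect_error(xray_spectrum(c(40, 40), c(1, 1)), "strictly increasing")
})

test_that("mean energy matches a fine-grid re-integration of Kramers x Al transmission", {
  kvp <- 120; filt <- 2.5; n <- 64
  s <- tungsten_spectrum(kvp, filt, n)
  # independent fine-grid oracle at 10x the binning
  edges <- seq(20, kvp, length.out = 10 * n + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  mu_al <- attenuation_mu("aluminium", centers)
  w <- (kvp - centers) / centers * exp(-mu_al * filt)
  mean_fine <- sum(centers * w) / sum(w)
  expect_lt(abs(sum(s$energies * s$weights) - mean_fine), 0.5)
})

test_that("attenuation lookups are exact at nodes, ordered, and log-log monotone", {
  tab <- attenuation_table()
  expect_equal(attenuation_mu("soft", 60), tab$soft$mu[tab$soft$energies == 60])
  expect_equal(attenuation_mu("bone", 40), tab$bone$mu[tab$bone$energies == 40])
  expect_gt(attenuation_mu("bone", 40), attenuation_mu("soft", 40))
  ee <- seq(30, 150, by = 5)
  expect_true(all(attenuation_mu("bone", ee) > attenuation_mu("soft", ee)))
  expect_true(all(diff(attenuation_mu("soft", ee)) <= 0))
  # off-node value lies between its bracketing nodes (40 and 50 keV) and
  # equals the direct log-log interpolation formula
  mu45 <- attenuation_mu("soft", 45)
  mu40 <- attenuation_mu("soft", 40); mu50 <- attenuation_mu("soft", 50)
  expect_true(mu45 < mu40 && mu45 > mu50)
  direct <- exp(log(mu40) + (log(45) - log(40)) / (log(50) - log(40)) *
                  (log(mu50) - log(mu40)))
  expect_equal(mu45, direct, tolerance = 1e-12)
  expect_error(attenuation_mu("soft", 10), "outside")
  expect_error(attenuation_mu("soft", 200), "outside")
})

test_that("vacuum thickness gives N = N0 and PVMI A = 0", {
  z <- peti_pair(matrix(0, 4, 5), matrix(0, 4, 5))
  s <- tungsten_spectrum()
  pan <- synthesize_pan(z$bone, z$soft, s)
  expect_equal(pan$counts, matrix(s$n0, 4, 5))
  expect_equal(pan$attenuation, matrix(0, 4, 5))
  expect_equal(unclass(synthesize_pvmi(z$bone, z$soft, 60)),
               matrix(0, 4, 5), ignore_attr = TRUE)
})

test_that("a single-bin PAN equals the monoenergetic forward model", {
  set.seed(11)
  tb <- matrix(runif(30, 0, 12), 5, 6)
  ts <- matrix(runif(30, 0, 120), 5, 6)
  pp <- peti_pair(tb, ts)
  s1 <- xray_spectrum(60, 1)
  pan <- synthesize_pan(pp$bone, pp$soft, s1)
  pvmi <- synthesize_pvmi(pp$bone, pp$soft, 60)
  expect_lt(max(abs(pan$attenuation - unclass(pvmi))), 1e-12)
})

test_that("two-bin Beer-Lambert matches independent scalar arithmetic", {
  pp <- peti_pair(matrix(1), matrix(10))  # 1 mm bone, 10 mm soft
  s <- xray_spectrum(c(40, 60), c(0.5, 0.5), n0 = 1e5)
  pan <- synthesize_pan(pp$bone, pp$soft, s)
  tab <- attenuation_table()
  mu_b <- tab$bone$mu[tab$bone$energies %in% c(40, 60)]
  mu_s <- tab$soft$mu[tab$soft$energies %in% c(40, 60)]
  hand <- 1e5 * (0.5 * exp(-mu_b[1] * 1 - mu_s[1] * 10) +
                   0.5 * exp(-mu_b[2] * 1 - mu_s[2] * 10))
  expect_equal(as.vector(pan$counts), hand, tolerance = 1e-12)
})

test_that("PVMI is linear in thickness and matches a direct table lookup", {
  pp <- peti_pair(matrix(1), matrix(10))
  a60 <- synthesize_pvmi(pp$bone, pp$soft, 60)
  tab <- attenuation_table()
  expect_equal(as.vector(a60),
               tab$bone$mu[tab$bone$energies == 60] * 1 +
                 tab$soft$mu[tab$soft$energies == 60] * 10,
               tolerance = 1e-12)
  pp2 <- peti_pair(matrix(2), matrix(20))
  expect_equal(2 * as.vector(a60),
               as.vector(synthesize_pvmi(pp2$bone, pp2$soft, 60)),
               tolerance = 1e-12)
  expect_error(synthesize_pvmi(pp$bone, pp$soft, 500), "outside")
  expect_error(synthesize_pvmi(pp$bone, material_thickness_image(
    matrix(0, 2, 2), "soft", "fixture"), 60), "mismatched")
})

test_that("two-energy decomposition round-trips random thickness maps", {
  set.seed(3)
  tb <- matrix(runif(200, 0, 15), 10, 20)
  ts <- matrix(runif(200, 0, 150), 10, 20)
  pp <- peti_pair(tb, ts)
  a40 <- synthesize_pvmi(pp$bone, pp$soft, 40)
  a60 <- synthesize_pvmi(pp$bone, pp$soft, 60)
  rec <- recover_thickness(a40, a60)
  expect_lt(max(abs(unclass(rec$bone) - tb)), 1e-9)
  expect_lt(max(abs(unclass(rec$soft) - ts)), 1e-9)

  z <- peti_pair(matrix(0, 3, 3), matrix(0, 3, 3))
  rz <- recover_thickness(synthesize_pvmi(z$bone, z$soft, 40),
                          synthesize_pvmi(z$bone, z$soft, 60))
  expect_equal(unclass(rz$bone), matrix(0, 3, 3), ignore_attr = TRUE)

  expect_error(recover_thickness(a40, a40), "singular")
})

test_that("attenuation is monotone in thickness and energy; beam hardening has the right sign", {
  pp1 <- peti_pair(matrix(2), matrix(30))
  pp2 <- peti_pair(matrix(2.5), matrix(30))
  s <- tungsten_spectrum()
  expect_gt(synthesize_pan(pp1$bone, pp1$soft, s)$counts,
            synthesize_pan(pp2$bone, pp2$soft, s)$counts)
  expect_lt(as.vector(synthesize_pvmi(pp1$bone, pp1$soft, 60)),
            as.vector(synthesize_pvmi(pp2$bone, pp2$soft, 60)))
  # 40 keV attenuation is at least the 60 keV attenuation, pixelwise
  set.seed(5)
  tb <- matrix(runif(50, 0, 10), 5, 10); ts <- matrix(runif(50, 0, 80), 5, 10)
  pp <- peti_pair(tb, ts)
  expect_true(all(unclass(synthesize_pvmi(pp$bone, pp$soft, 40)) >=
                    unclass(synthesize_pvmi(pp$bone, pp$soft, 60))))
  # effective attenuation per mm decreases with depth for a polychromatic
  # beam and is constant for a single-bin one
  depth <- c(10, 50, 100, 200)
  eff <- vapply(depth, function(t) {
    pp <- peti_pair(matrix(0), matrix(t))
    synthesize_pan(pp$bone, pp$soft, s)$attenuation / t
  }, numeric(1))
  expect_true(all(diff(eff) < 0))
  eff1 <- vapply(depth, function(t) {
    pp <- peti_pair(matrix(0), matrix(t))
    synthesize_pan(pp$bone, pp$soft, xray_spectrum(60, 1))$attenuation / t
  }, numeric(1))
  expect_equal(max(eff1) - min(eff1), 0, tolerance = 1e-12)
})

test_that("windowing maps level to mid-gray and clips outside the window", {
  img <- matrix(c(-10, 0, 5, 10, 20, 100), 2, 3)
  w <- window_image(img, level = 5, width = 10)
  expect_equal(w[img == 5], 128)
  expect_true(all(w[img < 0] == 0))
  expect_true(all(w[img > 10] == 255))
  const <- window_image(matrix(7, 3, 3))
  expect_true(all(const == 128))
  expect_error(window_image(img, level = 0, width = -1), "positive")
})
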