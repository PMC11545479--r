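test_that("texture generator amplitude calibration matches the closed form", {
  # single band: total RMS = h1/(2*sqrt(2)) (RMS of a sinusoid ensemble
  # rescaled to the equivalent peak-to-valley convention)
  p <- texture_params(h1 = 2.7, L1 = 939, h2 = 0, L2 = 98.5)
  hm <- make_surface_texture(p, size = 256, pixel_size = 20, seed = 1)
  expect_rel(sqrt(mean(unclass(hm)^2)), 2.7 / (2 * sqrt(2)), 0.02)

  # zero amplitudes give a flat map
  p0 <- texture_params(h1 = 0, L1 = 939, h2 = 0, L2 = 98.5)
  hm0 <- make_surface_texture(p0, size = 256, pixel_size = 20, seed = 1)
  expect_true(all(unclass(hm0) == 0))

  # determinism given the seed
  a <- make_surface_texture(p, size = 256, pixel_size = 20, seed = 7)
  b <- make_surface_texture(p, size = 256, pixel_size = 20, seed = 7)
  expect_identical(unclass(a)[, ], unclass(b)[, ])

  # band-filtered RMS calibration holds per band on two-band textures
  ctrl <- preset("control")$texture
  hm2 <- make_surface_texture(ctrl, size = 256, pixel_size = 20, seed = 2)
  bands <- decompose_bands(hm2, 300)
  expect_rel(sqrt(mean(unclass(bands$low)^2)), 2.7 / (2 * sqrt(2)), 0.05)
  expect_rel(sqrt(mean(unclass(bands$high)^2)), 0.9 / (2 * sqrt(2)), 0.05)

  # unresolvable period is a parameter error
  expect_error(
    make_surface_texture(texture_params(1, 2000, 1, 20), size = 128,
                         pixel_size = 10),
    class = "rbcnano_parameter_error")
})

test_that("cell-scene generator composes classes and geometry as labelled", {
  sc <- make_cell_scene(composition_params(100, 0, 0), n_cells = 5, seed = 1)
  tr <- scene_truth(sc)
  expect_equal(nrow(tr), 5)
  expect_true(all(tr$label == "discocyte"))

  # geometric label consistency, checked against the rendered map
  sc3 <- make_cell_scene(composition_params(40, 40, 20), n_cells = 10, seed = 2)
  tr3 <- scene_truth(sc3)
  px_um <- attr(sc3, "pixel_size") / 1000
  z <- unclass(sc3)
  for (i in seq_len(nrow(tr3))) {
    ci <- tr3$x_um[i] / px_um
    cj <- tr3$y_um[i] / px_um
    centre <- z[round(ci), round(cj)]
    R_px <- tr3$radius_um[i] / px_um
    ang <- seq(0, 2 * pi, length.out = 73)[-73]
    rim <- z[cbind(pmax(1, round(ci + 0.8 * R_px * cos(ang))),
                   pmax(1, round(cj + 0.8 * R_px * sin(ang))))]
    if (tr3$label[i] == "discocyte") {
      expect_lt(centre, max(rim))
    } else if (tr3$label[i] == "codocyte") {
      # central dome is a local maximum: centre above the mid-radius trough
      mid <- z[round(ci + 0.45 * R_px), round(cj)]
      expect_gt(centre, mid)
    } else {
      # echinocyte rim carries at least 10 angular maxima
      yl <- c(rim[length(rim)], rim[-length(rim)])
      yr <- c(rim[-1], rim[1])
      expect_gte(sum(rim > yl & rim >= yr), 10)
    }
  }

  # largest-remainder counts at the reported 7-h acidic composition
  sc100 <- make_cell_scene(composition_params(54, 42, 4), n_cells = 100,
                           seed = 3)
  counts <- table(scene_truth(sc100)$label)
  expect_equal(unname(counts[c("discocyte", "echinocyte", "codocyte")]),
               c(54L, 42L, 4L), ignore_attr = TRUE)

  # invariant violations
  expect_error(composition_params(50, 30, 10), class = "rbcnano_parameter_error")
  expect_error(make_cell_scene(list(discocyte = 50, echinocyte = 40,
                                    codocyte = 0), 5),
               class = "rbcnano_parameter_error")
})

test_that("mesh generator honours deterministic seeds and calibration", {
  # regular 4x4 seed grid on a 4x4 um field: the four interior cells are
  # 1x1 um squares eroded by 50 nm on every side -> Feret = sqrt(2) * 0.9
  seeds <- as.matrix(expand.grid(c(0.5, 1.5, 2.5, 3.5), c(0.5, 1.5, 2.5, 3.5)))
  hm <- make_cytoskeleton_image(mesh_params(4, 0.5, ridge_width = 100),
                                size = 512, pixel_size = 4000 / 512,
                                seed = 1, seeds = seeds)
  tr <- mesh_truth(hm)
  expect_equal(nrow(tr), 16)
  interior <- dplyr::filter(tr, !border)
  expect_equal(nrow(interior), 4)
  expect_true(all(abs(interior$feret_um - sqrt(2) * 0.9) < 0.03))

  # control preset: ground truth close to the requested density and length
  ctl <- preset("control")$mesh
  counts <- ferets <- numeric(3)
  for (s in 1:3) {
    m <- make_cytoskeleton_image(ctl, size = 512, seed = s)
    gt <- dplyr::filter(mesh_truth(m), !border)
    area <- attr(m, "pixel_size")^2 * 512^2 / 1e6  # um^2
    counts[s] <- nrow(gt)
    ferets[s] <- mean(gt$feret_um)
  }
  expect_rel(mean(ferets), 0.13, 0.12)

  # joint parameter infeasibility is a parameter error
  expect_error(make_cytoskeleton_image(mesh_params(125, 0.5), size = 256),
               class = "rbcnano_parameter_error")
})

test_that("force-curve generator inverts and scales per the Hertz law", {
  # noiseless inversion at the reported control modulus
  fc <- make_force_curve(4.1, contact_z = 500, max_indentation = 500,
                         noise_sd = 0)
  fit <- fit_hertz(fc)
  expect_rel(fit$E, 4.1, 1e-3)

  # no contact: flat zero curve
  fc0 <- make_force_curve(5, contact_z = 500, max_indentation = 0,
                          noise_sd = 0)
  expect_true(all(fc0$y == 0))

  # doubling E doubles deflection in the contact region only approximately
  # (the deflection feeds back into the indentation); force at equal true
  # indentation doubles exactly, which is what the linearity law states
  f1 <- make_force_curve(3, contact_z = 200, max_indentation = 300,
                         noise_sd = 0)
  f2 <- make_force_curve(6, contact_z = 200, max_indentation = 300,
                         noise_sd = 0)
  fi1 <- to_force_indentation(f1, 200)
  fi2 <- to_force_indentation(f2, 200)
  # compare forces at matched indentations by interpolation
  common <- seq(50, 250, by = 10)
  F1 <- approx(fi1$indentation, fi1$force, xout = common)$y
  F2 <- approx(fi2$indentation, fi2$force, xout = common)$y
  expect_true(all(abs(F2 / F1 - 2) < 1e-3))

  expect_error(make_force_curve(-1), class = "rbcnano_parameter_error")
})

test_that("extinction table and spectrum generator match their constructions", {
  tab <- make_extinction_table()
  # HbO2 doublet at exactly 542 and 577 nm on the default grid
  i <- 2:(nrow(tab) - 1)
  locmax <- tab$wavelength[i][tab$eps_hbo2[i] > tab$eps_hbo2[i - 1] &
                                tab$eps_hbo2[i] > tab$eps_hbo2[i + 1]]
  expect_equal(locmax, c(542, 577))
  expect_equal(tab$wavelength[which.max(tab$eps_hb)], 555)
  expect_true(all(tab$eps_hbo2 > 0 & tab$eps_hb > 0 & tab$eps_methb > 0))
  expect_error(make_extinction_table(520:700), class = "rbcnano_parameter_error")

  # single-species spectrum is the MetHb column plus background terms
  sp <- make_spectrum(list(HbO2 = 0, Hb = 0, MetHb = 100), total_conc = 0.8,
                      M = 0.01, S = 2e8, noise_sd = 0)
  expect_equal(sp$y, 0.8 * tab$eps_methb + 0.01 + 2e8 / tab$wavelength^4,
               tolerance = 1e-12)

  # zero everything gives the zero spectrum
  sp0 <- make_spectrum(list(HbO2 = 100, Hb = 0, MetHb = 0), total_conc = 0,
                       M = 0, S = 0, noise_sd = 0)
  expect_true(all(sp0$y == 0))

  expect_error(make_spectrum(list(HbO2 = -5, Hb = 105, MetHb = 0)),
               class = "rbcnano_parameter_error")
})

test_that("current-trace generator produces the stated plateau behaviour", {
  tr <- make_current_trace(0, 10, noise_sd = 0)
  expect_equal(max_current(tr), 10, tolerance = 1e-9)

  # peak ratio of two is preserved through the reduction
  t1 <- make_current_trace(1, 11, noise_sd = 0)
  t2 <- make_current_trace(1, 21, noise_sd = 0)
  r1 <- trace_ros(t1, reference = 100)
  r2 <- trace_ros(t2, reference = 100)
  expect_rel(r2$normalized / r1$normalized, 2, 1e-6)

  # noisy plateau maximum stays within 3 sd of the peak (smoothed)
  devs <- vapply(1:20, function(s) {
    tr <- make_current_trace(0, 10, noise_sd = 1, seed = s)
    abs(max_current(tr) - 10)
  }, numeric(1))
  expect_true(all(devs < 3 * 1))

  expect_error(make_current_trace(5, 5), class = "rbcnano_parameter_error")
})
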