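test_that("segmentation finds placed cells and honours the border rule", {
  sc <- make_cell_scene(composition_params(100, 0, 0), n_cells = 5, seed = 4)
  reg <- segment_cells(sc)
  tr <- scene_truth(sc)
  expect_equal(nrow(reg), 5)
  # centroids match ground truth within 3 px
  px_um <- attr(sc, "pixel_size") / 1000
  for (i in seq_len(nrow(tr))) {
    d <- sqrt((reg$x_um - tr$x_um[i])^2 + (reg$y_um - tr$y_um[i])^2) / px_um
    expect_lt(min(d), 3)
  }

  # flat map: empty table, not an error
  expect_equal(nrow(segment_cells(heightmap(matrix(0, 128, 128), 60))), 0)

  # a cell drawn across the border is excluded
  z <- unclass(sc)
  zb <- matrix(0, nrow(z), ncol(z))
  zb[1:40, 1:40] <- 1500  # plateau touching rows/cols 1
  expect_equal(nrow(segment_cells(heightmap(zb, attr(sc, "pixel_size")))), 0)
})

test_that("radial profiles expose the class-defining geometry", {
  sc <- make_cell_scene(composition_params(34, 33, 33), n_cells = 9, seed = 6)
  reg <- segment_cells(sc)
  tr <- scene_truth(sc)
  for (i in seq_len(nrow(reg))) {
    rp <- radial_profile(sc, reg[i, ])
    truth_i <- which.min((tr$x_um - reg$x_um[i])^2 + (tr$y_um - reg$y_um[i])^2)
    lab <- tr$label[truth_i]
    prof <- rp$profile
    centre <- mean(prof$height[prof$radius < 0.15])
    if (lab == "discocyte") {
      expect_lt(centre, max(prof$height))
    } else if (lab == "codocyte") {
      mid <- min(prof$height[prof$radius >= 0.2 & prof$radius <= 0.65])
      expect_gt(centre, mid)
    } else {
      yl <- c(rp$angular[length(rp$angular)], rp$angular[-length(rp$angular)])
      yr <- c(rp$angular[-1], rp$angular[1])
      expect_gte(sum(rp$angular > yl & rp$angular >= yr), 10)
    }
  }
})

test_that("classifier separates the archetypes and handles degenerate input", {
  # pure discocyte population
  sc <- make_cell_scene(composition_params(100, 0, 0), n_cells = 30, seed = 7)
  out <- scene_composition(sc)
  disc <- out$composition$percent[out$composition$label == "discocyte"]
  expect_gte(disc, 95)

  # echinocytes carry their spicule counts
  sce <- make_cell_scene(composition_params(0, 100, 0), n_cells = 10, seed = 8)
  oute <- scene_composition(sce)
  expect_true(all(oute$cells$label == "echinocyte"))
  expect_true(all(oute$cells$spicule_count >= 10))

  # an all-zero profile is unclassified
  flatprof <- tibble::tibble(radius = seq(0.02, 0.98, length.out = 24),
                             height = 0)
  cl <- classify_cell(flatprof, rep(0, 90))
  expect_equal(cl$label, "unclassified")

  # zero cells is an error
  expect_error(scene_composition(heightmap(matrix(0, 128, 128), 60)),
               class = "rbcnano_insufficient_data")
})

test_that("classification is invariant to translation, rotation and scaling", {
  sc <- make_cell_scene(composition_params(50, 30, 20), n_cells = 10, seed = 9)
  base <- scene_composition(sc)$cells |> dplyr::arrange(.data$x_um)

  # 90 degree rotation of the scene
  z <- unclass(sc)
  rot <- heightmap(t(z)[ncol(z):1, ], attr(sc, "pixel_size"))
  rotc <- scene_composition(rot)$cells
  expect_equal(sort(table(rotc$label)), sort(table(base$label)))

  # uniform height scaling (indices are normalised)
  scl <- heightmap(z * 2.4, attr(sc, "pixel_size"))
  sclc <- scene_composition(scl)$cells |> dplyr::arrange(.data$x_um)
  expect_equal(sclc$label, base$label)

  # translation by whole pixels on a padded canvas (no cell lost)
  sh <- matrix(0, nrow(z) + 40, ncol(z) + 40)
  sh[11:(nrow(z) + 10), 16:(ncol(z) + 15)] <- z
  shc <- scene_composition(heightmap(sh, attr(sc, "pixel_size")))$cells
  expect_equal(sort(table(shc$label)), sort(table(base$label)))
})

test_that("scene composition recovers generated mixtures", {
  sc <- make_cell_scene(composition_params(54, 42, 4), n_cells = 60, seed = 10)
  comp <- scene_composition(sc)$composition
  for (lab in c("discocyte", "echinocyte", "codocyte")) {
    got <- comp$percent[comp$label == lab]
    want <- c(discocyte = 54, echinocyte = 42, codocyte = 4)[[lab]]
    expect_lt(abs(got - want), 5)
  }

  # single-cell scene: 100/0/0
  sc1 <- make_cell_scene(composition_params(100, 0, 0), n_cells = 1, seed = 2)
  comp1 <- scene_composition(sc1)$composition
  expect_equal(comp1$percent[comp1$label == "discocyte"], 100)
})
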