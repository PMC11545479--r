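#' Generate a multi-cell scene with known shape labels
#'
#' Places `n_cells` non-overlapping parametric red-blood-cell models on a
#' flat substrate and returns the rendered height map together with the
#' ground-truth label of every cell. Class counts follow the requested
#' composition by largest-remainder rounding. The three archetypes are
#' radial models built from textbook RBC geometry (7.5 um diameter,
#' 1.6 um rim height by default, with 5 % log-normal size jitter):
#'
#' * discocyte — biconcave disc; the central dimple is ~55 % of the rim
#'   height.
#' * echinocyte — disc carrying 10-14 radial spicules, modelled as an
#'   angular sinusoid concentrated at 0.8 of the cell radius.
#' * codocyte — target cell: central dome, annular trough, elevated rim.
#'
#' @param comp Composition percentages: a list/vector with `discocyte`,
#'   `echinocyte`, `codocyte` summing to 100 (see [composition_params()]).
#' @param n_cells Number of cells (>= 1).
#' @param seed RNG seed.
#' @param pixel_size nm per pixel of the rendered scene.
#' @param cell_diameter_um,cell_height_nm Mean cell diameter and rim height.
#' @return The scene [heightmap()], with the ground-truth per-cell table
#'   (columns `cell`, `label`, `x_um`, `y_um`, `radius_um`, `height_nm`,
#'   `n_spicules`) attached as attribute `"cells"` (also returned by
#'   [scene_truth()]).
#' @examples
#' sc <- make_cell_scene(composition_params(100, 0, 0), n_cells = 3, seed = 1)
#' scene_truth(sc)
#' @export
make_cell_scene <- function(comp, n_cells, seed = NULL, pixel_size = 60,
                            cell_diameter_um = 7.5, cell_height_nm = 1600) {
  fr <- c(discocyte = comp$discocyte %||% comp[["discocyte"]],
          echinocyte = comp$echinocyte %||% comp[["echinocyte"]],
          codocyte = comp$codocyte %||% comp[["codocyte"]])
  if (anyNA(fr)) abort_param("comp must name discocyte, echinocyte, codocyte")
  if (any(fr < 0) || abs(sum(fr) - 100) > 1e-8) {
    abort_param("composition percentages must be >= 0 and sum to 100")
  }
  if (n_cells < 1) abort_param("n_cells must be >= 1")
  counts <- largest_remainder(fr, n_cells)
  labels <- rep(names(counts), counts)

  slot_um <- 1.4 * cell_diameter_um
  n_side <- ceiling(sqrt(n_cells))
  field_um <- n_side * slot_um + cell_diameter_um
  npx <- ceiling(field_um * 1000 / pixel_size)

  with_seed(seed, {
    labels <- sample(labels)
    radius <- cell_diameter_um / 2 * exp(stats::rnorm(n_cells, 0, 0.05))
    h0 <- cell_height_nm * exp(stats::rnorm(n_cells, 0, 0.05))
    n_spic <- sample(10:14, n_cells, replace = TRUE)
    pos <- place_cells(n_cells, radius, field_um)
    z <- matrix(0, npx, npx)
    for (i in seq_len(n_cells)) {
      z <- render_cell(z, pixel_size, labels[i], pos$x[i], pos$y[i],
                       radius[i], h0[i], n_spic[i])
    }
    truth <- tibble(cell = seq_len(n_cells), label = labels,
                    x_um = pos$x, y_um = pos$y, radius_um = radius,
                    height_nm = h0, n_spicules = ifelse(labels == "echinocyte",
                                                        n_spic, 0L))
    hm <- heightmap(z, pixel_size = pixel_size, name = "scene")
    attr(hm, "cells") <- truth
    hm
  })
}

#' Ground-truth cell table of a synthetic scene
#' @param scene A scene produced by [make_cell_scene()].
#' @return Tibble of per-cell ground truth.
#' @export
scene_truth <- function(scene) {
  tr <- attr(scene, "cells")
  if (is.null(tr)) abort_param("scene carries no ground-truth table")
  tr
}

# integer class counts from percentages, largest-remainder rounding
largest_remainder <- function(perc, n) {
  raw <- perc / 100 * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(short)]] <- base[o[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(base), names(perc))
}

# rejection-sample non-overlapping centres (um), fixed iteration cap
place_cells <- function(n, radius, field_um) {
  margin <- radius + 0.3
  xs <- numeric(0)
  ys <- numeric(0)
  tries <- 0L
  cap <- 4000L * n
  for (i in seq_len(n)) {
    repeat {
      tries <- tries + 1L
      if (tries > cap) {
        abort(sprintf("could not place %d cells without overlap on a %.0f um field",
                      n, field_um), class = "rbcnano_placement_error")
      }
      x <- stats::runif(1, margin[i], field_um - margin[i])
      y <- stats::runif(1, margin[i], field_um - margin[i])
      if (i == 1 ||
          all((x - xs)^2 + (y - ys)^2 > (radius[i] + radius[seq_len(i - 1)] + 0.3)^2)) {
        xs <- c(xs, x)
        ys <- c(ys, y)
        break
      }
    }
  }
  list(x = xs, y = ys)
}

# render one cell onto the scene (heights in nm, coordinates in um)
render_cell <- function(z, pixel_size, label, cx, cy, R, h0, n_spic) {
  px_um <- pixel_size / 1000
  npx <- nrow(z)
  i0 <- max(1, floor((cx - R) / px_um))
  i1 <- min(npx, ceiling((cx + R) / px_um))
  j0 <- max(1, floor((cy - R) / px_um))
  j1 <- min(npx, ceiling((cy + R) / px_um))
  xi <- (i0:i1 - 0.5) * px_um
  yj <- (j0:j1 - 0.5) * px_um
  dx <- matrix(xi - cx, length(xi), length(yj))
  dy <- matrix(yj - cy, length(xi), length(yj), byrow = TRUE)
  rho <- sqrt(dx^2 + dy^2) / R
  theta <- atan2(dy, dx)
  p <- cell_profile(label, rho, theta, n_spic)
  patch <- z[i0:i1, j0:j1]
  z[i0:i1, j0:j1] <- pmax(patch, h0 * p)
  z
}

cell_profile <- function(label, rho, theta, n_spic) {
  dome <- sqrt(pmax(0, 1 - rho^2))
  p <- switch(label,
    discocyte = dome * (1 - 0.45 * exp(-(rho / 0.45)^2)),
    echinocyte = dome * (1 - 0.25 * exp(-(rho / 0.5)^2)) *
      (1 + 0.35 * cos(n_spic * theta) * exp(-((rho - 0.8) / 0.18)^2)),
    codocyte = 0.75 * exp(-(rho / 0.25)^2) +
      0.9 * exp(-((rho - 0.75) / 0.15)^2) + 0.15 * dome,
    abort_param(sprintf("unknown cell label '%s'", label)))
  p[rho > 1] <- 0
  pmax(p, 0)
}
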