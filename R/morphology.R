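#' Segment individual cells from a scene height map
#'
#' Thresholds the (substrate-levelled) scene at `min_height`, labels
#' connected components, discards components touching the image border and
#' filters by physical area. Connected-component labelling is done with
#' EBImage.
#'
#' @param scene A [heightmap()] with substrate near 0 nm.
#' @param min_height Threshold in nm separating cells from substrate.
#' @param min_area_um2,max_area_um2 Physical area bounds for a single cell.
#' @return A tibble with one row per cell region: `region`, `row`, `col`
#'   (centroid, px), `x_um`, `y_um`, `area_um2`, `equiv_diameter_um`,
#'   `mean_height_nm`. The full label matrix is attached as attribute
#'   `"labels"`.
#' @export
segment_cells <- function(scene, min_height = 200, min_area_um2 = 10,
                          max_area_um2 = 80) {
  if (!inherits(scene, "heightmap")) abort_param("`scene` must be a heightmap")
  px_um <- pixel_size(scene) / 1000
  mask <- as_plain_matrix(scene) > min_height
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  if (max(lab) == 0) return(empty_regions(lab))
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  ids <- setdiff(seq_len(max(lab)), border)
  if (length(ids) == 0) return(empty_regions(lab))
  idx <- which(lab > 0)
  l <- lab[idx]
  keepi <- l %in% ids
  idx <- idx[keepi]
  l <- l[keepi]
  rows <- ((idx - 1) %% nrow(lab)) + 1
  cols <- ((idx - 1) %/% nrow(lab)) + 1
  reg <- tibble(region = l, row = rows, col = cols,
                h = as_plain_matrix(scene)[idx]) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(area_px = dplyr::n(), row = mean(.data$row),
                     col = mean(.data$col), mean_height_nm = mean(.data$h)) |>
    dplyr::mutate(area_um2 = .data$area_px * px_um^2,
                  equiv_diameter_um = 2 * sqrt(.data$area_um2 / pi),
                  x_um = (.data$row - 0.5) * px_um,
                  y_um = (.data$col - 0.5) * px_um) |>
    dplyr::filter(.data$area_um2 >= min_area_um2,
                  .data$area_um2 <= max_area_um2) |>
    dplyr::select("region", "row", "col", "x_um", "y_um", "area_um2",
                  "equiv_diameter_um", "mean_height_nm")
  lab[!(lab %in% reg$region)] <- 0L
  attr(reg, "labels") <- lab
  reg
}

empty_regions <- function(lab) {
  out <- tibble(region = integer(), row = numeric(), col = numeric(),
                x_um = numeric(), y_um = numeric(), area_um2 = numeric(),
                equiv_diameter_um = numeric(), mean_height_nm = numeric())
  attr(out, "labels") <- lab * 0L
  out
}

#' Radial height profile and angular rim series of one cell
#'
#' The radial profile is the mean height versus normalised radius (0 at the
#' centroid, 1 at the equivalent-circle radius); the angular series samples
#' the height by bilinear interpolation on a circle at `rim_radius` of the
#' cell radius — the basis for dimple/dome/spicule descriptors.
#'
#' @param scene The scene [heightmap()].
#' @param region One row of the [segment_cells()] table.
#' @param n_bins Number of radial bins.
#' @param n_angular Number of angular samples on the rim circle.
#' @param rim_radius Rim sampling radius as a fraction of the cell radius.
#' @return A list with `profile` (tibble `radius`, `height`) and `angular`
#'   (numeric vector of rim heights).
#' @export
radial_profile <- function(scene, region, n_bins = 24, n_angular = 90,
                           rim_radius = 0.8) {
  z <- as_plain_matrix(scene)
  px_um <- pixel_size(scene) / 1000
  R_px <- region$equiv_diameter_um / 2 / px_um
  if (R_px < n_bins / 2) abort_data("cell too small for the requested radial bins")
  cr <- region$row
  cc <- region$col
  # radial profile from all pixels within 1.05 R of the centroid
  rwin <- ceiling(R_px * 1.05)
  i0 <- max(1, floor(cr - rwin)); i1 <- min(nrow(z), ceiling(cr + rwin))
  j0 <- max(1, floor(cc - rwin)); j1 <- min(ncol(z), ceiling(cc + rwin))
  di <- matrix((i0:i1) - cr, i1 - i0 + 1, j1 - j0 + 1)
  dj <- matrix((j0:j1) - cc, i1 - i0 + 1, j1 - j0 + 1, byrow = TRUE)
  rr <- sqrt(di^2 + dj^2) / R_px
  sel <- rr <= 1
  bin <- pmin(floor(rr[sel] * n_bins) + 1, n_bins)
  hm <- tapply(z[i0:i1, j0:j1][sel], bin, mean)
  profile <- tibble(radius = (as.numeric(names(hm)) - 0.5) / n_bins,
                    height = as.numeric(hm))
  ang <- seq(0, 2 * pi, length.out = n_angular + 1)[-(n_angular + 1)]
  ai <- cr + rim_radius * R_px * cos(ang)
  aj <- cc + rim_radius * R_px * sin(ang)
  angular <- bilinear(z, ai, aj)
  list(profile = profile, angular = angular)
}

bilinear <- function(z, ri, cj) {
  ri <- pmin(pmax(ri, 1), nrow(z) - 1e-9)
  cj <- pmin(pmax(cj, 1), ncol(z) - 1e-9)
  i0 <- floor(ri); j0 <- floor(cj)
  fi <- ri - i0; fj <- cj - j0
  i1 <- pmin(i0 + 1, nrow(z)); j1 <- pmin(j0 + 1, ncol(z))
  z[cbind(i0, j0)] * (1 - fi) * (1 - fj) + z[cbind(i1, j0)] * fi * (1 - fj) +
    z[cbind(i0, j1)] * (1 - fi) * fj + z[cbind(i1, j1)] * fi * fj
}

#' Classify one cell as discocyte, echinocyte or codocyte
#'
#' Decision rule on normalised shape descriptors, applied in order:
#' 1. `spicule_count` — angular rim maxima whose circular prominence exceeds
#'    both `prominence_factor` times the rim-series SD and `prominence_floor`
#'    of the cell height. At least `spicule_min` maxima: echinocyte.
#' 2. `dome_index = (centre - mid-radius minimum) / cell height` above
#'    `dome_threshold`: codocyte (central dome inside an annular trough).
#' 3. `dimple_index = (rim maximum - centre) / cell height` above
#'    `dimple_threshold`: discocyte (biconcave).
#' 4. otherwise unclassified.
#'
#' All indices are height-normalised, so the rule is invariant to uniform
#' height scaling.
#'
#' @param profile Radial profile tibble from [radial_profile()].
#' @param angular Angular rim series from [radial_profile()].
#' @param thresholds List of rule parameters; see [default_config()]
#'   `$morphology`.
#' @return One-row tibble: `label`, `spicule_count`, `dome_index`,
#'   `dimple_index`.
#' @export
classify_cell <- function(profile, angular,
                          thresholds = default_config()$morphology) {
  th <- thresholds
  height <- max(profile$height)
  if (!is.finite(height) || height <= 0) {
    return(tibble(label = "unclassified", spicule_count = 0L,
                  dome_index = NA_real_, dimple_index = NA_real_))
  }
  prom_min <- max(th$prominence_factor * stats::sd(angular),
                  th$prominence_floor * height)
  spic <- circular_peak_count(angular, prom_min)
  centre <- mean(profile$height[profile$radius < 0.15])
  mid_min <- min(profile$height[profile$radius >= 0.2 & profile$radius <= 0.65])
  rim_max <- max(profile$height[profile$radius >= 0.5])
  dome_index <- (centre - mid_min) / height
  dimple_index <- (rim_max - centre) / height
  label <- if (spic >= th$spicule_min) "echinocyte"
  else if (dome_index > th$dome_threshold) "codocyte"
  else if (dimple_index > th$dimple_threshold) "discocyte"
  else "unclassified"
  tibble(label = label, spicule_count = as.integer(spic),
         dome_index = dome_index, dimple_index = dimple_index)
}

# count local maxima of a circular series with prominence above prom_min
circular_peak_count <- function(y, prom_min) {
  n <- length(y)
  if (n < 3) return(0L)
  yl <- c(y[n], y[-n])
  yr <- c(y[-1], y[1])
  peaks <- which(y > yl & y >= yr)
  if (length(peaks) == 0) return(0L)
  count <- 0L
  y3 <- c(y, y, y)
  for (p in peaks) {
    pc <- p + n
    # walk left and right until a higher point; prominence vs deepest saddle
    left <- y3[seq(pc - 1, pc - n)]
    right <- y3[seq(pc + 1, pc + n)]
    higher_l <- which(left > y[p])
    higher_r <- which(right > y[p])
    min_l <- if (length(higher_l)) min(left[seq_len(higher_l[1])]) else min(left)
    min_r <- if (length(higher_r)) min(right[seq_len(higher_r[1])]) else min(right)
    prom <- y[p] - max(min_l, min_r)
    if (prom > prom_min) count <- count + 1L
  }
  count
}

#' Classify every cell in a scene and summarise the composition
#'
#' Runs [segment_cells()], [radial_profile()] and [classify_cell()] over a
#' scene and reports the percentage of each shape class among classified
#' cells (unclassified cells are counted separately, not in the
#' percentages).
#'
#' @param scene A [heightmap()] scene.
#' @param config Analysis configuration; see [default_config()].
#' @return A list of class `scene_composition`: `cells` (per-cell tibble
#'   with positions, descriptors and labels) and `composition` (tibble
#'   `label`, `n`, `percent`), plus `n_unclassified`.
#' @examples
#' sc <- make_cell_scene(composition_params(100, 0, 0), n_cells = 4, seed = 1)
#' scene_composition(sc)$composition
#' @export
scene_composition <- function(scene, config = default_config()) {
  mc <- config$morphology
  regions <- segment_cells(scene, min_height = mc$min_height_nm,
                           min_area_um2 = mc$min_area_um2,
                           max_area_um2 = mc$max_area_um2)
  if (nrow(regions) == 0) abort_data("no cells segmented from the scene")
  cells <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    rp <- radial_profile(scene, regions[i, ], n_bins = mc$n_radial_bins,
                         n_angular = mc$n_angular_bins,
                         rim_radius = mc$rim_radius)
    dplyr::bind_cols(regions[i, ], classify_cell(rp$profile, rp$angular, mc))
  })
  classified <- cells |> dplyr::filter(.data$label != "unclassified")
  comp <- classified |>
    dplyr::count(.data$label) |>
    tidyr::complete(label = c("discocyte", "echinocyte", "codocyte"),
                    fill = list(n = 0L)) |>
    dplyr::mutate(percent = 100 * .data$n / max(1, sum(.data$n)))
  structure(list(cells = cells, composition = comp,
                 n_unclassified = sum(cells$label == "unclassified")),
            class = "scene_composition")
}

#' @export
print.scene_composition <- function(x, ...) {
  cat(sprintf("<scene_composition> %d cells (%d unclassified)\n",
              nrow(x$cells), x$n_unclassified))
  print(x$composition)
  invisible(x)
}
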