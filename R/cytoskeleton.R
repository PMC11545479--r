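#' Watershed segmentation of cytoskeletal pores
#'
#' Pores are the depressions enclosed by the filament network. The relief is
#' Gaussian-smoothed, inverted, and segmented by topographic watershed
#' (EBImage) so that each catchment basin around a regional minimum deeper
#' than `depth_threshold` becomes one candidate pore; basins are then
#' restricted to pixels below the filament mid-height, so the measured pore
#' is the depression proper, not the basin up to the filament crest. Pores
#' touching the image border are discarded and the pore count is rescaled by
#' the interior-area fraction (truncation-bias correction); pores smaller
#' than `min_area` are dropped.
#'
#' @param map A cytoskeleton [heightmap()].
#' @param smooth_sigma Gaussian smoothing sigma in nm.
#' @param depth_threshold Minimum depth (nm) of a regional minimum below its
#'   surroundings for it to seed a pore (the watershed merge tolerance).
#' @param min_area Minimum pore area in um^2.
#' @return A tibble of class `pore_set`, one row per pore: `pore`,
#'   `area_um2`, `feret_um`, centroid `x_um`, `y_um`. Attributes:
#'   `field_area_um2`, `interior_area_um2`, `count_per_2x2um2` (border-
#'   corrected density) and the pore `labels` matrix.
#' @examples
#' hm <- make_cytoskeleton_image(preset("control")$mesh, size = 256, seed = 1)
#' pore_stats(detect_pores(hm))
#' @export
detect_pores <- function(map, smooth_sigma = 10, depth_threshold = 0.5,
                         min_area = 1e-4) {
  if (!inherits(map, "heightmap")) abort_param("`map` must be a heightmap")
  px <- pixel_size(map)
  px_um <- px / 1000
  z <- as_plain_matrix(map)
  field_area <- prod(dim(z)) * px_um^2
  if (max(z) - min(z) < depth_threshold) {
    return(empty_pore_set(z, field_area))
  }
  zs <- z
  if (smooth_sigma > 0) {
    zs <- EBImage::imageData(EBImage::gblur(EBImage::Image(z),
                                            sigma = smooth_sigma / px))
  }
  # separation on the smoothed relief; filament/pore classification on the
  # raw heights at the filament mid-height (robust quantile midpoint)
  q <- stats::quantile(z, c(0.01, 0.99))
  hcut <- mean(q)
  inv <- max(zs) - zs
  ws <- EBImage::imageData(EBImage::watershed(EBImage::Image(inv),
                                              tolerance = depth_threshold,
                                              ext = 1))
  mask <- z < hcut
  lab <- ws * mask
  if (max(lab) == 0) return(empty_pore_set(z, field_area))
  nr <- nrow(lab)
  # a pore is a border pore if its watershed basin reaches the image frame;
  # its whole basin (pore + filament share) counts as excluded area so that
  # the density rescale is unbiased
  border_ids <- unique(c(ws[1, ], ws[nr, ], ws[, 1], ws[, ncol(ws)]))
  border_ids <- border_ids[border_ids > 0]
  idx <- which(lab > 0)
  l <- lab[idx]
  rows <- ((idx - 1) %% nr) + 1
  cols <- ((idx - 1) %/% nr) + 1
  min_px <- max(1, round(min_area / px_um^2))
  tab <- tabulate(l)
  keep_ids <- which(tab >= min_px)
  interior_ids <- setdiff(keep_ids, border_ids)
  basin_tab <- tabulate(ws[ws > 0])
  border_area <- sum(basin_tab[border_ids]) * px_um^2
  pores <- purrr::map_dfr(interior_ids, function(i) {
    sel <- l == i
    pts <- cbind(rows[sel], cols[sel]) * px_um
    tibble(pore = i, area_um2 = sum(sel) * px_um^2,
           feret_um = feret_from_points(pts),
           x_um = mean(pts[, 1]), y_um = mean(pts[, 2]))
  })
  lab[!(lab %in% interior_ids)] <- 0L
  interior_area <- field_area - border_area
  out <- pores
  class(out) <- c("pore_set", class(out))
  attr(out, "field_area_um2") <- field_area
  attr(out, "interior_area_um2") <- interior_area
  attr(out, "count_per_2x2um2") <- nrow(pores) / interior_area * 4
  attr(out, "labels") <- lab
  out
}

empty_pore_set <- function(z, field_area) {
  out <- tibble(pore = integer(), area_um2 = numeric(), feret_um = numeric(),
                x_um = numeric(), y_um = numeric())
  class(out) <- c("pore_set", class(out))
  attr(out, "field_area_um2") <- field_area
  attr(out, "interior_area_um2") <- field_area
  attr(out, "count_per_2x2um2") <- 0
  attr(out, "labels") <- matrix(0L, nrow(z), ncol(z))
  out
}

#' Maximum Feret diameter of a pixel mask
#'
#' The maximum caliper length: the largest distance between two pixel
#' centres of the mask, computed on the convex hull.
#'
#' @param mask Logical matrix (the pore), or a two-column matrix of pixel
#'   `(row, col)` indices.
#' @param pixel_size nm per pixel.
#' @return Length in um.
#' @examples
#' m <- matrix(FALSE, 12, 12); m[2, 2:11] <- TRUE
#' feret_max(m, pixel_size = 10)  # 9 px centre-to-centre = 0.09 um
#' @export
feret_max <- function(mask, pixel_size) {
  if (is.logical(mask) && is.matrix(mask)) {
    pts <- which(mask, arr.ind = TRUE)
  } else if (is.matrix(mask) && ncol(mask) == 2) {
    pts <- mask
  } else {
    abort_param("`mask` must be a logical matrix or a 2-column index matrix")
  }
  if (nrow(pts) == 0) abort_param("empty mask")
  if (nrow(pts) == 1) return(0)
  feret_from_points(pts) * pixel_size / 1000
}

#' Summary statistics of a pore set
#'
#' @param pores A `pore_set` from [detect_pores()].
#' @return One-row tibble: `n_pores`, `count_per_2x2um2` (border-corrected
#'   density scaled to the standard 2x2 um^2 window), `mean_feret_um`,
#'   `sd_feret_um`, `mean_area_um2`, `empty` flag.
#' @export
pore_stats <- function(pores) {
  if (!inherits(pores, "pore_set")) abort_param("`pores` must be a pore_set")
  if (nrow(pores) == 0) {
    return(tibble(n_pores = 0L, count_per_2x2um2 = 0, mean_feret_um = 0,
                  sd_feret_um = 0, mean_area_um2 = 0, empty = TRUE))
  }
  tibble(n_pores = nrow(pores),
         count_per_2x2um2 = attr(pores, "count_per_2x2um2"),
         mean_feret_um = mean(pores$feret_um),
         sd_feret_um = stats::sd(pores$feret_um),
         mean_area_um2 = mean(pores$area_um2),
         empty = FALSE)
}
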