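# Poisson-Voronoi erosion calibration for the spectrin-mesh generator.
#
# Filaments of finite width shrink every Voronoi cell: the observable pore is
# the cell eroded by half the filament width t. In scaled units
# u = t * sqrt(seed intensity), simulation of interior Poisson-Voronoi cells
# gives the survival fraction s(u) (pores not swallowed by the filaments) and
# the scaled mean max-Feret f(u) = E[Feret_survivor] * sqrt(intensity).
# u = 0 recovers the classical full-cell value f = 1.49 * sqrt(mean area).
# Frozen from a one-off simulation (4 fields of ~1100 cells per u).
voronoi_erosion_table <- data.frame(
  u = c(0.00, 0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.35, 0.40),
  s = c(1.000, 1.000, 0.998, 0.989, 0.958, 0.887, 0.764, 0.616, 0.459),
  # scaled Feret, corrected by one raster pixel (0.056 scaled) for the
  # centre-to-centre underestimate of the simulation raster
  f = c(1.548, 1.386, 1.252, 1.081, 0.961, 0.856, 0.755, 0.642, 0.599)
)

# Solve for (seed intensity lambda_s per um^2, erosion half-width t um) so
# that surviving-pore density and mean Feret match the requested targets.
calibrate_mesh <- function(pore_density_per4um2, mean_pore_length_um) {
  lam_p <- pore_density_per4um2 / 4   # pores per um^2
  g_target <- mean_pore_length_um * sqrt(lam_p)
  tab <- voronoi_erosion_table
  g <- tab$f * sqrt(tab$s)            # decreasing in u
  if (g_target > max(g) || g_target < min(g)) {
    abort_param(sprintf(
      "pore_density %.3g per 4 um^2 and mean_pore_length %.3g um are jointly out of the tessellation's reachable range",
      pore_density_per4um2, mean_pore_length_um))
  }
  u <- stats::approx(rev(g), rev(tab$u), xout = g_target)$y
  s <- stats::approx(tab$u, tab$s, xout = u)$y
  lam_s <- lam_p / s
  t <- u / sqrt(lam_s)
  list(intensity = lam_s, erosion = t)
}

#' Generate a synthetic cytoskeleton mesh with known pores
#'
#' Models the spectrin-actin network as elevated filaments along the edges
#' of a Voronoi tessellation of Poisson-distributed seed points, with the
#' enclosed depressions as pores. Filaments have a Gaussian cross-section of
#' FWHM `ridge_width`, so each observable pore is its Voronoi cell eroded by
#' half the filament width; the seed intensity and erosion depth are jointly
#' calibrated (frozen simulation-derived curve) so that the surviving-pore
#' density and mean maximum-Feret length match `pore_density` and
#' `mean_pore_length`.
#'
#' @param params Mesh parameters (list with `pore_density` in pores per
#'   2x2 um^2, `mean_pore_length` in um, optional explicit `ridge_width` in
#'   nm which then bypasses the Feret calibration); see [mesh_params()] and
#'   [preset()].
#' @param size Image size in pixels.
#' @param pixel_size nm per pixel. Default `2000/size` gives the standard
#'   2 x 2 um analysis field.
#' @param seed RNG seed.
#' @param amplitude Filament height above the pore floor, nm.
#' @param seeds Optional matrix of seed coordinates in um (two columns) to
#'   place deterministically instead of sampling a Poisson pattern.
#' @return The mesh [heightmap()]; the ground-truth pore table (columns
#'   `pore`, `x_um`, `y_um`, `area_um2`, `feret_um`, `border`) is attached
#'   as attribute `"pores"` (see [mesh_truth()]).
#' @examples
#' hm <- make_cytoskeleton_image(preset("control")$mesh, size = 256, seed = 1)
#' head(mesh_truth(hm))
#' @export
make_cytoskeleton_image <- function(params, size = 1024,
                                    pixel_size = 2000 / size, seed = NULL,
                                    amplitude = 8, seeds = NULL) {
  field_um <- size * pixel_size / 1000
  if (is.null(seeds)) {
    cal <- calibrate_mesh(params$pore_density, params$mean_pore_length)
    expected <- cal$intensity * field_um^2
    if (expected < 4) abort_param("expected pore count on the field is below 4")
  } else {
    cal <- list(intensity = nrow(seeds) / field_um^2,
                erosion = (params$ridge_width %||% 100) / 2000)
  }
  if (!is.null(params$ridge_width)) cal$erosion <- params$ridge_width / 2000
  typical_spacing <- 1 / sqrt(cal$intensity)
  if (2 * cal$erosion >= typical_spacing) {
    abort_param("ridge width is as large as the typical pore spacing")
  }
  with_seed(seed, {
    if (is.null(seeds)) {
      n <- stats::rpois(1, cal$intensity * field_um^2)
      if (n < 4) n <- 4L
      seeds <- cbind(stats::runif(n, 0, field_um), stats::runif(n, 0, field_um))
    }
    mesh_from_seeds(seeds, size, pixel_size, cal$erosion, amplitude)
  })
}

mesh_from_seeds <- function(seeds, size, pixel_size, erosion_um, amplitude) {
  px_um <- pixel_size / 1000
  field_um <- size * px_um
  n <- nrow(seeds)
  g <- (seq_len(size) - 0.5) * px_um
  # pass 1: nearest seed (label) and its squared distance
  lab <- matrix(1L, size, size)
  d1s <- outer((g - seeds[1, 1])^2, (g - seeds[1, 2])^2, "+")
  if (n > 1) for (i in 2:n) {
    d <- outer((g - seeds[i, 1])^2, (g - seeds[i, 2])^2, "+")
    nb <- d < d1s
    d1s[nb] <- d[nb]
    lab[nb] <- i
  }
  # adjacency pairs from the label grid
  pr <- rbind(cbind(as.vector(lab[-size, ]), as.vector(lab[-1, ])),
              cbind(as.vector(lab[, -size]), as.vector(lab[, -1])))
  pr <- pr[pr[, 1] != pr[, 2], , drop = FALSE]
  pr <- unique(rbind(pr, pr[, 2:1]))
  # pass 2: exact distance to the Voronoi boundary via bisector planes
  idxl <- split(seq_along(lab), as.vector(lab))
  rr <- ((seq_along(lab) - 1) %% size) + 1
  cc <- ((seq_along(lab) - 1) %/% size) + 1
  pxv <- g[rr]
  pyv <- g[cc]
  edge <- rep(Inf, length(lab))
  if (nrow(pr) > 0) for (k in seq_len(nrow(pr))) {
    i <- pr[k, 1]
    j <- pr[k, 2]
    idx <- idxl[[as.character(i)]]
    if (is.null(idx)) next
    dj <- (pxv[idx] - seeds[j, 1])^2 + (pyv[idx] - seeds[j, 2])^2
    Dij <- sqrt(sum((seeds[i, ] - seeds[j, ])^2))
    edge[idx] <- pmin(edge[idx], (dj - d1s[idx]) / (2 * Dij))
  }
  sigma <- erosion_um / sqrt(2 * log(2))   # half-max of the ridge at edge = t
  z <- amplitude * exp(-edge^2 / (2 * sigma^2))
  z <- matrix(z, size, size)
  # ground truth: pore = Voronoi cell minus the filament band (edge > t);
  # a pore whose Voronoi cell is clipped by the image frame is flagged border
  pore_px <- edge > erosion_um
  min_px <- max(2, round(1e-4 / px_um^2))  # same floor as detect_pores()
  truth <- purrr::map_dfr(seq_len(n), function(i) {
    idx <- idxl[[as.character(i)]]
    onb <- any(rr[idx] %in% c(1L, size)) || any(cc[idx] %in% c(1L, size))
    idx <- idx[pore_px[idx]]
    if (length(idx) < min_px) return(NULL)
    pts <- cbind(pxv[idx], pyv[idx])
    tibble(pore = i, x_um = seeds[i, 1], y_um = seeds[i, 2],
           area_um2 = length(idx) * px_um^2,
           feret_um = feret_from_points(pts), border = onb)
  })
  hm <- heightmap(z, pixel_size = pixel_size, name = "cytoskeleton")
  attr(hm, "pores") <- truth
  hm
}

#' Ground-truth pore table of a synthetic cytoskeleton image
#' @param mesh A mesh produced by [make_cytoskeleton_image()].
#' @return Tibble of per-pore ground truth.
#' @export
mesh_truth <- function(mesh) {
  tr <- attr(mesh, "pores")
  if (is.null(tr)) abort_param("mesh carries no ground-truth table")
  tr
}

# maximum pairwise distance over the convex hull of a point set
feret_from_points <- function(pts) {
  if (nrow(pts) < 2) return(0)
  h <- grDevices::chull(pts)
  max(stats::dist(pts[h, , drop = FALSE]))
}
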