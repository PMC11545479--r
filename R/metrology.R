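#' Remove a polynomial background from a height map
#'
#' Least-squares 2D polynomial flattening, the standard preprocessing before
#' any roughness analysis of a curved cell surface. Fits and subtracts all
#' monomials `x^i * y^j` with `i + j <= order` on coordinates scaled to
#' \[-1, 1\]; the residual has (numerically) zero mean.
#'
#' @param map A [heightmap()].
#' @param order Polynomial degree, one of 1, 2, 3.
#' @return The flattened [heightmap()].
#' @export
flatten <- function(map, order = 1L) {
  if (!inherits(map, "heightmap")) abort_param("`map` must be a heightmap")
  order <- as.integer(order)
  if (!order %in% 1:3) abort_param("`order` must be 1, 2 or 3")
  n <- nrow(map)
  m <- ncol(map)
  nterms <- (order + 1) * (order + 2) / 2
  if (n * m < nterms) abort_data("map smaller than the number of polynomial terms")
  u <- if (n > 1) seq(-1, 1, length.out = n) else 0
  v <- if (m > 1) seq(-1, 1, length.out = m) else 0
  U <- matrix(u, n, m)
  V <- matrix(v, n, m, byrow = TRUE)
  cols <- list()
  for (i in 0:order) for (j in 0:(order - i)) {
    cols[[length(cols) + 1]] <- as.vector(U^i * V^j)
  }
  X <- do.call(cbind, cols)
  fit <- stats::lm.fit(X, as.vector(unclass(map)))
  res <- matrix(fit$residuals, n, m)
  heightmap(res, pixel_size = pixel_size(map), name = map_name(map))
}

#' Radially averaged power spectral density
#'
#' Hann-windowed 2D power spectrum averaged over annuli of constant radial
#' spatial frequency. The window power is renormalised so that the spectrum
#' integrates back to the map variance (Parseval):
#' `sum(power * df) ~= var(map)`.
#'
#' @param map A flattened [heightmap()]. Non-square maps are zero-padded to
#'   square.
#' @return A tibble of class `radial_psd` with columns `spatial_frequency`
#'   (1/nm, strictly increasing, DC excluded), `power` (isotropic 2D
#'   spectral density, nm^2 nm^2) and `n_cells` (frequency cells per
#'   annulus).
#' @export
radial_psd <- function(map) {
  if (!inherits(map, "heightmap")) abort_param("`map` must be a heightmap")
  px <- pixel_size(map)
  z <- as_plain_matrix(map)
  if (nrow(z) <= 8 || ncol(z) <= 8) abort_data("map too small for a spectrum")
  n <- max(nrow(z), ncol(z))
  if (nrow(z) != ncol(z)) {
    zz <- matrix(0, n, n)
    zz[seq_len(nrow(z)), seq_len(ncol(z))] <- z - mean(z)
    z <- zz
  } else {
    z <- z - mean(z)
  }
  w1 <- hann_window(n)
  w2 <- outer(w1, w1)
  f2 <- stats::fft(z * w2)
  # fraction of total power per frequency cell, corrected for window power
  p2 <- Mod(f2)^2 / (length(z) * sum(w2^2))
  fr <- fft_radial_freq(n, px)
  df <- 1 / (n * px)
  k <- round(fr / df)
  keep <- k >= 1  # all annuli out to the diagonal Nyquist, DC excluded
  pow <- tapply(p2[keep], k[keep], sum)
  cnt <- tapply(rep(1, sum(keep)), k[keep], sum)
  freq <- as.numeric(names(pow)) * df
  # isotropic 2D density (per frequency-cell average): flat for white noise;
  # sum(power * n_cells * df^2) returns the variance (Parseval)
  out <- tibble(spatial_frequency = freq,
                power = as.numeric(pow) / (as.numeric(cnt) * df^2),
                n_cells = as.numeric(cnt))
  out <- out[order(out$spatial_frequency), ]
  class(out) <- c("radial_psd", class(out))
  attr(out, "bin_width") <- df
  out
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# radial frequency magnitude for each cell of an n x n FFT layout
fft_radial_freq <- function(n, px) {
  f1 <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)] / (n * px)
  sqrt(outer(f1^2, f1^2, "+"))
}

#' Split a height map into waviness and roughness bands
#'
#' Frequency-domain decomposition with a complementary raised-cosine
#' transition of relative width 0.2 around the cutoff frequency
#' `1/cutoff_wavelength`. The low band keeps wavelengths longer than the
#' cutoff (waviness), the high band the shorter ones (roughness), and
#' `low + high` reconstructs the input exactly.
#'
#' @param map A [heightmap()] (flatten first for cell surfaces).
#' @param cutoff_wavelength Cutoff in nm; must be resolvable on the grid
#'   (above `2 * pixel_size`, below the field size).
#' @return A list with elements `low` and `high`, both [heightmap()]s.
#' @export
decompose_bands <- function(map, cutoff_wavelength = 300) {
  if (!inherits(map, "heightmap")) abort_param("`map` must be a heightmap")
  px <- pixel_size(map)
  z <- as_plain_matrix(map)
  n0 <- nrow(z)
  m0 <- ncol(z)
  field <- max(n0, m0) * px
  if (cutoff_wavelength < 2 * px || cutoff_wavelength > field) {
    abort_param(sprintf(
      "cutoff %.3g nm not resolvable: must be in (%g, %g) nm", cutoff_wavelength,
      2 * px, field))
  }
  n <- max(n0, m0)
  zz <- matrix(0, n, n)
  zz[seq_len(n0), seq_len(m0)] <- z
  # mirror-pad to 2n so the periodic extension is continuous at the edges;
  # without this, edge discontinuities leak waviness power into the high band
  zp <- rbind(cbind(zz, zz[, n:1]), cbind(zz[n:1, ], zz[n:1, n:1]))
  np <- 2L * n
  fr <- fft_radial_freq(np, px)
  fc <- 1 / cutoff_wavelength
  flo <- fc * 0.9
  fhi <- fc * 1.1
  H <- ifelse(fr <= flo, 1,
              ifelse(fr >= fhi, 0, 0.5 * (1 + cos(pi * (fr - flo) / (fhi - flo)))))
  low <- Re(stats::fft(stats::fft(zp) * H, inverse = TRUE)) / length(zp)
  low <- low[seq_len(n0), seq_len(m0), drop = FALSE]
  high <- z - low  # complementary by construction
  list(low = heightmap(low, px, paste0(map_name(map), "_waviness")),
       high = heightmap(high, px, paste0(map_name(map), "_roughness")))
}

#' Amplitude and dominant period of one frequency band
#'
#' The amplitude is reported as the equivalent single-sinusoid peak-to-valley
#' value `h = 2*sqrt(2) * RMS(band)`; the lateral period `L = 1/f_peak`, where
#' `f_peak` is the power-weighted mode of the band's radial power spectrum:
#' the centroid of the two annuli either side of the maximum bin (sub-bin
#' refinement; less biased than a three-point parabola when the dominant
#' period spans only a few annuli). A band with (numerically) zero power
#' returns `h = 0` and `L = NA`.
#'
#' @param band A band-filtered [heightmap()].
#' @return A tibble with columns `h` (nm) and `L` (nm).
#' @export
band_params <- function(band) {
  if (!inherits(band, "heightmap")) abort_param("`band` must be a heightmap")
  z <- as_plain_matrix(band)
  z <- z - mean(z)
  h <- 2 * sqrt(2) * sqrt(mean(z^2))
  if (h < 1e-12 * (1 + max(abs(z)))) {
    return(tibble(h = 0, L = NA_real_))
  }
  psd <- radial_psd(band)
  k <- which.max(psd$power)
  w <- max(1, k - 2):min(nrow(psd), k + 2)
  f <- sum(psd$spatial_frequency[w] * psd$power[w]) / sum(psd$power[w])
  tibble(h = h, L = 1 / f)
}

#' Waviness and roughness parameters of a height map
#'
#' The full surface-metrology chain: polynomial flattening, complementary
#' band decomposition at the cutoff wavelength, then per-band amplitude and
#' period estimation. Returns the four standard parameters: waviness
#' amplitude `h1` and period `L1` (low band) and roughness amplitude `h2`
#' and period `L2` (high band).
#'
#' @param map A [heightmap()].
#' @param cutoff_wavelength Band cutoff in nm (default 300, the geometric
#'   midpoint between the ~100 nm roughness and ~900 nm waviness scales).
#' @param flatten_order Polynomial degree for background removal.
#' @return A one-row tibble: `name`, `h1`, `L1`, `h2`, `L2` (nm).
#' @examples
#' hm <- make_surface_texture(preset("control")$texture, size = 256,
#'                            pixel_size = 10, seed = 1)
#' surface_params(hm)
#' @export
surface_params <- function(map, cutoff_wavelength = 300, flatten_order = 1L) {
  flat <- flatten(map, order = flatten_order)
  bands <- decompose_bands(flat, cutoff_wavelength)
  lo <- band_params(bands$low)
  hi <- band_params(bands$high)
  tibble(name = map_name(map),
         h1 = lo$h, L1 = lo$L, h2 = hi$h, L2 = hi$L)
}
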