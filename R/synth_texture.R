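#' Generate a two-band sinusoidal surface texture
#'
#' Builds a synthetic membrane surface as the sum of two isotropic ensembles
#' of randomly oriented sinusoids: a waviness band with equivalent
#' peak-to-valley amplitude `h1` and dominant lateral period `L1`, and a
#' roughness band with `h2`, `L2`. Within each band the component
#' wavelengths are log-normally jittered (5 % sd) around the band period and
#' orientations/phases are uniform, giving a narrow isotropic ring spectrum.
#' Each band is rescaled to RMS exactly `h/(2*sqrt(2))`, the RMS of a single
#' sinusoid of peak-to-valley amplitude `h` — the amplitude convention shared
#' with [band_params()], which makes generator/estimator recovery a genuine
#' round trip.
#'
#' @param params Texture parameters: a list with `h1`, `L1`, `h2`, `L2` (nm)
#'   and optionally `n_components` (sinusoids per band, default 64). See
#'   [preset()] for the experimental-group values.
#' @param size Image size in pixels (square, >= 128).
#' @param pixel_size nm per pixel.
#' @param seed RNG seed; the generator is deterministic given the seed.
#' @return A [heightmap()].
#' @examples
#' hm <- make_surface_texture(preset("control")$texture, size = 256,
#'                            pixel_size = 10, seed = 1)
#' @export
make_surface_texture <- function(params, size = 512, pixel_size = 10, seed = NULL) {
  p <- params
  if (is.null(p$h1) || is.null(p$L1) || is.null(p$h2) || is.null(p$L2)) {
    abort_param("params must contain h1, L1, h2, L2")
  }
  if (!(p$L1 > p$L2 && p$L2 > 0)) abort_param("need L1 > L2 > 0")
  if (p$h1 < 0 || p$h2 < 0) abort_param("amplitudes must be >= 0")
  if (size < 128) abort_param("size must be >= 128 pixels")
  field <- size * pixel_size
  for (L in c(p$L1, p$L2)) {
    if (L < 4 * pixel_size || L > field / 4) {
      abort_param(sprintf(
        "period %.3g nm unresolvable: must lie in [%g, %g] nm on this grid",
        L, 4 * pixel_size, field / 4))
    }
  }
  ncomp <- as.integer(p$n_components %||% 64L)
  with_seed(seed, {
    z <- band_field(p$h1, p$L1, ncomp, size, pixel_size) +
      band_field(p$h2, p$L2, ncomp, size, pixel_size)
    heightmap(z, pixel_size = pixel_size, name = "texture")
  })
}

# One isotropic sinusoid ensemble, rescaled to RMS = h / (2*sqrt(2)).
band_field <- function(h, L, ncomp, size, pixel_size) {
  z <- matrix(0, size, size)
  if (h <= 0) return(z)
  xv <- (seq_len(size) - 1) * pixel_size
  theta <- stats::runif(ncomp, 0, 2 * pi)
  phase <- stats::runif(ncomp, 0, 2 * pi)
  lam <- L * exp(stats::rnorm(ncomp, 0, 0.05))
  for (i in seq_len(ncomp)) {
    fx <- cos(theta[i]) / lam[i]
    fy <- sin(theta[i]) / lam[i]
    z <- z + cos(outer(2 * pi * fx * xv, 2 * pi * fy * xv, "+") + phase[i])
  }
  z <- z - mean(z)
  rms <- sqrt(mean(z^2))
  if (rms > 0) z <- z * (h / (2 * sqrt(2))) / rms
  z
}
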