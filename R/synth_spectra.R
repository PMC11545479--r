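#' Synthetic molar-extinction table for hemoglobin derivatives
#'
#' A bundled stand-in for a published molar-absorption table, reproducing
#' the qualitative features the unmixing relies on: oxyhemoglobin has the
#' characteristic double band with local maxima exactly at 542 and 577 nm
#' (two equal Gaussian bands), deoxyhemoglobin a single broad band at
#' 555 nm, methemoglobin a distinct band at 630 nm; all columns are
#' strictly positive. Units are arbitrary but consistent, which is
#' immaterial for relative fractions. A user-supplied real table in the
#' same schema can be passed to [unmix()] instead.
#'
#' @param grid Wavelength grid in nm; must cover 500-700 nm.
#' @return A tibble of class `extinction_table`: `wavelength`, `eps_hbo2`,
#'   `eps_hb`, `eps_methb`.
#' @examples
#' tab <- make_extinction_table()
#' tab$wavelength[which.max(tab$eps_hb)]  # 555
#' @export
make_extinction_table <- function(grid = 500:700) {
  if (min(grid) > 500 || max(grid) < 700) {
    abort_param("grid must cover the 500-700 nm hemoglobin window")
  }
  if (min(grid) < 450 || max(grid) > 750) {
    abort_param("grid extends outside the supported 450-750 nm range")
  }
  l <- as.numeric(grid)
  out <- tibble(
    wavelength = l,
    eps_hbo2 = 0.05 + exp(-(l - 542)^2 / (2 * 10^2)) + exp(-(l - 577)^2 / (2 * 10^2)),
    eps_hb = 0.03 + 0.8 * exp(-(l - 555)^2 / (2 * 20^2)),
    eps_methb = 0.04 + 0.6 * exp(-(l - 630)^2 / (2 * 15^2))
  )
  class(out) <- c("extinction_table", class(out))
  out
}

#' Generate a synthetic absorption spectrum of a hemoglobin mixture
#'
#' Computes the optical density on the extinction-table grid as the linear
#' mixture of the three derivative spectra plus a constant background `M`
#' and a Rayleigh scattering term `S / lambda^4`, then adds Gaussian noise:
#' `D(lambda) = eps_HbO2 C_HbO2 + eps_Hb C_Hb + eps_MetHb C_MetHb + M +
#' S/lambda^4` with `C_i = fraction_i/100 * total_conc` (the geometric light
#' path is folded into the concentration scale).
#'
#' @param fractions Percentages of HbO2, Hb, MetHb (named list or vector,
#'   nonnegative, summing to 100).
#' @param total_conc Total concentration-path product (OD scale).
#' @param M Background level, OD.
#' @param S Rayleigh scattering coefficient, OD nm^4.
#' @param table Extinction table ([make_extinction_table()] by default).
#' @param noise_sd Optical-density noise SD.
#' @param seed RNG seed.
#' @return An [xy_series()]: wavelength (nm) vs optical density.
#' @examples
#' sp <- make_spectrum(list(HbO2 = 85, Hb = 15, MetHb = 0))
#' @export
make_spectrum <- function(fractions, total_conc = 1, M = 0.02, S = 5e8,
                          table = make_extinction_table(), noise_sd = 0,
                          seed = NULL) {
  fr <- c(HbO2 = fractions$HbO2 %||% fractions[["HbO2"]],
          Hb = fractions$Hb %||% fractions[["Hb"]],
          MetHb = fractions$MetHb %||% fractions[["MetHb"]])
  if (anyNA(fr)) abort_param("fractions must name HbO2, Hb and MetHb")
  if (any(fr < 0)) abort_param("fractions must be nonnegative")
  if (abs(sum(fr) - 100) > 1e-8) abort_param("fractions must sum to 100")
  C <- fr / 100 * total_conc
  l <- table$wavelength
  D <- table$eps_hbo2 * C[["HbO2"]] + table$eps_hb * C[["Hb"]] +
    table$eps_methb * C[["MetHb"]] + M + S / l^4
  with_seed(seed, {
    if (noise_sd > 0) D <- D + stats::rnorm(length(D), 0, noise_sd)
    xy_series(l, D, units = c("wavelength_nm", "optical_density"))
  })
}
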