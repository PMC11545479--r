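#' Unmix a hemoglobin absorption spectrum
#'
#' Decomposes an optical-density spectrum into oxy-, deoxy- and
#' met-hemoglobin contributions plus a constant background `M` and a
#' Rayleigh `S/lambda^4` scattering term. The model is linear in all five
#' unknowns, so the fit is a constrained linear least squares: the three
#' concentration terms and `S` are constrained nonnegative (solved with a
#' nonnegative least-squares routine, `M` split into positive and negative
#' parts so the baseline may be slightly negative after calibration).
#' Extinction columns are interpolated linearly onto the spectrum grid.
#'
#' @param spectrum An [xy_series()]: wavelength (nm) vs optical density,
#'   with at least 150 points inside 500-700 nm.
#' @param table Extinction table (columns `wavelength`, `eps_hbo2`,
#'   `eps_hb`, `eps_methb`); defaults to the bundled synthetic table.
#' @param absence_threshold Fraction (percent) below which methemoglobin is
#'   reported as absent.
#' @return An object of class `hb_fit`: concentrations `C_HbO2`, `C_Hb`,
#'   `C_MetHb` (concentration-path products, OD scale), `M` (OD), `S`
#'   (OD nm^4), `fractions` (percent, `NA` when the total is zero),
#'   `methb_absent`, `rms_residual`, and the fitted data. Supports
#'   [generics::tidy()], [generics::glance()], [ggplot2::autoplot()].
#' @examples
#' sp <- make_spectrum(list(HbO2 = 85, Hb = 15, MetHb = 0))
#' hb_fractions(unmix(sp))
#' @export
unmix <- function(spectrum, table = make_extinction_table(),
                  absence_threshold = 1) {
  l <- spectrum$x
  in_window <- l >= 500 & l <= 700
  if (sum(in_window) < 150) {
    abort_data("spectrum must cover 500-700 nm with at least 150 points")
  }
  if (min(l) < min(table$wavelength) - 1e-9 ||
      max(l) > max(table$wavelength) + 1e-9) {
    abort_data("extinction table does not cover the spectrum grid")
  }
  interp <- function(col) stats::approx(table$wavelength, col, xout = l)$y
  A <- cbind(hbo2 = interp(table$eps_hbo2),
             hb = interp(table$eps_hb),
             methb = interp(table$eps_methb),
             m_pos = 1,
             m_neg = -1,
             scatter = 1e10 / l^4)
  y <- spectrum$y
  if (all(abs(y) < 1e-14)) {
    fit <- list(C = c(0, 0, 0), M = 0, S = 0, resid = y)
  } else {
    nn <- pracma::lsqnonneg(A, y)
    co <- nn$x
    fit <- list(C = co[1:3], M = co[4] - co[5], S = co[6] * 1e10,
                resid = y - as.vector(A %*% co))
  }
  total <- sum(fit$C)
  fractions <- if (total > 0) 100 * fit$C / total else rep(NA_real_, 3)
  names(fractions) <- c("HbO2", "Hb", "MetHb")
  structure(list(
    C_HbO2 = fit$C[1], C_Hb = fit$C[2], C_MetHb = fit$C[3],
    M = fit$M, S = fit$S, fractions = fractions,
    methb_absent = is.finite(fractions[["MetHb"]]) &&
      fractions[["MetHb"]] < absence_threshold,
    rms_residual = sqrt(mean(fit$resid^2)),
    data = tibble(wavelength = l, od = y, fitted = y - fit$resid)
  ), class = "hb_fit")
}

#' Relative hemoglobin-derivative fractions of a fit
#'
#' @param fit An `hb_fit` from [unmix()].
#' @param absence_threshold Percent below which MetHb is flagged absent.
#' @return One-row tibble: `HbO2`, `Hb`, `MetHb` (percent, summing to 100)
#'   and `methb_absent`.
#' @export
hb_fractions <- function(fit, absence_threshold = 1) {
  total <- fit$C_HbO2 + fit$C_Hb + fit$C_MetHb
  if (!is.finite(total) || total <= 0) {
    abort_data("total hemoglobin concentration is zero: fractions undefined")
  }
  fr <- fit$fractions
  tibble(HbO2 = fr[["HbO2"]], Hb = fr[["Hb"]], MetHb = fr[["MetHb"]],
         methb_absent = fr[["MetHb"]] < absence_threshold)
}

#' @export
print.hb_fit <- function(x, ...) {
  if (all(is.finite(x$fractions))) {
    cat(sprintf("<hb_fit> HbO2 %.1f%%, Hb %.1f%%, MetHb %.1f%%%s\n",
                x$fractions[["HbO2"]], x$fractions[["Hb"]],
                x$fractions[["MetHb"]],
                if (x$methb_absent) " (absent)" else ""))
  } else {
    cat("<hb_fit> zero spectrum: fractions undefined\n")
  }
  cat(sprintf("  M = %.4g OD, S = %.4g OD nm^4, RMS residual %.2g OD\n",
              x$M, x$S, x$rms_residual))
  invisible(x)
}

#' @rdname unmix
#' @param x An `hb_fit`.
#' @param ... Unused.
#' @export
tidy.hb_fit <- function(x, ...) {
  tibble(term = c("C_HbO2", "C_Hb", "C_MetHb", "M", "S"),
         estimate = c(x$C_HbO2, x$C_Hb, x$C_MetHb, x$M, x$S))
}

#' @rdname unmix
#' @export
glance.hb_fit <- function(x, ...) {
  tibble(HbO2_pct = x$fractions[["HbO2"]], Hb_pct = x$fractions[["Hb"]],
         MetHb_pct = x$fractions[["MetHb"]], methb_absent = x$methb_absent,
         M = x$M, S = x$S, rms_residual = x$rms_residual)
}

#' Locate absorption peaks in a spectrum
#'
#' Local maxima whose prominence (height above the deepest saddle towards a
#' higher point) exceeds the threshold; positions are refined by parabolic
#' interpolation through the three samples around each maximum.
#'
#' @param spectrum An [xy_series()] with at least 20 points.
#' @param prominence Minimum prominence in the `y` units (OD).
#' @return Numeric vector of peak positions (nm), sorted ascending; may be
#'   empty.
#' @examples
#' sp <- make_spectrum(list(HbO2 = 100, Hb = 0, MetHb = 0))
#' find_peaks(sp)  # 542 and 577
#' @export
find_peaks <- function(spectrum, prominence = 0.02) {
  y <- spectrum$y
  x <- spectrum$x
  n <- length(y)
  if (n < 20) abort_data("need at least 20 points for peak finding")
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  if (length(idx) == 0) return(numeric(0))
  keep <- vapply(idx, function(i) peak_prominence(y, i) >= prominence, logical(1))
  idx <- idx[keep]
  pos <- vapply(idx, function(i) {
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    delta <- if (denom < 0) 0.5 * (y[i - 1] - y[i + 1]) / denom else 0
    x[i] + max(-0.5, min(0.5, delta)) * (x[min(i + 1, n)] - x[i])
  }, numeric(1))
  sort(pos)
}

peak_prominence <- function(y, i) {
  n <- length(y)
  left <- rev(y[seq_len(i - 1)])
  right <- y[seq(i + 1, n)]
  higher_l <- which(left > y[i])
  higher_r <- which(right > y[i])
  min_l <- if (length(higher_l)) min(left[seq_len(higher_l[1])]) else min(left)
  min_r <- if (length(higher_r)) min(right[seq_len(higher_r[1])]) else min(right)
  y[i] - max(min_l, min_r)
}
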