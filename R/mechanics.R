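#' Convert a force curve to force-indentation form
#'
#' Standard AFM conversion: force `F = k d` (nN) and true indentation
#' `delta = (z - contact_z) - d` (nm); only post-contact points
#' (`delta > 0`) are returned.
#'
#' @param curve An [xy_series()] force curve (piezo-Z nm vs deflection nm).
#' @param contact_z Contact point in nm, inside the curve's z range.
#' @param probe [probe_params()] supplying the spring constant.
#' @param baseline Deflection baseline to subtract (nm).
#' @return Tibble with columns `indentation` (nm) and `force` (nN).
#' @export
to_force_indentation <- function(curve, contact_z, probe = probe_params(),
                                 baseline = 0) {
  if (contact_z < min(curve$x) || contact_z > max(curve$x)) {
    abort_param("contact_z outside the curve's piezo range")
  }
  d <- curve$y - baseline
  delta <- (curve$x - contact_z) - d
  keep <- curve$x > contact_z & delta > 0 & d > 0
  if (!any(keep)) {
    abort_data("no post-contact points: the curve never indents the sample")
  }
  tibble(indentation = delta[keep], force = probe$spring_constant * d[keep])
}

#' Locate the contact point of a force curve
#'
#' Grid search over candidate contact points minimising the total squared
#' residual of the piecewise model: constant baseline before the candidate,
#' Hertz indentation response after it (the modulus has a closed-form
#' least-squares solution at each candidate, see [fit_hertz()]). A coarse
#' pass over the full range is refined around the best candidate.
#'
#' @inheritParams fit_hertz
#' @return Contact point in nm.
#' @export
find_contact_point <- function(curve, probe = probe_params(),
                               fit_max_indentation = 200) {
  fit_hertz(curve, probe, fit_max_indentation)$contact_z
}

#' Fit the Hertz contact model to a force curve
#'
#' Estimates Young's modulus `E` and the contact point jointly. For a
#' spherical tip, `F = (4/3) (E/(1-nu^2)) sqrt(R) delta^(3/2)` is linear in
#' `E` once the contact point is fixed, so each candidate contact point
#' yields a closed-form nonnegative `E` and a residual sum of squares that
#' also scores the pre-contact baseline; the best candidate on a
#' coarse-then-refined grid wins. Only the approach segment up to
#' `fit_max_indentation` enters the fit (small-indentation regime).
#'
#' @param curve An [xy_series()] force curve: piezo-Z (nm) vs deflection
#'   (nm), at least 50 points.
#' @param probe [probe_params()].
#' @param fit_max_indentation Upper indentation bound (nm) for points used
#'   in the fit.
#' @return An object of class `hertz_fit`: list with `E` (kPa), `contact_z`
#'   (nm), `baseline` (nm), `rms_residual` (nN), `n_points_fit`, `probe`
#'   and the force-indentation `data`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' fc <- make_force_curve(4.1, contact_z = 500, noise_sd = 0)
#' fit_hertz(fc)$E
#' @export
fit_hertz <- function(curve, probe = probe_params(), fit_max_indentation = 200) {
  if (nrow(curve) < 50) abort_data("force curve has fewer than 50 points")
  z <- curve$x
  d <- curve$y
  if (max(d) - min(d) < 1e-9 || stats::sd(d) == 0) {
    abort(("curve is flat: no contact found"), class = "rbcnano_no_contact")
  }
  n <- length(z)
  # coarse grid over the ramp, then a finer pass around the best candidate,
  # then continuous refinement of the bracket
  lo <- z[max(2, floor(0.05 * n))]
  hi <- z[floor(0.95 * n)]
  coarse <- seq(lo, hi, length.out = 160)
  sc <- vapply(coarse, hertz_ssr, numeric(1), z = z, d = d, probe = probe,
               cap = fit_max_indentation)
  best <- coarse[which.min(sc)]
  step <- diff(coarse[1:2])
  fine <- seq(best - 3 * step, best + 3 * step, length.out = 121)
  sf <- vapply(fine, hertz_ssr, numeric(1), z = z, d = d, probe = probe,
               cap = fit_max_indentation)
  zf <- fine[which.min(sf)]
  fstep <- diff(fine[1:2])
  opt <- stats::optimize(hertz_ssr, interval = c(zf - fstep, zf + fstep),
                         z = z, d = d, probe = probe,
                         cap = fit_max_indentation, tol = 1e-4)
  z0 <- opt$minimum
  sol <- hertz_solve(z0, z, d, probe, fit_max_indentation)
  if (!is.finite(sol$E) || sol$E <= 0) {
    abort("Hertz fit failed: nonpositive modulus at the optimum",
          class = "rbcnano_fit_error")
  }
  structure(list(E = sol$E, contact_z = z0, baseline = sol$baseline,
                 rms_residual = sol$rms, n_points_fit = sol$n_fit,
                 probe = probe,
                 data = tibble(indentation = sol$delta, force = sol$force)),
            class = "hertz_fit")
}

# closed-form E >= 0 and residuals for one candidate contact point
hertz_solve <- function(z0, z, d, probe, cap) {
  k <- probe$spring_constant
  pre <- z <= z0
  baseline <- if (sum(pre) >= 3) mean(d[pre]) else 0
  dc <- d - baseline
  delta <- (z - z0) - dc
  post <- z > z0 & delta > 0 & delta <= cap
  n_fit <- sum(post)
  if (n_fit < 10) {
    return(list(E = NA_real_, ssr = Inf, rms = Inf, n_fit = n_fit,
                baseline = baseline, delta = numeric(0), force = numeric(0)))
  }
  Fm <- k * dc[post]
  x <- delta[post]^1.5
  coef <- max(0, sum(Fm * x) / sum(x * x))     # nN/nm^(3/2)
  res_post <- Fm - coef * x
  res_pre <- k * dc[pre]
  # score deep-indentation points too (model extrapolated), so that a
  # candidate contact point cannot win by pushing the rising segment out of
  # the fitted window
  deep <- z > z0 & delta > cap
  res_deep <- k * dc[deep] - coef * delta[deep]^1.5
  ssr <- sum(res_post^2) + sum(res_pre^2) + sum(res_deep^2)
  geom <- (4 / 3) * sqrt(probe$radius) / (1 - probe$poisson_ratio^2)
  list(E = coef / geom * 1e6, ssr = ssr,
       rms = sqrt(mean(res_post^2)), n_fit = n_fit, baseline = baseline,
       delta = delta[post], force = Fm)
}

hertz_ssr <- function(z0, z, d, probe, cap) hertz_solve(z0, z, d, probe, cap)$ssr

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("<hertz_fit> E = %.3g kPa, contact at %.1f nm, %d points, RMS %.3g nN\n",
              x$E, x$contact_z, x$n_points_fit, x$rms_residual))
  invisible(x)
}

#' @rdname fit_hertz
#' @param x A `hertz_fit`.
#' @param ... Unused.
#' @export
tidy.hertz_fit <- function(x, ...) {
  tibble(term = c("E_kPa", "contact_z_nm", "baseline_nm"),
         estimate = c(x$E, x$contact_z, x$baseline))
}

#' @rdname fit_hertz
#' @export
glance.hertz_fit <- function(x, ...) {
  tibble(E_kPa = x$E, contact_z_nm = x$contact_z,
         rms_residual_nN = x$rms_residual, n_points_fit = x$n_points_fit)
}
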