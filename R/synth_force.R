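#' Generate a synthetic AFM force curve
#'
#' Forward model of a spherical-tip indentation experiment. Before the
#' contact point the deflection is zero (plus noise); after contact the
#' cantilever deflection `d` at piezo position `z` solves the Hertz
#' self-consistency equation
#' `k d = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2)` with the true
#' indentation `delta = (z - contact_z) - d` (the piezo travel is shared
#' between indenting the sample and bending the cantilever). The implicit
#' equation is solved per point by safeguarded Newton iteration; Gaussian
#' noise of SD `noise_sd` is then added to the deflection.
#'
#' @param E Young's modulus in kPa (> 0).
#' @param probe [probe_params()]: tip radius nm, spring constant N/m,
#'   Poisson ratio.
#' @param contact_z Piezo position of tip-sample contact, nm.
#' @param max_indentation Maximum true indentation reached, nm.
#' @param noise_sd Deflection noise SD, nm.
#' @param seed RNG seed.
#' @param n_points Samples along the piezo ramp.
#' @return An [xy_series()]: `x` piezo-Z (nm), `y` deflection (nm).
#' @examples
#' fc <- make_force_curve(4.1, probe_params(), contact_z = 500,
#'                        max_indentation = 400, noise_sd = 0)
#' @export
make_force_curve <- function(E, probe = probe_params(), contact_z = 500,
                             max_indentation = 500, noise_sd = 0.3,
                             seed = NULL, n_points = 600) {
  if (!is.numeric(E) || E <= 0) abort_param("E must be a positive modulus in kPa")
  if (max_indentation < 0) abort_param("max_indentation must be >= 0")
  B <- hertz_prefactor(E, probe)              # nN / nm^(3/2)
  k <- probe$spring_constant                  # N/m == nN/nm
  d_max <- B * max_indentation^1.5 / k
  z_max <- contact_z + max_indentation + d_max
  z <- seq(0, z_max, length.out = n_points)
  d <- hertz_deflection(z, contact_z, B, k)
  with_seed(seed, {
    if (noise_sd > 0) d <- d + stats::rnorm(length(d), 0, noise_sd)
    xy_series(z, d, units = c("piezo_z_nm", "deflection_nm"))
  })
}

# (4/3) * E/(1-nu^2) * sqrt(R) in nN/nm^(3/2); E in kPa = 1e-6 nN/nm^2
hertz_prefactor <- function(E_kPa, probe) {
  (4 / 3) * (E_kPa * 1e-6) / (1 - probe$poisson_ratio^2) * sqrt(probe$radius)
}

# solve k d = B ((z - z0) - d)^(3/2) for d at each z (vectorised Newton)
hertz_deflection <- function(z, z0, B, k) {
  s <- pmax(z - z0, 0)   # available travel past contact
  d <- rep(0, length(z))
  on <- s > 0
  if (!any(on) || B <= 0) return(d)
  di <- rep(0, sum(on))
  si <- s[on]
  for (it in 1:60) {
    delta <- pmax(si - di, 0)
    f <- k * di - B * delta^1.5
    fp <- k + 1.5 * B * sqrt(delta)
    step <- f / fp
    di <- pmin(pmax(di - step, 0), si)
    if (max(abs(step)) < 1e-12) break
  }
  d[on] <- di
  d
}
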