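#' Generate a synthetic amperometric ROS trace
#'
#' Models the current recorded while a nanoelectrode approaches and enters
#' a cell: a flat baseline, a sigmoidal rise at `approach_time`, and a
#' plateau at `peak`, with additive Gaussian noise.
#'
#' @param baseline Baseline current, pA (>= 0).
#' @param peak Plateau current, pA (> baseline).
#' @param approach_time Time of the rise midpoint, s.
#' @param noise_sd Current noise SD, pA.
#' @param seed RNG seed.
#' @param duration Trace length, s.
#' @param rate Sampling rate, Hz.
#' @param rise_tau Sigmoid time constant, s.
#' @return An [xy_series()]: time (s) vs current (pA).
#' @export
make_current_trace <- function(baseline, peak, approach_time = 4,
                               noise_sd = 0, seed = NULL, duration = 10,
                               rate = 100, rise_tau = 0.2) {
  if (baseline < 0) abort_param("baseline must be >= 0")
  if (peak <= baseline) abort_param("peak must exceed baseline")
  t <- seq(0, duration, by = 1 / rate)
  i <- baseline + (peak - baseline) / (1 + exp(-(t - approach_time) / rise_tau))
  with_seed(seed, {
    if (noise_sd > 0) i <- i + stats::rnorm(length(i), 0, noise_sd)
    xy_series(t, i, units = c("time_s", "current_pA"))
  })
}

#' Baseline current of a trace
#'
#' Median of the first `baseline_fraction` of samples (robust to the odd
#' early transient).
#'
#' @param trace An [xy_series()] current trace with >= 20 points.
#' @param baseline_fraction Fraction of initial samples used.
#' @return Baseline current, pA.
#' @export
baseline_current <- function(trace, baseline_fraction = 0.2) {
  n <- nrow(trace)
  if (n < 20) abort_data("trace too short: need at least 20 samples")
  k <- max(1, floor(baseline_fraction * n))
  stats::median(trace$y[seq_len(k)])
}

#' Maximum current of a trace
#'
#' Maximum of the moving-median-smoothed trace; the median window rejects
#' single-sample spikes that would otherwise masquerade as the plateau.
#'
#' @param trace An [xy_series()] with >= 20 points.
#' @param smooth_window Moving-median window in samples (odd; even values
#'   are bumped up).
#' @return Maximum smoothed current, pA.
#' @export
max_current <- function(trace, smooth_window = 5) {
  if (nrow(trace) < 20) abort_data("trace too short: need at least 20 samples")
  k <- as.integer(smooth_window)
  if (k %% 2 == 0) k <- k + 1L
  y <- if (k > 1) stats::runmed(trace$y, k, endrule = "median") else trace$y
  max(y)
}

#' Normalised intracellular ROS level
#'
#' The baseline-corrected maximum oxidation current, normalised to the
#' reference current measured in a ferrocene standard solution:
#' `(max - baseline) / reference`.
#'
#' @param max Maximum current, pA.
#' @param baseline Baseline current, pA.
#' @param reference Ferrocene reference current, pA (> 0).
#' @return Dimensionless normalised ROS level.
#' @export
normalize_ros <- function(max, baseline, reference) {
  if (!is.numeric(reference) || reference <= 0) {
    abort_param("reference current must be > 0")
  }
  (max - baseline) / reference
}

#' Reduce a current trace to a normalised ROS record
#'
#' @param trace An [xy_series()] current trace.
#' @param reference Ferrocene reference current, pA.
#' @param baseline_fraction,smooth_window See [baseline_current()] and
#'   [max_current()].
#' @return One-row tibble: `baseline_pA`, `max_pA`, `normalized`.
#' @export
trace_ros <- function(trace, reference = 100, baseline_fraction = 0.2,
                      smooth_window = 5) {
  b <- baseline_current(trace, baseline_fraction)
  m <- max_current(trace, smooth_window)
  tibble(baseline_pA = b, max_pA = m,
         normalized = normalize_ros(m, b, reference))
}

#' Group summary of normalised ROS values
#'
#' @param values Numeric vector of normalised ROS levels.
#' @return One-row tibble: `n`, `mean`, `sd`, `sem`.
#' @export
ros_summary <- function(values) {
  tibble(n = length(values), mean = mean(values), sd = stats::sd(values),
         sem = stats::sd(values) / sqrt(length(values)))
}
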