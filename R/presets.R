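#' Experimental-condition presets
#'
#' Parameter sets for the synthetic-data generators, one per experimental
#' group (pH level x incubation time). Each preset encodes the group values
#' reported for real cells so that parameter-recovery tests exercise the
#' pipeline under realistic conditions:
#'
#' * `texture`: waviness/roughness amplitudes and periods (nm). The control
#'   group is h1 = 2.7, L1 = 939, h2 = 0.9, L2 = 98.5 nm; the 7-h acidic and
#'   alkaline groups apply the reported fold changes (h1 x5, h2 x3.3/x3.4,
#'   L1 x1.5/x1.4, L2 x2/x1.8).
#' * `composition`: percentage of discocytes/echinocytes/codocytes. Only the
#'   7-h pH 6.4 (54/42/4) and pH 8.4 (56/38/6) groups are fully reported;
#'   the remaining groups are filled in consistently with the reported fold
#'   changes in echinocyte counts.
#' * `mesh`: cytoskeletal pore density per 2x2 um^2 and mean max-Feret pore
#'   length (um). Control: 125 pores per 2x2 um^2, 0.13 um.
#' * `elastic`: population mean and SD of Young's modulus (kPa). Control
#'   30 min: 4.1 +/- 1.6 kPa; control 7 h: 5.6 +/- 1.0 kPa.
#' * `hemoglobin`: HbO2/Hb/MetHb percentages (84/16, 85/15, 86/14, MetHb
#'   absent).
#' * `ros`: relative plateau currents; the 7-h acidic/alkaline groups are
#'   twice their 30-min values, the 7-h control 1.7x its 30-min value.
#'
#' @param group One of `"control"` (alias of `"ph74_30m"`), `"ph64_30m"`,
#'   `"ph84_30m"`, `"ph74_7h"`, `"ph64_7h"`, `"ph84_7h"`.
#' @return A named list with elements `texture`, `composition`, `mesh`,
#'   `elastic`, `hemoglobin`, `ros`.
#' @examples
#' preset("control")$texture
#' @export
preset <- function(group = c("control", "ph74_30m", "ph64_30m", "ph84_30m",
                             "ph74_7h", "ph64_7h", "ph84_7h")) {
  group <- match.arg(group)
  if (group == "control") group <- "ph74_30m"
  p <- rbcnano_presets[[group]]
  if (is.null(p)) abort_param(sprintf("unknown preset group '%s'", group))
  p
}

texture_params <- function(h1, L1, h2, L2, n_components = 64L) {
  if (!(L1 > L2 && L2 > 0)) abort_param("need L1 > L2 > 0")
  if (h1 < 0 || h2 < 0) abort_param("amplitudes must be >= 0")
  list(h1 = h1, L1 = L1, h2 = h2, L2 = L2, n_components = as.integer(n_components))
}

composition_params <- function(discocyte, echinocyte, codocyte) {
  fr <- c(discocyte = discocyte, echinocyte = echinocyte, codocyte = codocyte)
  if (any(fr < 0) || any(fr > 100)) abort_param("fractions must be in [0, 100]")
  if (abs(sum(fr) - 100) > 1e-8) abort_param("fractions must sum to 100")
  as.list(fr)
}

mesh_params <- function(pore_density, mean_pore_length, ridge_width = NULL) {
  if (pore_density <= 0) abort_param("pore_density must be > 0")
  if (mean_pore_length <= 0) abort_param("mean_pore_length must be > 0")
  list(pore_density = pore_density, mean_pore_length = mean_pore_length,
       ridge_width = ridge_width)
}

#' AFM probe parameters
#'
#' @param radius Tip radius in nm (default 150 nm, the force-spectroscopy
#'   probe used for red blood cells).
#' @param spring_constant Cantilever spring constant in N/m (default 1).
#' @param poisson_ratio Sample Poisson ratio; 0.5 treats the cell as
#'   incompressible.
#' @return A named list of class `probe_params`.
#' @export
probe_params <- function(radius = 150, spring_constant = 1, poisson_ratio = 0.5) {
  if (radius <= 0) abort_param("probe radius must be > 0")
  if (spring_constant <= 0) abort_param("spring constant must be > 0")
  if (poisson_ratio < 0 || poisson_ratio > 0.5) {
    abort_param("poisson_ratio must be in [0, 0.5]")
  }
  structure(list(radius = radius, spring_constant = spring_constant,
                 poisson_ratio = poisson_ratio), class = "probe_params")
}

ctrl_tex <- function() texture_params(h1 = 2.7, L1 = 939, h2 = 0.9, L2 = 98.5)

rbcnano_presets <- local({
  tex <- function(fh1, fL1, fh2, fL2) {
    texture_params(h1 = 2.7 * fh1, L1 = 939 * fL1, h2 = 0.9 * fh2, L2 = 98.5 * fL2)
  }
  list(
    ph74_30m = list(
      texture = tex(1, 1, 1, 1),
      composition = composition_params(94, 6, 0),
      mesh = mesh_params(125, 0.13),
      elastic = list(mean = 4.1, sd = 1.6),
      hemoglobin = list(HbO2 = 85, Hb = 15, MetHb = 0),
      ros = list(baseline = 1, peak = 11, reference = 100)
    ),
    ph64_30m = list(
      texture = tex(1, 1, 1, 1),
      composition = composition_params(58, 42, 0),
      mesh = mesh_params(115, 0.195),
      elastic = list(mean = 8.2, sd = 2.0),
      hemoglobin = list(HbO2 = 84, Hb = 16, MetHb = 0),
      ros = list(baseline = 1, peak = 16, reference = 100)
    ),
    ph84_30m = list(
      texture = tex(1, 1, 1, 1),
      composition = composition_params(77, 23, 0),
      mesh = mesh_params(115, 0.195),
      elastic = list(mean = 7.6, sd = 2.0),
      hemoglobin = list(HbO2 = 86, Hb = 14, MetHb = 0),
      ros = list(baseline = 1, peak = 16, reference = 100)
    ),
    ph74_7h = list(
      texture = tex(1, 1, 1, 1.3),
      composition = composition_params(67, 30, 3),
      mesh = mesh_params(100, 0.13),
      elastic = list(mean = 5.6, sd = 1.0),
      hemoglobin = list(HbO2 = 85, Hb = 15, MetHb = 0),
      ros = list(baseline = 1, peak = 11 * 1.7, reference = 100)
    ),
    ph64_7h = list(
      texture = tex(5, 1.5, 3.3, 2),
      composition = composition_params(54, 42, 4),
      mesh = mesh_params(125 / 2.6, 0.13 * 1.7),
      elastic = list(mean = 8.2 * 1.1, sd = 2.2),
      hemoglobin = list(HbO2 = 84, Hb = 16, MetHb = 0),
      ros = list(baseline = 1, peak = 32, reference = 100)
    ),
    ph84_7h = list(
      texture = tex(5, 1.4, 3.4, 1.8),
      composition = composition_params(56, 38, 6),
      mesh = mesh_params(125 / 1.7, 0.13 * 1.4),
      elastic = list(mean = 7.6 * 1.2, sd = 2.2),
      hemoglobin = list(HbO2 = 86, Hb = 14, MetHb = 0),
      ros = list(baseline = 1, peak = 32, reference = 100)
    )
  )
})

#' Default analysis configuration
#'
#' All tunables of the analysis stages in one nested list; [load_config()]
#' merges a YAML file over these defaults, and every CLI flag overrides both.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    surface = list(cutoff_nm = 300, flatten_order = 1L),
    morphology = list(
      min_height_nm = 200, min_area_um2 = 10, max_area_um2 = 80,
      n_radial_bins = 24L, n_angular_bins = 90L, rim_radius = 0.8,
      spicule_min = 6L, prominence_factor = 2.0, prominence_floor = 0.04,
      dome_threshold = 0.05, dimple_threshold = 0.05
    ),
    pores = list(smooth_sigma_nm = 10, depth_threshold_nm = 0.5,
                 min_area_um2 = 1e-4),
    elastic = list(fit_max_indentation_nm = 200,
                   probe = list(radius = 150, spring_constant = 1,
                                poisson_ratio = 0.5)),
    spectra = list(absence_threshold = 1, peak_prominence = 0.02),
    ros = list(baseline_fraction = 0.2, smooth_window = 5L, reference_pA = 100),
    scene = list(pixel_size_nm = 60, cell_diameter_um = 7.5,
                 cell_height_nm = 1600)
  )
}

#' Load a YAML configuration file over the defaults
#'
#' @param path YAML file; keys mirror [default_config()]. `NULL` returns the
#'   defaults unchanged.
#' @return Nested named list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) abort_format(sprintf("no such config file: %s", path))
  user <- yaml::read_yaml(path)
  merge_lists(cfg, user)
}

merge_lists <- function(base, over) {
  for (k in names(over)) {
    if (is.list(over[[k]]) && is.list(base[[k]])) {
      base[[k]] <- merge_lists(base[[k]], over[[k]])
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}
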