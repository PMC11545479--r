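---
title: "Methods: nanoscale morphometry and biophysics of red blood cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nanoscale morphometry and biophysics of red blood cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcnano)
```

`rbcnano` implements the quantitative chain used to characterise red blood
cells (RBCs) under acid-base stress with scanning-probe and optical methods:
AFM surface metrology, shape classification, cytoskeletal pore analysis,
force-curve elasticity, hemoglobin spectral unmixing, amperometric ROS
reduction, and the group statistics that tie the stages together. Because
raw instrument data for such studies are rarely deposited, the package pairs
every analysis stage with a synthetic-data generator whose ground truth is
known exactly, so each stage is validated by parameter recovery rather than
by comparison to an unavailable reference dataset.

This vignette documents the models, parameter conventions, numerical
choices, and the limits of what the recovery tests demonstrate.

## Surface metrology: waviness and roughness

An AFM height map of a cell membrane mixes two lateral scales: a micron-scale
*waviness* (amplitude $h_1$, period $L_1$) tracking the underlying
spectrin-actin network, and a sub-100 nm *roughness* ($h_2$, $L_2$) of the
membrane itself. The decomposition is a 2D Fourier band split:

1. `flatten()` removes a least-squares polynomial background (degree 1-3) —
   cells are curved objects and any roughness statistic on an unflattened
   patch measures mostly curvature.
2. `decompose_bands()` multiplies the 2D spectrum by a radial raised-cosine
   filter with relative transition width 0.2 around the cutoff frequency
   $1/\lambda_c$, returning complementary low/high maps whose sum is exactly
   the input. The image is mirror-padded before the FFT so that the periodic
   extension is continuous; without this, edge discontinuities leak waviness
   power into the roughness band (a ~6 % upward bias on $h_2$ in our
   measurements).
3. `band_params()` reports, per band, $h = 2\sqrt{2}\,\mathrm{RMS}$ (the
   peak-to-valley amplitude of the equivalent single sinusoid) and
   $L = 1/f_\mathrm{peak}$, with $f_\mathrm{peak}$ the power-weighted
   centroid of the two annuli either side of the radial-spectrum mode.

Neither $h$ nor $L$ has a universal definition in AFM practice; the package
fixes the two conventions above and uses the *same* conventions in the
texture generator, which is what makes recovery a genuine round trip rather
than a fit of one arbitrary convention to another.

**Cutoff choice.** The default cutoff is 300 nm, the approximate geometric
midpoint between the two scales observed on RBCs ($L_2 \approx 100$ nm,
$L_1 \approx 900$ nm). It is exposed as `cutoff_wavelength` everywhere.

**Resolution limits.** The radial spectrum has annulus width $1/(N p)$ for an
$N$-pixel image at $p$ nm/px. On the default 512-pixel, 10 nm/px field the
939 nm waviness period spans only ~5.5 annuli, so the period estimate
carries a small (+2-3 %) discretisation bias; amplitudes are unbiased to
within a fraction of a percent. The texture generator requires every band
period to lie in $[4p,\ Np/4]$ and refuses otherwise.

The radial PSD itself (`radial_psd()`) is Hann-windowed and reported as an
isotropic 2D density, normalised so that integrating power over frequency
area returns the map variance (Parseval), which the tests assert within 3 %.

## Shape classification

Three archetypes are distinguished, following the standard morphological
series: the biconcave **discocyte**, the spiculated **echinocyte**, and the
target-cell **codocyte**. Segmentation (`segment_cells()`) is a height
threshold (default 200 nm above the substrate) plus connected components;
border-touching components are discarded and components outside 10-80 µm²
(a plausible single-RBC footprint) are dropped rather than split — touching
or overlapping cells are out of scope.

Classification works on two 1D reductions of each cell
(`radial_profile()`): the mean height versus normalised radius, and the
height sampled on a circle at 0.8 of the cell radius. The decision rule
(`classify_cell()`), applied in order:

1. **echinocyte** — at least `spicule_min = 6` angular maxima whose circular
   prominence exceeds both `2.0` rim-series SDs and 4 % of the cell height
   (the absolute floor stops pixel-interpolation ripple on smooth cells
   from counting as spicules);
2. **codocyte** — dome index (centre minus mid-radius minimum, height-
   normalised) above 0.05;
3. **discocyte** — dimple index (rim maximum minus centre) above 0.05;
4. otherwise **unclassified** (stomatocytes and spherocytes, which the
   generator does not produce, would land here).

All indices are normalised by cell height, so labels are invariant to
uniform height scaling, translation and 90° rotation (tested). The
thresholds separate the three parametric archetypes with wide margin; on
real data they are starting points, and all are config-exposed.

## Cytoskeleton pore analysis

Spread RBC ghosts imaged at high resolution show the spectrin-actin mesh as
ridges enclosing depressions ("pores"). `detect_pores()` segments them by
topographic watershed (EBImage) of the inverted, Gaussian-smoothed relief
(`smooth_sigma` 10 nm), with basins merged when their minimum is less than
`depth_threshold` = 0.5 nm deep. Separation runs on the smoothed relief, but
the filament/pore classification is a per-pixel threshold on the *raw*
heights at the filament mid-height (midpoint of the robust 1 %/99 %
quantiles): smoothing is good for suppressing spurious minima but
systematically erodes pore boundaries if used for the mask too.

Pores touching the image frame are excluded, and the pore density is
rescaled by the interior-area fraction, where the excluded area is the full
watershed basin (pore plus its filament share) of every border pore —
rescaling by the pore mask alone would undercount the excluded territory
and bias the density low by ~10 %. Pore length is the maximum Feret
diameter, computed on the convex hull (and cross-checked in the tests
against a brute-force all-pairs oracle, which it must match exactly).

**The mesh generator is calibrated, not free.** A Poisson-Voronoi
tessellation with 125 pores per 2×2 µm² would have a mean max-Feret of
$1.49/\sqrt{\lambda} \approx 0.27$ µm — twice the observed 0.13 µm. The two
observables are reconcilable only if filaments have finite width: the
observable pore is its Voronoi cell eroded by half the filament width. The
generator therefore solves, from a frozen simulation-derived curve (scaled
erosion depth $u$ versus cell survival $s(u)$ and scaled survivor Feret
$f(u)$), for the seed intensity and erosion depth that deliver the requested
density *and* mean Feret; for the control preset this gives a filament FWHM
of ~90 nm, consistent with tip-broadened spectrin filaments in AFM images.
Cells whose eroded interior falls below the detector's minimum pore area
(10⁻⁴ µm²) are not counted as ground-truth pores, mirroring the detector's
own floor.

## Force curves and elasticity

The forward model (`make_force_curve()`) is the spherical-indenter Hertz
law with the cantilever in series: at piezo position $z$ past contact $z_0$,
the deflection $d$ solves

$$ k d = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2},
\qquad \delta = (z - z_0) - d, $$

solved per point by safeguarded Newton iteration. Defaults follow the
experimental configuration: $R = 150$ nm, $k = 1$ N/m; $\nu = 0.5$
(incompressible cell) and the spherical geometry are declared conventions —
instrument software rarely documents either.

`fit_hertz()` estimates $(E, z_0)$ jointly: for fixed $z_0$ the model is
linear in $E$, giving a closed-form nonnegative estimate, and the total
squared residual (baseline before $z_0$, Hertz after, with the fitted model
also scored on points deeper than the fit window so that a candidate cannot
win by pushing the informative segment out of range) is minimised over a
coarse-to-fine grid with a final continuous refinement. The fit uses the
approach segment up to `fit_max_indentation` = 200 nm (small-indentation
regime).

**Information limit on the contact point.** At the soft-cell conditions
(4 kPa, 150 nm tip, 1 N/m lever, 0.3 nm deflection noise) the deflection a
few tens of nm past contact is a small fraction of the noise SD, and the
residual landscape around $z_0$ is nearly flat: the per-curve contact-point
estimate has an irreducible spread of roughly ±30 nm. This is a property of
the measurement, not the optimiser; the modulus is far better conditioned
(population means recover within ~3 %), and the tests assert the
contact point at the attainable level (exact without noise, unbiased as a
cohort mean with noise).

## Hemoglobin spectral unmixing

An RBC suspension's optical density over 500-700 nm is modelled as

$$ D(\lambda) = \varepsilon_{\mathrm{HbO_2}}(\lambda) C_{\mathrm{HbO_2}}
 + \varepsilon_{\mathrm{Hb}}(\lambda) C_{\mathrm{Hb}}
 + \varepsilon_{\mathrm{MetHb}}(\lambda) C_{\mathrm{MetHb}}
 + M + S\lambda^{-4}, $$

with background $M$ and Rayleigh scattering $S$. The geometric light path
appears only multiplied by the concentrations and is folded into them
(only relative fractions are reported). The model is linear in all five
unknowns, so `unmix()` is a constrained linear least squares: concentrations
and $S$ nonnegative (solved with `pracma::lsqnonneg`; $M$ is split into
positive and negative parts so a slightly negative baseline after
calibration remains representable). No nonlinear optimiser is involved, and
noiseless recovery is exact to numerical precision. A MetHb fraction below
1 % is flagged "absent".

The bundled extinction table (`make_extinction_table()`) is **synthetic**:
Gaussian bands reproducing the qualitative features the analysis relies on —
the HbO₂ doublet with maxima exactly at 542 and 577 nm, a broad Hb band at
555 nm, a distinct MetHb band at 630 nm, all strictly positive. It removes
the dependency on tabulated literature coefficients while preserving every
testable property; `unmix()` accepts a user-supplied real table in the same
schema, and fractions are insensitive to the (arbitrary) units of the
table. `find_peaks()` reports local maxima above a prominence threshold with
parabolic sub-sample refinement.

## ROS traces

The amperometric reduction is deliberately simple and robust: baseline =
median of the first 20 % of samples; maximum = maximum of the 5-sample
moving median (single-sample spikes are rejected); normalised level =
(max − baseline)/reference, with the ferrocene reference current supplied
by the user. Baseline subtraction before normalisation is a declared choice
(it makes the value invariant to a constant offset on the whole trace);
whether the original instrument workflow subtracts it is not documented,
and only ratios between groups are scientifically interpreted here.

## Statistics

Group comparisons use the two-sided Mann-Whitney U test uniformly
(`mann_whitney()`, backed by `stats::wilcox.test`): exact enumeration when
$n \cdot m \le 400$ with no ties, else the normal approximation with
midranks, tie correction and continuity correction. The worst-case
disagreement between the two branches at 8 vs 8 is 0.011 in $p$ — a
property of the approximation, documented in the tests. `pearson()`,
`fold_change()`, `star_code()` and `pairwise_stats()` complete the
reporting layer. No multiple-testing correction is applied by default
(matching per-comparison reporting conventions); a Bonferroni option
exists in `pairwise_stats()`. One-way ANOVA is intentionally not part of
the default path.

## What the synthetic generators do and do not emulate

The generators reproduce: banded isotropic surface texture with controlled
amplitudes and periods; non-overlapping parametric cell shapes with size
jitter (textbook geometry: 7.5 µm diameter, 1.6 µm rim height, both
config-exposed — cell-size distributions are not reported for this system);
an eroded-Voronoi filament mesh; Hertzian force curves with deflection
noise; linear-mixture absorption spectra with background and $\lambda^{-4}$
scattering; sigmoidal approach traces.

They do **not** emulate: AFM tip convolution (the real pre-processing
deconvolves the tip shape; synthetic maps have no tip artifact), scanner
drift or line noise, touching/overlapping cells, stomatocytes and
spherocytes, filament-thickness variation, electrode physics, or real
literature extinction coefficients. Passing recovery tests therefore
demonstrates the correctness and calibration of the analysis chain under
its stated model assumptions — not robustness to every artifact of real
instrument data.

## Problem sizes and determinism

Every generator takes a `seed` and is bit-reproducible given it (RNG state
is restored afterwards). The recovery batteries use the sizes at which the
study conditions are stated: 20 surfaces of 512² at 10 nm/px; 10 meshes of
1024² over 2×2 µm; 100-curve cohorts with log-normal moduli; 20 scenes of
100 cells for classification (5 scenes in the headline recovery run); 50
traces per ROS cohort; 1000 null replicates for the test-size check. On a
single CPU the full test suite runs in about four minutes and the
acceptance script in about two.

## Known limitations

* The period estimate $L_1$ carries a small positive discretisation bias
  (~2-3 % at the default field of view); enlarging the field removes it.
* The contact-point estimate is information-limited on soft cells (above).
* The classifier is a fixed-threshold rule tuned to separated archetypes;
  intermediate real morphologies will land in `unclassified` rather than
  being force-assigned.
* Pore statistics assume pores are depressions enclosed by brighter
  filaments; inverted-contrast images must be negated first.
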