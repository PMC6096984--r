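---
title: "Curvature-elastic analysis of light-induced vesicle budding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-elastic analysis of light-induced vesicle budding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(0)
```

```{r setup}
library(vesicurv)
```

## The physical problem

Giant unilamellar vesicles (GUVs) doped with a photoswitchable amphiphile
change shape under illumination: the membrane gains area and acquires a
spontaneous (preferred) curvature, and the vesicle expels micron-scale buds.
Three measurable quantities capture this process, and this package computes
all three from raw tabular data:

1. **How much switch is in the membrane** — from size-exclusion
   chromatography (SEC) absorbance traces.
2. **How much area the light adds** — from electrodeformation time series,
   where an AC field stretches the vesicle into a prolate spheroid so that
   its true area can be read off the semiaxes.
3. **What spontaneous curvature the budded shapes imply** — from the radii
   of mother vesicle and bud via the closed-neck condition of the
   spontaneous-curvature / area-difference-elasticity (ADE) framework.

## Shape descriptors

A vesicle with membrane area $A$ and enclosed volume $V$ is characterised by
its *reduced volume*

$$\nu = \frac{6\sqrt{\pi}\,V}{A^{3/2}} \in (0, 1],$$

the volume relative to a sphere of equal area ($\nu = 1$ for a sphere;
$\nu < 1$ means excess area), and by the *dimensionless spontaneous
curvature* $\bar m = m\,R_{ve}$ with the vesicle size
$R_{ve} = \sqrt{A/4\pi}$. Units are fixed package-wide: µm, µm², µm³, µm⁻¹.

```{r}
two_sphere_geometry(R_alpha = 10, R_beta = 1.5)
```

## The closed-neck condition

Budded shapes are idealised as two tangent spheres — mother radius
$R_\alpha$, bud radius $R_\beta$ — joined by a neck of zero measure. Energy
minimisation in both the spontaneous-curvature and the ADE model requires an
*effective* spontaneous curvature $m_{eff} = m + m_{nlo}$, the sum of the
local contribution $m$ (bilayer/solution asymmetry) and the nonlocal
contribution $m_{nlo}$ (the ADE preference for a particular leaflet-area
difference). At a closed neck,

$$m_{eff} = \tfrac12\left(\frac{1}{R_\alpha} + \frac{1}{R_\beta}\right),
\qquad
m_{nlo} = \pi\,\frac{\kappa'}{\kappa}\,
  \frac{\sqrt{R_\alpha^2+R_\beta^2} - R_\alpha - R_\beta}
       {R_\alpha^2 + R_\beta^2},$$

where $\kappa'/\kappa$ is the ratio of nonlocal to local bending rigidity
(only the ratio ever enters). The bracketed difference is negative for all
positive radii, so $m_{nlo} \le 0$: the nonlocal term always opposes outward
budding, and the local curvature solving the condition,
$2m = 1/R_\alpha + 1/R_\beta - 2m_{nlo}$, *increases* with $\kappa'/\kappa$.
The typeset form of this relation is ambiguous about the grouping of the
radical; the adopted algebra is isolated in a single internal function and
guarded by two invariants that any correct grouping must satisfy —
$m_{nlo} \le 0$, and $m$ increasing in $\kappa'/\kappa$ at fixed shape —
both enforced by property tests.

```{r}
neck_curvature(R_alpha = 10, R_beta = 1.5, kappa_ratio = 1)
```

## Morphology diagram and limit shapes

For each $\kappa'/\kappa$, sweeping the bud-to-mother ratio
$x = R_\beta/R_\alpha \in (0, 1]$ traces the *line of limit shapes* in the
$(\nu, \bar m)$ plane — the boundary at which membrane necks close. Both
coordinates are scale invariant; the two-sphere reduced volume is
$\nu(x) = (1+x^3)/(1+x^2)^{3/2}$, decreasing from 1 (vanishing bud) to
$1/\sqrt 2$ (equal spheres), so the attainable band is
$\nu \in (1/\sqrt 2, 1)$. Inversion of $\nu(x)$ (needed to place a measured
$\nu$ on the theoretical curve) uses bracketed bisection — bisection is the
only root finder in the package, chosen for robustness over speed at the
problem sizes involved; the tolerance is $10^{-12}$ on $x$ and brackets are
verified before iteration.

`neck_fit()` is the package's central model fit: it applies the neck
condition to a population of measured $(R_\alpha, R_\beta)$ pairs over a
grid of rigidity ratios (default $\{0, 0.5, 1, 1.5, 2\}$, the standard
range) and returns a classed object with `print`, `summary`, `coef`,
`predict` and `plot` methods; `plot` draws the morphology diagram with the
theoretical lines and the per-vesicle points.

```{r, fig.width = 6, fig.height = 4.5}
pop <- gen_budded_population(n = 10, m_true = 0.4, kappa_ratio = 0,
                             radius_noise = 0.02, seed = 42)
fit <- neck_fit(pop$shapes, kappa_ratio = c(0, 1))
summary(fit)
plot(fit)
```

Summaries report the population mean of $m$ with the across-vesicle standard
deviation as the primary dispersion (the spread over vesicles, not the
standard error; both are emitted), and also as a reciprocal length
$1/(x\,\mu m)$ — the field's convention for micron-scale curvatures — with
the uncertainty on $x$ propagated to first order, $sd_x = sd_m/m^2$.

## Electrodeformation area extraction

The relative area increase upon photoisomerisation is
$\bar{\Delta A} = (A_{UV} - A)/A$. The baseline $A$ is the area at *maximal
pre-UV deformation* — not the first frame — because only after the field has
pulled the excess area out of thermal fluctuations does the ellipse area
equal the true membrane area. Both $A$ and $A_{UV}$ come from the frame of
maximal aspect ratio in their window (ties broken by earliest time; an
optional 5-frame rolling median resists single-frame outliers and is off by
default). Prolate area and volume use the exact closed forms, with a series
branch near the sphere limit ($a/b - 1 < 10^{-8}$) to avoid dividing by the
vanishing eccentricity.

```{r}
series <- gen_deformation_series(delta_A_max = 0.046, frame_noise = 0)
analyze_series(series)
```

## SEC partitioning

The membrane-incorporated switch elutes with the vesicles (narrow peak near
5.4 mL), ahead of the free molecule (overlapping peaks near 7.0 and
8.1 mL). Peak areas are trapezoidal integrals over user-set windows,
optionally above a linear baseline. The calibration is proportional
response: equal molar absorbance for free and inserted switch at the
detection wavelength, so
$c_{inc} = c_{tot}\,\cdot$ (incorporated area)/(total area). This is a
declared assumption — the minimal one for single-wavelength quantification —
not a fitted model; Gaussian deconvolution of the overlapping free peaks is
deliberately not the default, since the incorporated/free split only needs
the window boundary between 6 and 7 mL where the trace is near baseline.

```{r}
trace <- gen_elution_trace()
partition_analysis(trace, incorporated_window = c(4.8, 6.0),
                   free_windows = list(c(6.0, 7.55), c(7.55, 9.3)),
                   c_total = 0.25e-3, c_lipid = 0.1e-3)
```

## What the synthetic data emulate — and what they do not

Every analysis stage has a seeded generator producing inputs with recorded
ground truth, so the full pipeline is testable without any microscopy or
chromatography raw data:

* `gen_budded_population()` inverts the neck condition: mother radii are
  log-normal (median 7.5 µm, log-sd 0.25, a typical GUV batch), the bud
  radius solves the neck condition for the prescribed true curvature
  (default 0.4 µm⁻¹ = 1/(2.5 µm), the scale relevant for micron-sized
  buds), and 2 % multiplicative radius noise emulates image-analysis error.
  Radii that admit no bud are rejected and counted, never clamped — clamping
  would bias recovery tests.
* `gen_deformation_series()` builds a constant-volume series: a saturating
  field ramp to aspect ratio 1.05 with a 1.5 s time constant, UV onset at
  7.2 s, then saturating area growth (default 4.6 %) normalised so the
  configured maximum is reached at the final frame. Frame noise perturbs
  the *apparent aspect ratio* and reconstructs the semiaxes at the true
  volume, so both semiaxes carry anti-correlated multiplicative errors
  while every frame's volume stays exactly constant — mirroring the optical
  observation that vesicle volume does not change during irradiation.
* `gen_contour()` samples ellipse or two-tangent-circle outlines with
  isotropic Gaussian point noise.
* `gen_elution_trace()` sums Gaussian peaks at 5.4/7.0/8.1 mL; free-peak
  width 0.25 mL keeps the membrane peak baseline-resolved (as in measured
  profiles) while the two free peaks still overlap. The incorporated
  amplitude is set from the designed area share (default 0.74 %).

The generators do **not** emulate: real micrograph segmentation (halo
artefacts, defocus), membrane fluctuation spectra, photoisomerisation
kinetics (the exponential time constants are phenomenological), bud
readsorption, or chromatographic peak asymmetry. Passing round-trip tests
therefore demonstrates correctness of the *analysis arithmetic* under
realistic noise magnitudes, not robustness to every imaging artefact of real
data.

## Numerical choices

* **Root finding**: verified-bracket bisection everywhere (limit-line
  inversion, bud-radius solving), tolerance $10^{-12}$; no derivative
  methods.
* **Inverse spheroid map** (`spheroid_from_area_volume`): bisection on the
  log aspect ratio followed by Newton polish; round-trips area and volume to
  better than $10^{-9}$ relative.
* **Degenerate inputs**: $a < b$ is rejected, not swapped (it signals a
  data-entry error); reduced volumes in $(1, 1+10^{-9}]$ are clipped to 1,
  larger values rejected; two-circle fits that collapse onto near-concentric
  circles raise a classed "no bud" condition instead of returning a bogus
  bud.
* **Ellipse fitting**: the numerically stabilised direct least-squares conic
  fit (block-decomposed scatter matrix, ellipse constraint $4AC - B^2 = 1$),
  exact on noise-free data; data are centred first for conditioning.
* **Two-circle fitting**: principal-axis split, per-lobe algebraic circle
  fit, iterated reassignment; single-circle alternative compared by BIC.

## Problem sizes

The test suite and the acceptance script run populations of 100 vesicles,
deformation series of ~200 frames, 30-series cohorts, and 100-point limit
lines — the sizes at which the corresponding experiments are reported, and
comfortably desk-scale (the whole suite runs in seconds).

## Known limitations

* Only the two-sphere limit shapes are computed; the full axisymmetric
  shape equations (and hence non-limit equilibrium shapes) are out of
  scope, as is estimating $\kappa$ or $\kappa'$ individually.
* The reduced volume attributed to a budded vesicle is computed from its
  post-budding two-sphere geometry; whether a pre-budding
  electrodeformation estimate would be preferable is data-dependent, and
  the package leaves the choice of input to the caller.
* The partitioning calibration assumes equal extinction for free and
  membrane-inserted switch; if insertion shifts the absorption spectrum,
  the incorporated share is systematically biased.
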