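# vesicurv

Curvature-elastic analysis of light-induced membrane area increase and
budding of giant unilamellar vesicles (GUVs).

When a water-soluble photoswitchable amphiphile partitions into a GUV
membrane and is photoisomerised, the membrane gains area and spontaneous
curvature, and the vesicle expels micron-scale buds. This package is for
membrane biophysicists who want to quantify that process from tabular
measurements:

* **Neck condition.** A budded vesicle idealised as two tangent spheres
  (mother radius $R_\alpha$, bud radius $R_\beta$) keeps its neck closed
  when the effective spontaneous curvature equals the mean sphere
  curvature,

  $$m + m_{nlo} = \tfrac12\!\left(\tfrac{1}{R_\alpha} +
  \tfrac{1}{R_\beta}\right),\qquad
  m_{nlo} = \pi\,\frac{\kappa'}{\kappa}\,
  \frac{\sqrt{R_\alpha^2+R_\beta^2}-R_\alpha-R_\beta}
       {R_\alpha^2+R_\beta^2}\le 0,$$

  where $m$ is the local spontaneous curvature, $m_{nlo}$ the nonlocal
  (area-difference-elasticity) contribution, and $\kappa'/\kappa$ the
  nonlocal-to-local bending-rigidity ratio. `neck_fit()` applies this to a
  population of measured radii and returns a classed model object with
  `print`/`summary`/`coef`/`predict`/`plot` methods; `plot()` draws the
  $(\nu, \bar m)$ morphology diagram with the theoretical limit-shape
  lines, where $\nu = 6\sqrt\pi V A^{-3/2}$ is the reduced volume and
  $\bar m = m\sqrt{A/4\pi}$ the dimensionless spontaneous curvature.
* **Electrodeformation.** `analyze_series()` extracts the relative area
  increase $\bar{\Delta A} = (A_{UV}-A)/A$ from time series of prolate
  semiaxes under an AC field, using exact spheroid geometry.
* **SEC partitioning.** `partition_analysis()` converts absorbance peak
  areas of an elution trace into the membrane-incorporated concentration,
  the incorporated fraction, and the lipid-per-switch ratio.
* **Synthetic data.** Seeded generators (`gen_budded_population()`,
  `gen_deformation_series()`, `gen_contour()`, `gen_elution_trace()`)
  produce every input with recorded ground truth, so the full pipeline is
  testable without raw microscopy or chromatography data.

## Worked example

Generate a 10-vesicle budded population with true curvature
0.4 µm⁻¹ = 1/(2.5 µm) and 2 % radius noise, then infer the curvature back
at two rigidity ratios:

```r
library(vesicurv)
pop <- gen_budded_population(n = 10, m_true = 0.4, kappa_ratio = 0,
                             radius_noise = 0.02, seed = 42)
fit <- neck_fit(pop$shapes, kappa_ratio = c(0, 1))
fit
#> Closed-neck curvature analysis
#>   10 vesicles, kappa'/kappa in {0, 1}
#>
#>   kappa'/kappa = 0     m = 0.4014 +/- 0.0078 1/um   ( m ~ 1/(2.5 +/- 0.048 um) )
#>   kappa'/kappa = 1     m = 0.4604 +/- 0.025 1/um    ( m ~ 1/(2.2 +/- 0.12 um) )
```

At the generating ratio ($\kappa'/\kappa = 0$) the population mean recovers
the true 1/(2.5 µm); analysing the same shapes at $\kappa'/\kappa = 1$
yields a larger local curvature, because the (negative) nonlocal term must
be compensated — the dispersion is the spread across vesicles, also given
as an uncertainty on the reciprocal length.

Area increase from a noise-free synthetic electrodeformation series with a
configured 4.6 % gain, and partitioning from a synthetic three-peak elution
trace carrying a 0.74 % incorporated share:

```r
analyze_series(gen_deformation_series(delta_A_max = 0.046, frame_noise = 0))
#> Area increase: 4.6% (A = 1257.16 -> 1314.98 um^2), baseline nu = 0.9994

trace <- gen_elution_trace()
partition_analysis(trace, incorporated_window = c(4.8, 6.0),
                   free_windows = list(c(6.0, 7.55), c(7.55, 9.3)),
                   c_total = 0.25e-3, c_lipid = 0.1e-3)
#> Incorporated: 1.85e-06 M (0.742% of total); one switch per 53.9 lipids
```

A config-driven pipeline (`run_simulate()`, `run_analyze_buds()`,
`run_deformation()`, `run_partitioning()`) writes CSV outputs plus
provenance logs; `scripts/vesicurv.R` is a thin command-line wrapper:

```sh
Rscript scripts/vesicurv.R simulate --seed 3 --out-dir out/
Rscript scripts/vesicurv.R partitioning --config cfg.yaml --out-dir out/
```

See the vignette `vignettes/vesicle-budding-analysis.Rmd` for the model,
assumptions, numerical choices and limitations.

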