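# barentsiso

Multi-decadal change at the base of the Barents Sea food web, traced with
nitrogen isotopes. `barentsiso` is a desk-scale R implementation of the
inference chain that links a 60-year record of phenylalanine δ15N
(δ15N_Phe) in harp seal teeth — a conserved proxy for the isotope baseline
of the ecosystem — to its environmental drivers: atmospheric reactive-
nitrogen deposition, growing Atlantic inflow, and rising local primary
production.

It is written for isotope ecologists and ocean biogeochemists who want the
whole chain runnable, testable and seedable on a laptop:

* **Seal record** — nearest-standard correction
  (δ_reported = mean(δ_sample) − (δ_std,measured − δ_std,known)),
  duplicate/triplicate QC at a 1.0 ‰ tolerance, growth-layer-group
  chronology (GLG2+GLG3 = second and third year of life), OLS trend of
  δ15N_Phe on year with residual diagnostics.
* **Telemetry** — bivariate normal kernel utilization distribution
  (bandwidth 250 km on an equal-area projection) and its 95% isopleth as a
  habitat mask.
* **Forcing** — historical deposition ramp: 11 Tg N yr⁻¹ preindustrial,
  piecewise linear through 1850/2000/2030 anchors with 60% of the
  1850–2000 increase after 1950; deposited N at δ15N = −4 ‰.
* **Box model** — Atlantic source box → Barents surface box with isotope
  mass-balance mixing and closed-system Rayleigh fractionation
  (δ_POM = δ_supply + ε·f·ln f/(1−f), ε = 5 ‰), run as a paired
  with/without-deposition attribution experiment.
* **Section diagnostics** — Atlantic Water masking (θ > 2 °C, S > 34.5 psu),
  volume transport in Sv, velocity-vs-volume trend decomposition, nitrate
  flux, masked and regional means, integrated NPP, per-cell decadal trend
  maps and attribution percentages.
* **Synthetic generators** — seeded inputs with recorded ground truth for
  every stage, so everything above is testable offline.

## Worked example

Generate a synthetic tooth record at the archived study's conditions
(72 seals, two-year windows spanning 1951–2012, baseline −0.36 ‰ decade⁻¹,
0.5 ‰ noise), build QC'd records, and fit the trend:

```r
library(barentsiso)
ds  <- gen_seal_dataset(seal_truth(seed = 1))
fit <- fit_trend(build_seal_records(ds$measurements))
fit
#> Linear trend of d15N_Phe on year
#>   slope: -0.392 permil/decade (se 0.042), intercept 88.20
#>   R2 = 56.0%, F = 89.1 on 1 and 70 df, p = 4.12e-14, n = 72
```

The fitted −0.392 ± 0.042 ‰ decade⁻¹ recovers the prescribed −0.36 within
one standard error for this seed; R², F and n describe the usual OLS
summary of the 72-record fit.

Run the paired deposition-attribution experiment (1851–2019, analysed over
1970–2019):

```r
d <- demo_experiment()
paired_experiment(d$params, d$forcing, d$scenario, d$years, d$trend_window)
#> Paired deposition attribution, 1970-2019
#>   delta_in   trend: -0.0776 (with) vs -0.0372 (without) per decade
#>   delta_pom  trend: -0.0356 (with) vs +0.0320 (without) per decade
#>   npp        trend: +2.3131 (with) vs +2.1666 (without) per decade
#>   cumulative nitrate delivered: +4.91% with deposition
#>   mean NPP: +2.47% with deposition
```

Read: the δ15N_NO3 of inflowing Atlantic Water declines in both runs
(endmember shift toward subtropical water) and roughly twice as fast when
anthropogenic deposition is included; the δ15N of new production *rises*
without deposition (increasing utilization enriches it) but *falls* with
deposition (isotopically light input wins); primary production rises in
both runs, and its attribution (+2.5%) stays below the nitrate attribution
(+4.9%) because uptake saturates.

An end-to-end demonstration with manifest and per-stage outputs:

```r
run_pipeline(pipeline_config(out_dir = "demo_run", seed = 1))
```

A thin command-line front-end over the same functions is installed at
`inst/cli/isoscape.R`
(`Rscript isoscape.R demo|seal-trend|ud|forcing|boxmodel|section ...`).

## Data note

The archived tooth measurement data are deposited at
`doi:10.5285/6AAA53E8-3D0A-48FE-838E-31C5B5F24CE7` (NERC EDS UK Polar Data
Centre) and `doi:10.5281/zenodo.6127524`. They are not bundled here; to run
the published-record checks, place the measurement table (in the schema of
`read_measurements()`) at `inst/extdata/deposited/measurements.csv`. All
other functionality uses the synthetic generators.

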