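# spectscatter

Scatter-correction evaluation for quantitative Tc-99m bone SPECT/CT, fully
in silico.

In Tc-99m imaging, 25–40% of the counts inside the ±10% photopeak window
at 140 keV are Compton scatter, and the choice of scatter correction —
dual-energy-window (DEW) subtraction, triple-energy-window (TEW)
trapezoid, or model-based effective-scatter-source estimation (ESSE) —
directly moves the reported activity concentration. `spectscatter`
rebuilds the classic phantom comparison of those corrections as a
reproducible pipeline for medical-physics work:

* **Digital phantoms** — a 20 cm cylinder (air / water / bone-equivalent
  K₂HPO₄ solution) with a central 74.0 MBq line source, and a 16 cm
  uniform cylinder with 222.0 MBq (`buildTLSP()`,
  `buildUniformCylinder()`).
* **Seeded Monte-Carlo acquisition** — Klein–Nishina Compton transport,
  Gaussian energy resolution (9.8% FWHM at 140 keV), parallel-beam LEHR
  acceptance, 60 views over 360°, with *all* energy windows recorded
  simultaneously and the ground-truth primary/scatter split kept per bin
  (`simulateProjections()`).
* **Corrections** — DEW (`Cprim = Ctotal − k·Cs`, k = 1; 5–20%
  sub-windows), TEW (`k_eff = W_prim/(2·W_sub)`: 3.3, 2.0, 1.4, 1.0 for
  3/5/7/10% sub-windows), and an ESSE-style kernel estimator fitted to the
  package's own Monte-Carlo point responses (`dewEstimate()`,
  `tewEstimate()`, `esseEstimate()`).
* **Reconstruction** — attenuated OSEM (2 iterations × 15 subsets by
  default) with matched projectors, optional additive scatter modeling and
  optional Gaussian resolution recovery (`osem()`).
* **Metrics** — scatter fraction `SF% = (T_med − T_air)/T_med × 100`,
  `NMSE%`, and uniformity `CV% = SD/mean × 100`, plus residual-scatter
  difference images (`scatterFraction()`, `nmse()`, `cv()`,
  `residualImage()`).

## Worked example

Simulate the line-source phantom over three backgrounds, apply four
corrections, reconstruct, and score against the air reference:

```r
library(spectscatter)

cfg <- experimentConfig(
  media       = c("air", "water", "k2hpo4"),
  corrections = c("none", "dew20", "tew10", "esse"),
  gridSize    = 65, voxelSize = 4.8,
  histories   = 1e6, seeds = 1:3,
  geometry    = acquisitionGeometry(detectorBins = 64))

res <- runMatrix(cfg)         # ~30 s on one CPU
res$sf_table[, 1:4]
```

```
   medium method sf_percent nmse_percent
1     air   none      0.000        0.000
...
5   water   none     28.839        0.317
6   water  dew20     -1.517        0.160
7   water  tew10     13.515        0.360
8   water   esse     -0.331        0.092
9  k2hpo4   none     36.595        0.501
10 k2hpo4  dew20     -4.533        1.146
11 k2hpo4  tew10     17.611        0.365
12 k2hpo4   esse     -4.187        0.760
```

Reading it: without correction ~29% (water) and ~37% (bone-equivalent) of
the reconstructed ROI counts are scatter (SF); the wide DEW 20% window
removes essentially all of it and slightly overshoots (negative SF), the
narrow TEW 10% trapezoid undercorrects, and the fitted ESSE matches water
almost exactly while overcorrecting in the denser bone-equivalent medium.
The uniform-cylinder arm (`res$cv_table`) shows the price of the wide DEW
window — the worst uniformity of all corrections:

```
  method cv_percent
1   none       14.0
2  dew20       30.7
3  tew10       19.4
4   esse       19.5
```

`reportResults(res, "out/")` writes the CSV tables, SF/NMSE/CV bar plots
and a residual-scatter panel against the DEW 20% reference. Because the
simulator keeps the true scatter per bin, any correction can also be
scored directly: `estimateScatter(wp, "truth")` reconstructs the
scatter-free ceiling.

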