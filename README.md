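# dissolvis

Quantifying tablet dissolution from time-resolved X-ray micro-CT.

`dissolvis` is for pharmaceutical scientists and imaging groups who run
in-situ dissolution experiments: a sustained-release tablet sits in a
flow-through cell perfused with contrast-agent (CsCl) brine inside a
micro-CT scanner, a high-quality dry scan captures the static structure,
fast scans during dissolution capture the advancing wetting front, and UV
spectrophotometry of sampled medium quantifies drug release. The package
turns those raw pieces into porosity, a water-penetration profile, a
quantified release profile, and their comparison — and ships a synthetic
4D tablet phantom with exact ground truth on which the whole chain is
validated.

## What it computes

* **Porosity** by voxel counting after bilateral filtering, threshold +
  largest-component segmentation, and hole filling:
  `phi = V_pore / V_tablet`.
* **Wet/dry discrimination** per timestep inside the tablet-matrix VOI,
  two ways:
  * a global threshold at the intersection of the two Gaussians
    `w_i * N(mu_i, sigma_i)` fitted to the first (dry) and last (wet)
    histograms, and
  * a k-nearest-neighbour classifier (k = 10, Euclidean metric on
    z-scored features) on per-voxel `(x, y, z, gray, EDT)` — EDT being
    the exact Euclidean distance to the nearest background voxel —
    trained on the first/last timesteps labelled all-dry/all-wet.
* **Penetration profile**: wetted fraction of the VOI versus time.
* **Release quantification**: linear UV calibration
  `A = a * C + b`, withdrawal-corrected cumulative release for
  sequential 5 mL samples from 900 mL (closed loop), and the similarity
  factor `f2 = 50 log10( 100 / sqrt(1 + mean((R_t - T_t)^2)) )`.
* **Phantom**: Beer–Lambert attenuation (`I_out = I_in e^(-mu T)`),
  a porous cylinder with countable spherical pores, a shrinking-core
  wetting front `r(t) = R - v t`, scan noise, and the low-frequency
  shading artifacts of a brine-filled cell.

See `vignettes/dissolvis-methods.Rmd` for the models, parameter
rationale, and limitations.

## Worked example

A complete synthetic experiment — 64³ phantom, six scans over 7.5 h,
matched release data — through the full pipeline:

```r
library(dissolvis)
cfg <- demo_config("run1", grid = 64, seed = 1)
rep <- run_pipeline(cfg)

cat(sprintf("porosity: %.4f\n", rep$porosity))
cat(sprintf("wet/dry threshold (gray): %.4f\n", rep$wet_threshold))
cat(sprintf("KNN validation error: %.4f\n", rep$knn$validation_error))
cat(sprintf("max |KNN - truth| wet fraction: %.4f\n", rep$max_abs_knn_error))
cat(sprintf("max |threshold - truth| wet fraction: %.4f\n", rep$max_abs_threshold_error))
cat(sprintf("f2, recovered vs generating release profile: %.1f\n", rep$f2_release_recovery))
```

```
porosity: 0.2326
wet/dry threshold (gray): 0.4635
KNN validation error: 0.0075
max |KNN - truth| wet fraction: 0.0041
max |threshold - truth| wet fraction: 0.0649
f2, recovered vs generating release profile: 99.9
```

The phantom was built with 23.24% target porosity and the dry-scan
analysis recovers 23.26%. The Gaussian-intersection threshold lands
between the dry-matrix (0.38) and wetted-matrix (0.54) gray levels. The
KNN penetration profile tracks the analytic ground truth to within 0.004
at every timestep, while the global threshold — misled by the smooth
shading artifact the phantom adds to the brine-immersed scans — is off by
up to 0.065, classifying 4% of a completely dry tablet as wet:

```
  time_h   knn threshold truth
1    0.0 0.004     0.040 0.000
2    1.0 0.190     0.190 0.187
3    2.0 0.427     0.398 0.426
4    3.0 0.633     0.584 0.635
5    4.5 0.851     0.795 0.854
6    7.5 0.996     0.935 1.000
```

An f2 of 99.9 between the quantified and the generating release profile
says the calibration/withdrawal-correction chain is essentially lossless
at the default 0.002 AU absorbance noise (f2 = 100 means identical;
>= 50 is the conventional similarity bound). All tabular outputs, the
JSON report, and (optionally) the classified masks land in the run
directory; rerunning the same configuration reproduces them byte for
byte.

The same steps are scriptable from a shell:

```sh
Rscript inst/cli/dissolvis.R phantom --out demo --grid 96 --seed 1
Rscript inst/cli/dissolvis.R f2 ref.csv test.csv
```

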