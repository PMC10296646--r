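# mifcal

Cross-microscope calibration of multispectral, multiplex
immunofluorescence (mIF) whole-slide images.

## The problem

High-throughput mIF studies scan slides on several multispectral
microscopes. Instruments of the same model differ in illumination
intensity and — above all — in the transmission of their static broadband
filter cubes, so the same tissue produces systematically different flux
spectra on different scanners. Left uncorrected, these differences
contaminate every downstream marker-expression measurement. `mifcal` is
for imaging scientists and image-analysis engineers who need to quantify
these differences, correct them, and standardize all raw images to one
reference microscope before spectral unmixing.

## The model

Tiled image stacks ("high-power fields", H x W x K unsigned 16-bit
counts) are masked (Otsu background + per-layer saturation thresholds),
exposure-normalized to flux, and reduced per scan to average tissue-flux
spectra `X_mrkn` (sample *n*, microscope *m*, scan repeat *r*, layer *k*),
normalized to unit grand mean. A sequential multiplicative model is then
fitted and applied, one correction at a time:

    x = X / (B_n * C_m)        sample and microscope amplitudes
    y = x / b_nk               per-sample spectral profiles
    z = y / w_mk               per-microscope spectral profiles

with each profile normalized to mean 1 across its dimension at every
layer. The microscope profile decomposes exactly as
`w_mk = w_m_ill * w_mk_BB * w_mk_NB` (illumination, broadband-cube, and
narrowband-filter parts). Generalization of the microscope factors is
measured by an exhaustive subset bootstrap: tissue effects are homogenized
(`psi = X / (B_n * beta_nk)`), microscope factors are refitted on each of
the C(8,5) = 56 five-sample subsets and applied to the held-out samples.
Bootstrap-mean factors, divided by the reference microscope's row, become
per-layer standardization factors; standardized stacks are then unmixed by
per-pixel non-negative least squares against a pure-spectra library — a
transparent linear surrogate for proprietary vendor unmixing.

Real multi-microscope scan sets are not redistributable, so the package
ships a first-class synthetic-data generator with planted ground-truth
factors; every stage of the pipeline is validated against it.

## Worked example

```r
library(mifcal)
cfg <- simulation_config()           # 8 samples x 3 microscopes x 2 scans
ds  <- simulate_dataset(cfg, seed = 7)
run <- run_full_calibration(ds, ref_m = 2)
print(run)
#> mif_run 5588bb3a
#> layer-averaged residual std by stage:
#>   X       30.54 %
#>   x       12.11 %
#>   y        7.36 %
#>   z        0.39 %
#>   psi      7.17 %
#>   z_fit    1.89 %
#>   z_test   1.92 %
```

Reading the numbers: the raw spectra vary by 30.5% across samples,
microscopes and scans; amplitude corrections cut that to 12.1%, tissue
spectral profiles to 7.4%, and microscope spectral profiles to 0.39% —
the simulation's noise floor. In the bootstrap, tissue-homogenized spectra
(`psi`, 7.17%) drop to 1.89% when microscope factors are applied back to
the five fit samples and 1.92% on the three held-out samples: factors
fitted on one set of samples transfer to tissue they never saw.

The fitted illumination scales confirm that instrument differences are
spectral shape rather than brightness:

```r
round(run$fit$decomposition$wmill, 4)
#> [1] 0.9950 1.0053 0.9997
```

and the standardization factors for the first layers (microscope 2 is the
reference, so its row is exactly 1):

```r
round(run$std_factors$factors[, 1:4], 3)
#>       [,1]  [,2]  [,3]  [,4]
#> [1,] 0.933 0.951 0.964 0.945
#> [2,] 1.000 1.000 1.000 1.000
#> [3,] 0.977 0.993 0.959 0.927
```

`export_run(run, "out/", ds)` writes every factor table, per-stage std
report, bootstrap summary and the standardization factors as CSV. A thin
command-line wrapper ships in `inst/cli/mifcal.R`
(`simulate` / `run-all` subcommands) for shell use on on-disk datasets
(multi-page TIFF tiles plus a YAML manifest; see
`read_dataset_manifest()`).

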