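---
title: "Cross-microscope calibration of multispectral mIF images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-microscope calibration of multispectral mIF images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifcal)
```

## The problem

Multiplex immunofluorescence (mIF) whole-slide scanners capture each tissue
field as a stack of K narrowband image layers (43 on the instruments this
package targets), acquired behind a handful of static broadband filter
cubes. Two scanners of the same model do not return the same numbers for
the same slide: their LED arrays age differently, and above all their
broadband filter cubes are manufactured with different transmission curves.
When a study scans its slides on several microscopes, these instrument
effects masquerade as biology.

`mifcal` implements a sequential multiplicative calibration that separates
and removes these effects, quantifies what remains, validates that the
microscope-specific part generalizes to samples not used in the fit, and
standardizes raw images to one reference microscope before spectral
unmixing.

## From tiles to spectra

The unit of acquisition is the high-power field (HPF): an H x W x K stack
of unsigned 16-bit counts. For each scan the pipeline:

1. **Masks** each HPF with a binary tissue mask: background pixels fall
   below an Otsu threshold computed on the per-pixel mean of the
   exposure-normalized layers; oversaturated pixels exceed a per-layer
   count threshold in any layer. One 2-D mask applies to all layers.
2. **Exposure-normalizes** counts to flux (counts/ms), dividing each layer
   by the exposure time of its broadband group (the scanner auto-exposes
   per broadband cube, so exposure is a per-group quantity broadcast to
   member layers).
3. **Accumulates the mean image**: the per-pixel masked average flux over
   the scan's HPFs, with zero where no tile contributed.
4. **Averages over pixels** to one value per layer. The divisor is the
   full pixel count H x W, a deliberate convention of the statistic;
   zero-coverage pixels contribute zero, and a warning fires when more
   than half the pixels are uncovered.
5. **Weights** each scan's spectrum by its share of the dataset's tiles,
   and **normalizes** the whole tensor by its grand mean, yielding the
   stage-X spectra: relative tissue flux about 1, indexed by sample n,
   microscope m, scan repeat r and layer k.

All layer indices in this package are 1-based, following the R
convention; the manifest's layer order defines k.

## The sequential correction model

The model treats the stage-X spectra as a product of sample and microscope
effects, each split into a wavelength-independent amplitude and a
per-layer profile:

- **Amplitudes**: per-scan amplitudes `a_mrn` (layer means over the grand
  mean) are averaged into sample factors `B_n` (over microscopes and
  scans) and microscope factors `C_m` (over samples and scans);
  `x = X / (B_n C_m)`.
- **Tissue profiles**: the per-sample layer profile `T_nk` (mean of x over
  m, r), normalized per layer to sample-mean 1, gives `b_nk`;
  `y = x / b_nk`.
- **Microscope profiles**: the per-microscope layer profile `P_mk` (mean
  of y over n, r), normalized per layer to microscope-mean 1, gives
  `w_mk`; `z = y / w_mk`.

Each correction is fitted once on the output of the previous one and
applied once — no joint refit or iteration.
Fits require a complete N x M x R grid; missing cells
are an error, never silently reweighted. Residual variation is summarized
by the per-layer sample standard deviation (divisor NMR - 1) of the NMR
values at each layer, averaged over layers; on the unit-mean spectra this
is a fraction, reported as a percent.

The split between `B_n` and `C_m` carries a gauge freedom: only the
product enters the correction. More generally the model is identified only
up to the normalization conventions of the estimators themselves, which is
why simulation ground truth must be *gauge-fixed* before comparison (see
below).

The microscope profile decomposes exactly as
`w_mk = w_m^ill * w_mk^BB * w_mk^NB`: the layer-mean illumination scale,
the within-broadband-group mean of the rest (constant across each group's
layers), and the narrowband residual. On real instruments the broadband
part dominates — group-level offsets can reach 20% — which is also visible
as block structure in the layer-projected covariance matrix
`Sigma(X) = mean over (n,m,r) of outer(d, d)` with deviations `d` taken
about each microscope's own per-layer mean (population divisor NMR).
The per-layer standard deviation uses the sample divisor
NMR - 1; the two conventions differ negligibly at NMR = 48 and the choice
is recorded in each report object.

## Bootstrap generalization

To ask whether the microscope factors transfer to new tissue, the spectra
are first *homogenized* for tissue effects on the full dataset:
`chi = X / B_n`, then per-sample spectral factors `beta_nk` (the analogue
of `b_nk` computed from chi) are divided out to give `psi`, in which
remaining variation is attributable to the microscopes. Each bootstrap
iteration fits microscope amplitude and profile factors (`C_m^s`,
`omega_mk^s`) on a subset of N' = 5 of the 8 samples and applies them to
everyone via `z = psi / (C_m^s omega_mk^s)`; residual layer stds are
reported separately for the fit and the held-out test samples. All
C(8,5) = 56 subsets are enumerated in lexicographic order by default,
making the whole procedure deterministic; a seeded random mode exists for
designs too large to enumerate.

One property of these estimators matters for interpretation: `psi`
retains the microscope amplitude (only sample terms were divided out), so
`omega_mk^s` carries it in its layer mean, while `C_m^s` — computed from
the raw per-scan amplitudes — carries it again. The procedure therefore
divide a microscope amplitude out *twice*, which is harmless precisely
when microscope amplitudes are near 1. That is the regime the method was
designed for: per-broadband-filter auto-exposure equalizes overall
brightness between instruments, and the observed illumination scales
`w_m^ill` are approximately 1, with instrument differences living in the
broadband *shape*. The synthetic-data generator follows the same physics
(below), and the package reports both `w_m^ill` and `C_m` so a user can
verify the assumption on real data.

For standardization to a reference microscope the bootstrap factors are
aggregated as the product of the iteration means of `C_m^s` and of
`omega_mk^s` ("product of means"); the mean of per-iteration products is
also computed and exposed, and the two differ only at second order in the
iteration spread. Factors are divided by the reference microscope's row so
its data pass through bit-unchanged; being per-layer scalars, they commute
with exposure normalization and can be applied to counts or flux alike.

## Unmixing and the three-scenario comparison

Vendor unmixing software is proprietary; `mifcal` uses the standard
transparent surrogate, per-pixel non-negative least squares against a
K x K' library of pure component spectra (markers plus one
autofluorescence column). The solver is a block-principal-pivoting NNLS
vectorized over pixels sharing one library matrix, with columns grouped by
passive set so each sweep does one small Cholesky solve per distinct
pattern; a rank-deficient library triggers a warning and a vanishing-ridge
solve, numerically the minimum-norm optimum. Unmixing operates on flux
(exposure-normalized) input. Because the surrogate is not the vendor
algorithm, all unmixing comparisons are about the *ordering* of scenarios,
never absolute agreement with vendor output.

The comparison harness reduces unmixed stacks through the same masking, mean-image and
analogue pipeline at K' layers, removes sample effects (`B_n'`,
`beta_nk'`), and reports the residual layer std with the autofluorescence
layer excluded from the average, for three scenarios: (A) raw flux
unmixed with the reference microscope's library, (B) raw flux unmixed with
each microscope's own library, (C) flux standardized to the reference and
unmixed with the reference library.

Two subtleties determine how B and C compare on simulated data. First,
scenario-B libraries are built by projecting the reference library through
each microscope's *planted* response (`diag(C_m w_mk) x library`); exact
projection makes B optimal by construction, something physically measured
libraries never achieve, so the harness optionally adds a small
measurement-noise CV to the per-microscope libraries
(`microscope_library(noise_cv = )`). Second, the standardization factor
inherits a genuine limitation of the estimators: the amplitude factor
`C_m` absorbs the spectral coupling `mean_k(tbar_k w_mk)` between the mean
tissue spectrum and the microscope profile, which is not part of the
physical per-layer response; the profile part `omega_mk` is recovered
essentially exactly (ratio errors ~0.1% in our simulations), but the
amplitude carries a percent-scale bias whenever tissue spectra and
microscope profiles correlate. Scenario C therefore sits above the pure
noise floor — consistent with the original study, where the
corrected-then-unmixed residual also exceeded its bootstrap fit floor —
and with exactly projected, noise-free libraries scenario B can undercut
scenario C. With realistic library measurement error the familiar
C < B < A ordering re-emerges. The package asserts C < A and B < A as
hard guarantees; C vs B depends on library fidelity, as it does in
practice.

## The synthetic-data generator

Real multi-microscope scan sets are not redistributable, so the generator
is first-class, tested code. It emulates, per pixel:

```
counts = clip16( exposure_g * (background + tissue(i,j) *
                 A_n g_m t_nk w_mk * scene(i,j)) * jitter_mr * noise )
```

- **Design**: N = 8 samples x M = 3 microscopes x R = 2 scan repeats,
  K = 12 layers in 3 broadband groups, 64 x 64-pixel tiles, 4 tiles per
  scan — the full-size geometry (1872 x 1404, 43 layers, 7 groups) scaled
  to desk size while keeping every structural element. These are also the
  problem sizes used by the test suite and the acceptance script
  (32 x 32 tiles for the unmixing comparison).
- **Sample structure**: amplitudes `A_n` log-normal (sdlog 0.25 — sample
  brightness is the dominant raw variation); smooth per-sample spectral
  profiles `t_nk` (sdlog 0.10); a fixed tissue footprint of exactly
  round(0.6 H W) pixels shared by all tiles and scans of a sample (it is
  the same physical slide being re-scanned), and per-tile log-normal scene
  texture (sdlog 0.2), normalized to mean 1 over the footprint. The
  moderate texture spread keeps the tissue flux distribution clearly
  separated from background, which is the assumption Otsu masking rests
  on; much wider textures would push the low tissue tail into the
  background mode and the mask would clip tissue at a sample-dependent
  quantile.
- **Microscope structure**: broadband group offsets drawn uniformly within
  +/-20%, times a 2% smooth narrowband ripple, then normalized to unit
  layer mean per microscope — broadband differences are spectral shape;
  overall illumination stays near 1 because auto-exposure equalizes
  brightness, and residual microscope amplitudes `g_m` are log-normal with
  sdlog 0.02. Exposure times are drawn per (scan, broadband group) in
  5-15 ms and divide out exactly.
- **Noise**: 1% per-pixel multiplicative Gaussian noise; 0.5% per-scan
  amplitude jitter (re-scan repeatability); 16-bit quantization
  (switchable off for exact-model checks); a configured fraction (0.2%)
  of pixels planted at 65535 in one random layer to exercise the
  saturation rule.
- **Component mode**: for unmixing studies, tissue spectra arise from a
  random K x K' reference library (Gaussian emission bumps plus a flat
  autofluorescence column) and per-sample component compositions, with
  smooth per-tile abundance maps.

The generator does **not** model: optical point-spread functions,
bleed-through chemistry, per-pixel Poisson statistics, spatial flat-field
gradients within a tile, tile overlap and stitching, staining-batch
effects, or realistic fluorophore emission curves. Passing tests therefore
demonstrate the pipeline's correctness under the multiplicative model and
its stated noise sources, not robustness to every artefact of real
slides.

## Gauge fixing and recovery uncertainties

The sequential estimators identify factors only up to their own
normalizations, and the layer means couple `t_nk` and `w_mk` (through
`mean_k(t_nk w_mk)`), so no closed-form per-factor rescaling maps planted
truth onto the estimator's gauge. `gauge_fix_truth()` therefore defines
the reference operationally: the exact noise-free spectra tensor implied
by the planted factors is pushed through the very same fit chain, and
those factors are the comparison target. The product is preserved up to a
single global scalar; fits on noiseless simulated data reproduce the
gauge-fixed truth to floating-point precision.

For noisy data, `recovery_errors()` supplies pooled standard errors from
the fitted-model residual tensor `rho = X / (B_n C_m b_nk w_mk)`:
the pooled sd of the per-scan layer means of rho, divided by sqrt(MR) for
`B_n` and sqrt(NR) for `C_m`, and the pooled layer-level sd of rho divided
by the same roots for `b_nk` and `w_mk`. The pooled variances use the
residual degrees of freedom (NMR - N - M + 1 per layer) since N + M - 1
free amplitude parameters were fitted. At the default study conditions
the fitted factors land within 3 such standard errors of the gauge-fixed
truth.

A related identifiability note: the expected residual floor after all
corrections is `sqrt(jitter^2 + cv^2 / n_pixels)` per spectrum
(`expected_noise_floor()`), and the stage-z std on simulated data sits at
this floor — scan-to-scan jitter, not pixel noise, dominates once a few
thousand tissue pixels are averaged.

## Numerical choices

- Mean-image accumulation keeps double-precision running sums (16-bit
  counts overflow quickly) in a single streaming pass, bounded memory in
  the number of tiles.
- The Otsu threshold is computed on an equal-width histogram (65536 bins
  by default) by exhaustive between-class variance maximization; ties take
  the first maximizing cut; a constant projection skips Otsu with a
  warning and keeps every pixel (minus saturation). For 16-bit integer
  input with a full-range histogram this is exactly the classical discrete
  Otsu cut, and the tests verify equivalence with a brute-force
  intra-class-variance minimizer over all 65536 cut points.
- Factors are persisted at full double precision; manifests write floats
  with 15 significant digits so disk round-trips are lossless at double
  precision for all practical purposes.
- The r-tiff float writer clips to [0, 1], so real-valued corrected stacks
  are stored as float pages divided by a per-file scale recorded in a YAML
  sidecar.
- NNLS feasibility tolerance is 1e-10; columns that exhaust the block
  pivoting sweep budget (rare, degenerate inputs) fall back to a
  per-column Lawson-Hanson solve.
- 16-bit re-quantization of standardized stacks is opt-in
  (round-half-even, clipped, clipped-pixel count attached); the default
  output is real-valued to avoid quantization loss.

## Known limitations

- The shipped 7-group/43-layer default filter layout partitions layers
  into contiguous near-equal blocks; it is a placeholder for the
  instrument's true layer-to-cube mapping, which users should supply via
  `filter_layout()`.
- Otsu is applied per HPF; a global per-scan threshold is a plausible
  alternative the package does not implement.
- The amplitude factor `C_m` absorbs tissue-microscope spectral coupling
  (see above); standardization inherits a percent-scale amplitude bias
  when that coupling is strong.
- Cross-institution transfer, staining-batch standardization and
  wavelength-continuous profile models are out of scope.
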