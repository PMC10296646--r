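#' Stage-tagged spectra tensor
#'
#' The central container of the calibration pipeline: average relative
#' tissue flux indexed by sample `n`, microscope `m`, scan repeat `r` and
#' layer `k`, held as an N x M x R x K numeric array with a `stage`
#' attribute recording where in the correction sequence the values sit
#' (`"Xbar"`, `"Xtilde"`, `"X"`, `"x"`, `"y"`, `"z"`, `"chi"`, `"psi"`, ...).
#'
#' @param values Numeric N x M x R x K array.
#' @param stage Stage tag string.
#' @return A `spectra_tensor`.
#' @export
spectra_tensor <- function(values, stage) {
  if (length(dim(values)) != 4L) stopf("spectra tensor must be 4-dimensional (n, m, r, k)")
  if (any(!is.finite(values))) stopf("spectra tensor must be finite")
  structure(values, class = c("spectra_tensor", "array"), stage = stage)
}

#' @export
print.spectra_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("spectra_tensor [stage %s]: N=%d samples, M=%d microscopes, R=%d scans, K=%d layers\n",
              attr(x, "stage") %||% "?", d[1], d[2], d[3], d[4]))
  cat(sprintf("  grand mean %.6f, range [%.4f, %.4f]\n",
              mean(x), min(x), max(x)))
  invisible(x)
}

st_stage <- function(x) attr(x, "stage")

.rewrap <- function(values, stage) spectra_tensor(unclass(values), stage)

#' Accumulate the mean image of one scan
#'
#' Streams over the scan's masked flux tiles, accumulating the per-pixel
#' masked sum and coverage in double precision, and returns the mean image
#' `M(i,j,k)`: the masked average flux at each pixel (counts/ms), with 0
#' where no tile contributed (zero coverage). Memory is bounded in the
#' number of tiles.
#'
#' @param flux_stacks List of H x W x K flux arrays (one per HPF).
#' @param masks Matching list of `tissue_mask` objects or H x W 0/1
#'   matrices.
#' @return A list of class `mean_image`: `values` (H x W x K), `coverage`
#'   (H x W integer counts of contributing tiles).
#' @export
accumulate_mean_image <- function(flux_stacks, masks) {
  if (length(flux_stacks) == 0L) stopf("empty flux stream")
  if (length(flux_stacks) != length(masks)) stopf("one mask per flux stack required")
  d <- dim(flux_stacks[[1]])
  num <- array(0, dim = d)
  cov <- matrix(0, d[1], d[2])
  for (h in seq_along(flux_stacks)) {
    f <- flux_stacks[[h]]
    if (!identical(dim(f), d)) stopf("flux stack %d has mismatched shape", h)
    b <- masks[[h]]
    if (inherits(b, "tissue_mask")) b <- b$mask
    if (!identical(dim(b), d[1:2])) stopf("mask %d has mismatched shape", h)
    b <- as.numeric(b)
    num <- num + f * c(b)   # mask recycles over the layer dimension
    cov <- cov + b
  }
  vals <- num / c(pmax(cov, 1))
  zero <- cov == 0
  if (any(zero)) {
    vals[array(zero, dim = d)] <- 0
    if (mean(zero) > 0.5) {
      warnf("mean image: %.0f%% of pixels have zero coverage", 100 * mean(zero))
    }
  }
  structure(list(values = vals, coverage = cov), class = "mean_image")
}

#' Layer means of a mean image
#'
#' Averages the mean image over the two pixel dimensions to one value per
#' layer. The divisor is the full pixel count H*W, including zero-coverage
#' pixels (which contribute 0), matching the definition of the raw average
#' tissue-flux spectrum.
#'
#' @param mean_image A `mean_image`.
#' @return Numeric vector of length K.
#' @export
layer_mean_spectrum <- function(mean_image) {
  v <- mean_image$values
  colMeans(matrix(v, nrow = prod(dim(v)[1:2]), ncol = dim(v)[3]))
}

#' Weight spectra by each scan's share of tiles
#'
#' Multiplies every raw spectrum by the fraction of the dataset's tiles
#' that came from its own scan, `h_mrn / sum(h_mrn)`, so scans covering
#' more tissue carry proportionally more weight in the subsequent global
#' normalization.
#'
#' @param xbar `spectra_tensor` at stage `"Xbar"`.
#' @param hmrn N x M x R array (or conformable vector) of per-scan HPF
#'   counts.
#' @return `spectra_tensor` at stage `"Xtilde"`.
#' @export
hpf_fraction_weight <- function(xbar, hmrn) {
  total <- sum(hmrn)
  if (total <= 0) stopf("all HPF counts are zero")
  w <- as.numeric(hmrn) / total
  .rewrap(unclass(xbar) * c(w), "Xtilde")  # weight recycles over k
}

#' Normalize spectra to unit grand mean
#'
#' Divides the tensor by its grand mean over all samples, microscopes,
#' scans and layers, producing relative tissue-flux variations about one.
#'
#' @param xtilde `spectra_tensor` (stage `"Xtilde"`).
#' @return `spectra_tensor` at stage `"X"` with grand mean 1.
#' @export
grand_normalize <- function(xtilde) {
  g <- mean(xtilde)
  if (!(g > 0)) stopf("grand mean must be positive")
  .rewrap(unclass(xtilde) / g, "X")
}

#' Per-scan amplitude summary
#'
#' Collapses the layer dimension to one wavelength-independent relative
#' amplitude per (sample, microscope, scan): the per-scan mean over layers
#' divided by the grand mean over everything. On stage-X input the
#' amplitudes average to exactly 1.
#'
#' @param x_spectra A `spectra_tensor`.
#' @return N x M x R numeric array of class `amplitude_table`.
#' @export
amplitude_summary <- function(x_spectra) {
  v <- unclass(x_spectra)
  a <- apply(v, c(1, 2, 3), mean) / mean(v)
  structure(a, class = c("amplitude_table", "array"))
}

#' Reduce a dataset to raw average tissue-flux spectra
#'
#' Runs masking, exposure normalization, mean-image accumulation and layer
#' averaging for every scan of a dataset, assembling the raw `Xbar`
#' spectra tensor, the per-scan tile counts, and a masking QC table.
#'
#' @param dataset A `mif_dataset` (in-memory or manifest-backed).
#' @param thresholds Optional per-layer saturation thresholds.
#' @param otsu_source Projection spec for the background mask
#'   (see [compute_tissue_mask()]).
#' @param masks `"otsu"` (default) to compute tissue masks, or `"none"` to
#'   keep every pixel.
#' @return List with `xbar` (`spectra_tensor`, stage `"Xbar"`), `hmrn`
#'   (N x M x R tile counts), and `qc` (data.frame per scan).
#' @export
dataset_spectra <- function(dataset, thresholds = NULL, otsu_source = "mean",
                            masks = c("otsu", "none")) {
  masks <- match.arg(masks)
  N <- length(dataset$samples)
  M <- length(dataset$microscopes)
  R <- dataset$n_scan_reps
  K <- dataset$layout$K
  if (length(dataset$scans) != N * M * R) {
    have <- vapply(dataset$scans, function(s) sprintf("%d|%d|%d", s$n, s$m, s$r), "")
    grid <- expand.grid(n = seq_len(N), m = seq_len(M), r = seq_len(R))
    want <- sprintf("%d|%d|%d", grid$n, grid$m, grid$r)
    miss <- setdiff(want, have)
    stopf("incomplete scan grid: missing (n,m,r) = (%s)",
          gsub("\\|", ",", miss[1]))
  }
  xbar <- array(NA_real_, dim = c(N, M, R, K))
  hmrn <- array(0, dim = c(N, M, R))
  qc <- list()
  for (scan in dataset$scans) {
    flux_list <- vector("list", scan$n_hpf)
    mask_list <- vector("list", scan$n_hpf)
    for (h in seq_len(scan$n_hpf)) {
      px <- .get_hpf(scan, h)
      flux_list[[h]] <- exposure_normalize(px, scan$exposures, dataset$layout)
      mask_list[[h]] <- if (masks == "otsu") {
        compute_tissue_mask(px, scan$exposures, dataset$layout,
                            thresholds = thresholds, otsu_source = otsu_source)
      } else {
        matrix(1L, dataset$H, dataset$W)
      }
    }
    mi <- accumulate_mean_image(flux_list, mask_list)
    xbar[scan$n, scan$m, scan$r, ] <- layer_mean_spectrum(mi)
    hmrn[scan$n, scan$m, scan$r] <- scan$n_hpf
    if (masks == "otsu") {
      row <- cbind(data.frame(sample_id = scan$sample_id,
                              microscope_id = scan$microscope_id,
                              scan = scan$r),
                   mask_summary(mask_list))
      qc[[length(qc) + 1L]] <- row
    }
  }
  list(xbar = spectra_tensor(xbar, "Xbar"), hmrn = hmrn,
       qc = if (length(qc)) do.call(rbind, qc) else NULL)
}

#' Dataset to normalized stage-X spectra
#'
#' Convenience wrapper: [dataset_spectra()] followed by
#' [hpf_fraction_weight()] and [grand_normalize()], plus the per-scan
#' amplitude table.
#'
#' @inheritParams dataset_spectra
#' @return List with `X` (stage-X `spectra_tensor`), `amps`
#'   (`amplitude_table`), `hmrn`, and `qc`.
#' @export
normalized_spectra <- function(dataset, thresholds = NULL,
                               otsu_source = "mean",
                               masks = c("otsu", "none")) {
  red <- dataset_spectra(dataset, thresholds, otsu_source, masks)
  X <- grand_normalize(hpf_fraction_weight(red$xbar, red$hmrn))
  list(X = X, amps = amplitude_summary(X), hmrn = red$hmrn, qc = red$qc)
}
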