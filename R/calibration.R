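#' Fit sample and microscope amplitude correction factors
#'
#' The overall-brightness corrections of the sequential calibration model:
#' `B_n` is the mean amplitude of sample `n` over all microscopes and
#' scans, `C_m` the mean amplitude of microscope `m` over all samples and
#' scans. Fit from a stage-X amplitude table both have mean 1.
#'
#' @param amps An `amplitude_table` (N x M x R array, see
#'   [amplitude_summary()]).
#' @return A list of class `amplitude_factors`: `Bn` (length N), `Cm`
#'   (length M).
#' @export
fit_amplitude_factors <- function(amps) {
  a <- unclass(amps)
  if (length(dim(a)) != 3L) stopf("amplitude table must be an N x M x R array")
  if (any(!is.finite(a))) {
    idx <- which(!is.finite(a), arr.ind = TRUE)[1, ]
    stopf("missing amplitude at (n=%d, m=%d, r=%d)", idx[1], idx[2], idx[3])
  }
  structure(list(Bn = apply(a, 1, mean), Cm = apply(a, 2, mean)),
            class = "amplitude_factors")
}

.check_positive <- function(f, what) {
  if (any(!is.finite(f)) || any(f <= 0)) stopf("%s must be positive", what)
  f
}

#' Apply amplitude corrections
#'
#' Divides each spectrum by the product of its sample and microscope
#' amplitude factors, `x = X / (B_n * C_m)`. Only the product matters: the
#' split between `B_n` and `C_m` carries a gauge freedom.
#'
#' @param x_spectra Stage-X `spectra_tensor`.
#' @param factors An `amplitude_factors` object.
#' @return `spectra_tensor` at stage `"x"`.
#' @export
apply_amplitude <- function(x_spectra, factors) {
  Bn <- .check_positive(factors$Bn, "Bn")
  Cm <- .check_positive(factors$Cm, "Cm")
  d <- dim(x_spectra)
  denom <- outer(Bn, Cm)              # N x M
  v <- unclass(x_spectra)
  v <- v / c(denom)                   # recycles over (r, k)
  .rewrap(v, "x")
}

#' Fit the tissue spectral profile
#'
#' The per-sample relative spectral variation `T_nk` is the mean of the
#' amplitude-corrected spectra over microscopes and scans; dividing by the
#' per-layer mean over everything gives the correction factors `b_nk`,
#' which average to 1 over samples at every layer.
#'
#' @param x Stage-x `spectra_tensor`.
#' @return A list of class `tissue_profile`: `Tnk`, `bnk` (both N x K).
#' @export
fit_tissue_profile <- function(x) {
  v <- unclass(x)
  Tnk <- apply(v, c(1, 4), mean)
  layer_mean <- apply(v, 4, mean)
  if (any(layer_mean == 0)) stopf("zero per-layer mean; cannot form bnk")
  bnk <- sweep(Tnk, 2, layer_mean, "/")
  structure(list(Tnk = Tnk, bnk = bnk), class = "tissue_profile")
}

#' Apply the tissue profile correction
#'
#' `y = x / b_nk`, elementwise over (n, m, r, k).
#'
#' @param x Stage-x `spectra_tensor`.
#' @param profile A `tissue_profile`.
#' @return `spectra_tensor` at stage `"y"`.
#' @export
apply_tissue_profile <- function(x, profile) {
  bnk <- .check_positive(profile$bnk, "bnk")
  d <- dim(x)
  v <- unclass(x)
  # expand N x K over (m, r): permute to (n, k, m, r), divide, permute back
  vp <- aperm(v, c(1, 4, 2, 3))
  vp <- vp / c(bnk)
  .rewrap(aperm(vp, c(1, 3, 4, 2)), "y")
}

#' Fit the microscope spectral profile
#'
#' The per-microscope relative variation `P_mk` is the mean of the
#' tissue-corrected spectra over samples and scans; dividing by the
#' per-layer mean over everything gives the microscope correction factors
#' `w_mk`, averaging to 1 over microscopes at every layer.
#'
#' @param y Stage-y `spectra_tensor`.
#' @return A list of class `microscope_profile`: `Pmk`, `wmk` (both M x K).
#' @export
fit_microscope_profile <- function(y) {
  v <- unclass(y)
  Pmk <- apply(v, c(2, 4), mean)
  layer_mean <- apply(v, 4, mean)
  if (any(layer_mean == 0)) stopf("zero per-layer mean; cannot form wmk")
  wmk <- sweep(Pmk, 2, layer_mean, "/")
  structure(list(Pmk = Pmk, wmk = wmk), class = "microscope_profile")
}

#' Apply the microscope profile correction
#'
#' `z = y / w_mk`, elementwise over (n, m, r, k).
#'
#' @param y Stage-y `spectra_tensor`.
#' @param profile A `microscope_profile`.
#' @return `spectra_tensor` at stage `"z"`.
#' @export
apply_microscope_profile <- function(y, profile) {
  wmk <- .check_positive(profile$wmk, "wmk")
  v <- unclass(y)
  vp <- aperm(v, c(2, 4, 1, 3))       # (m, k, n, r)
  vp <- vp / c(wmk)
  .rewrap(aperm(vp, c(3, 1, 4, 2)), "z")
}

#' Decompose microscope profiles into illumination, broadband and
#' narrowband parts
#'
#' Splits each microscope's per-layer correction factors `w_mk` into an
#' overall illumination scale `w_m^ill` (the mean over all layers), a
#' broadband-filter contribution `w_mk^BB` (the within-group mean of
#' `w_mk / w_m^ill`, constant across each broadband group's layers), and a
#' narrowband residual `w_mk^NB = w_mk / (w_m^ill * w_mk^BB)`. The product
#' of the three parts reconstructs `w_mk` exactly.
#'
#' @param profile A `microscope_profile`.
#' @param layout The `filter_layout` grouping layers by broadband cube.
#' @return A list of class `wmk_decomposition`: `wmill` (length M),
#'   `wmkBB`, `wmkNB` (both M x K).
#' @export
decompose_microscope_profile <- function(profile, layout) {
  layout <- validate_layout(layout)
  wmk <- profile$wmk
  if (ncol(wmk) != layout$K) stopf("profile has %d layers, layout %d", ncol(wmk), layout$K)
  wmill <- rowMeans(wmk)
  if (any(wmill == 0)) stopf("zero illumination scale")
  rel <- wmk / wmill
  wmkBB <- rel
  for (g in layout$groups) {
    gm <- rowMeans(rel[, g, drop = FALSE])
    if (any(gm == 0)) stopf("zero broadband factor")
    wmkBB[, g] <- gm
  }
  wmkNB <- wmk / (wmill * wmkBB)
  structure(list(wmill = wmill, wmkBB = wmkBB, wmkNB = wmkNB),
            class = "wmk_decomposition")
}

#' Fit the full sequential calibration
#'
#' Runs the fixed correction sequence on a stage-X tensor: amplitude
#' factors (B_n, C_m), then the tissue spectral profile (b_nk), then the
#' microscope spectral profile (w_mk), each fitted on the output of the
#' previous correction and applied once.
#'
#' @param X Stage-X `spectra_tensor`.
#' @param layout Optional `filter_layout`; when given, the microscope
#'   profile decomposition is included.
#' @return A list of class `calibration_fit`: staged tensors `X`, `x`,
#'   `y`, `z`; `amps`; factor objects `amplitude`, `tissue`, `microscope`;
#'   and `decomposition` (or NULL).
#' @export
fit_calibration <- function(X, layout = NULL) {
  amps <- amplitude_summary(X)
  fa <- fit_amplitude_factors(amps)
  x <- apply_amplitude(X, fa)
  ft <- fit_tissue_profile(x)
  y <- apply_tissue_profile(x, ft)
  fm <- fit_microscope_profile(y)
  z <- apply_microscope_profile(y, fm)
  dec <- if (!is.null(layout)) decompose_microscope_profile(fm, layout) else NULL
  structure(
    list(X = X, x = x, y = y, z = z, amps = amps,
         amplitude = fa, tissue = ft, microscope = fm, decomposition = dec),
    class = "calibration_fit"
  )
}

#' Pooled standard errors for fitted calibration factors
#'
#' Approximate standard errors for each fitted factor, derived from the
#' residual tensor `rho = X / (B_n C_m b_nk w_mk)`. Amplitude-level
#' residual spread (of the per-scan layer means of rho) is pooled and
#' divided by the square root of the number of scans averaged into each
#' amplitude factor; layer-level residual spread of rho itself serves the
#' same role for the profile factors. These are the natural uncertainties
#' to compare fitted factors against known simulation ground truth.
#'
#' @param fit A `calibration_fit`.
#' @return List with `se_Bn`, `se_Cm` (vectors) and `se_bnk`, `se_wmk`
#'   (matrices), on the scale of the factors themselves.
#' @export
recovery_errors <- function(fit) {
  d <- dim(fit$X)
  N <- d[1]; M <- d[2]; R <- d[3]; K <- d[4]
  rho <- unclass(fit$z)                # X with the full fitted model divided out
  alpha <- apply(rho, c(1, 2, 3), mean)
  # residuals follow fits of N + M - 1 free amplitude parameters (per layer
  # for the profiles), so the pooled variances carry the matching df
  df_amp <- N * M * R - N - M + 1
  df_layer <- K * (N * M * R - N - M + 1)
  sd_alpha <- sqrt(sum((alpha - mean(alpha))^2) / df_amp)
  sd_rho <- sqrt(sum((rho - mean(rho))^2) / df_layer)
  list(
    se_Bn = fit$amplitude$Bn * sd_alpha / sqrt(M * R),
    se_Cm = fit$amplitude$Cm * sd_alpha / sqrt(N * R),
    se_bnk = fit$tissue$bnk * sd_rho / sqrt(M * R),
    se_wmk = fit$microscope$wmk * sd_rho / sqrt(N * R)
  )
}
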