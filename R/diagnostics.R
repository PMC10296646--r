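#' Per-layer standard deviation across samples, microscopes and scans
#'
#' The headline residual-variation statistic: for each layer `k`, the
#' sample standard deviation (divisor NMR - 1) of the N*M*R spectra values
#' at that layer, plus its mean over a designated set of layers. On
#' stage-normalized spectra (values about 1) the statistic is a fraction
#' and is also reported as a percent.
#'
#' @param spectra A `spectra_tensor`.
#' @param exclude_layers Optional integer vector of layers to leave out of
#'   the layer-averaged summary (e.g. an autofluorescence layer); the
#'   per-layer values are still reported for all layers.
#' @return A list of class `layer_std_report`: `sigma_k` (length K),
#'   `mean_std`, `mean_std_pct`, `stage`, `excluded`.
#' @export
layer_std <- function(spectra, exclude_layers = NULL) {
  v <- unclass(spectra)
  d <- dim(v)
  nobs <- prod(d[1:3])
  if (nobs < 2L) stopf("need at least 2 observations per layer")
  flat <- matrix(v, nrow = nobs, ncol = d[4])
  sigma_k <- apply(flat, 2, stats::sd)
  keep <- setdiff(seq_len(d[4]), exclude_layers)
  if (length(keep) == 0L) stopf("all layers excluded")
  m <- mean(sigma_k[keep])
  structure(
    list(sigma_k = sigma_k, mean_std = m, mean_std_pct = 100 * m,
         stage = attr(spectra, "stage"), excluded = exclude_layers),
    class = "layer_std_report"
  )
}

#' @export
print.layer_std_report <- function(x, ...) {
  cat(sprintf("layer_std_report [stage %s]: mean std %.3f%% over %d layers%s\n",
              x$stage %||% "?", x$mean_std_pct,
              length(x$sigma_k) - length(x$excluded),
              if (length(x$excluded)) sprintf(" (excluding %s)",
                                              paste(x$excluded, collapse = ","))
              else ""))
  invisible(x)
}

#' Image-layer-projected covariance matrix
#'
#' Covariance of the spectra across layers, with deviations taken about
#' each microscope's own per-layer mean `mu_mk` (over samples and scans)
#' and pooled over all (n, m, r) with divisor NMR (population convention).
#' Centering within microscope means purely microscope-level offsets do
#' not contribute; what remains shows the correlation structure across
#' layers, typically block-patterned by broadband group.
#'
#' @param spectra A `spectra_tensor`.
#' @return A list of class `covariance_report`: `sigma` (K x K symmetric
#'   matrix), `mu_mk` (M x K), `stage`.
#' @export
covariance_matrix <- function(spectra) {
  v <- unclass(spectra)
  d <- dim(v)
  N <- d[1]; M <- d[2]; R <- d[3]; K <- d[4]
  mu_mk <- apply(v, c(2, 4), mean)
  dev <- aperm(v, c(2, 4, 1, 3))        # (m, k, n, r)
  dev <- dev - c(mu_mk)
  dev <- aperm(dev, c(3, 1, 4, 2))      # back to (n, m, r, k)
  flat <- matrix(dev, nrow = N * M * R, ncol = K)
  sigma <- crossprod(flat) / (N * M * R)
  sigma <- (sigma + t(sigma)) / 2
  structure(list(sigma = sigma, mu_mk = mu_mk,
                 stage = attr(spectra, "stage")),
            class = "covariance_report")
}
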