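#' Discrete Otsu threshold
#'
#' Bins the input values into `n_bins` equal-width bins over `range` and
#' exhaustively picks the cut maximizing the between-class variance of the
#' binned histogram (equivalently, minimizing the weighted intra-class
#' variance). Ties take the first maximizing cut.
#'
#' For unsigned 16-bit integer data, `n_bins = 65536` with
#' `range = c(0, 65536)` makes each bin one integer value, so the result is
#' the classical discrete Otsu cut over all 65536 possible thresholds.
#'
#' @param v Numeric vector of values.
#' @param n_bins Number of histogram bins (default 65536).
#' @param range Length-2 numeric; values are binned over `[range[1],
#'   range[2])`. Defaults to the data range (top value clamped into the
#'   last bin).
#' @return The threshold value: pixels with `v < threshold` fall in the
#'   lower (background) class. `NA` if the input is constant (no threshold
#'   separates anything).
#' @export
otsu_threshold <- function(v, n_bins = 65536L, range = NULL) {
  v <- as.numeric(v)
  lo_hi <- range %||% base::range(v)
  lo <- lo_hi[1]; hi <- lo_hi[2]
  if (!(hi > lo)) return(NA_real_)
  width <- (hi - lo) / n_bins
  idx <- pmin(floor((v - lo) / width), n_bins - 1)
  idx <- pmax(idx, 0)
  counts <- tabulate(as.integer(idx) + 1L, nbins = n_bins)
  mids <- lo + (seq_len(n_bins) - 0.5) * width
  w1 <- cumsum(counts)
  total <- w1[n_bins]
  w2 <- total - w1
  m1 <- cumsum(counts * mids)
  m2 <- m1[n_bins] - m1
  # between-class variance (unnormalized); cut t keeps bins 1..t in class 1
  bc <- w1 * w2 * (m1 / w1 - m2 / w2)^2
  bc[w1 == 0 | w2 == 0] <- NA
  if (all(is.na(bc))) return(NA_real_)
  t_star <- which.max(bc)
  lo + t_star * width
}

#' Saturation thresholds
#'
#' Per-layer count thresholds above which a pixel is treated as
#' oversaturated. Real thresholds are hand-tuned per instrument and layer;
#' the default of 65500 counts (near the 16-bit full scale) is a
#' conservative stand-in.
#'
#' @param K Number of layers.
#' @param value Threshold counts, either a scalar recycled to all layers or
#'   a length-K vector; values in (0, 65535].
#' @return Numeric vector of length K.
#' @export
saturation_thresholds <- function(K, value = 65500) {
  th <- rep_len(as.numeric(value), K)
  if (any(th <= 0 | th > 65535)) stopf("saturation thresholds must lie in (0, 65535]")
  th
}

#' Compute the binary tissue mask for one HPF
#'
#' A pixel is kept (mask 1) when it shows well-imaged tissue: its projection
#' value reaches the Otsu threshold computed on this HPF's projection
#' histogram (separating empty background), and its raw count stays at or
#' below the saturation threshold in every layer. One 2-D mask applies to
#' all layers of the stack, so a pixel saturated in any layer is removed
#' everywhere.
#'
#' The projection fed to Otsu is, by default, the per-pixel mean over all
#' exposure-normalized layers; a broadband group name restricts it to that
#' group's layers (e.g. a nuclear counterstain group).
#'
#' @param pixels Integer H x W x K array of raw counts.
#' @param exposures Named exposure vector (ms per group), for the flux
#'   projection.
#' @param layout A `filter_layout`.
#' @param thresholds Per-layer saturation thresholds
#'   (see [saturation_thresholds()]); default 65500 for every layer.
#' @param otsu_source `"mean"` for the all-layer mean projection, or the
#'   name of a broadband group.
#' @param n_bins Histogram bins for the Otsu search.
#' @return A list of class `tissue_mask`: `mask` (H x W, 0/1 integer),
#'   `n_background`, `n_saturated` (pixels removed by each rule; pixels
#'   failing both count under both), `otsu_threshold`, and `constant`
#'   (TRUE when the projection was constant and Otsu was skipped with a
#'   warning).
#' @export
compute_tissue_mask <- function(pixels, exposures, layout,
                                thresholds = NULL, otsu_source = "mean",
                                n_bins = 65536L) {
  layout <- validate_layout(layout)
  d <- dim(pixels)
  K <- d[3]
  thresholds <- thresholds %||% saturation_thresholds(K)
  if (length(thresholds) != K) stopf("need one saturation threshold per layer")

  flux <- exposure_normalize(pixels, exposures, layout)
  if (identical(otsu_source, "mean")) {
    proj <- rowMeans(flux, dims = 2L)
  } else {
    g <- layout$groups[[otsu_source]]
    if (is.null(g)) stopf("unknown otsu_source group '%s'", otsu_source)
    proj <- rowMeans(flux[, , g, drop = FALSE], dims = 2L)
  }

  thr <- otsu_threshold(proj, n_bins = n_bins)
  constant <- is.na(thr)
  if (constant) {
    warnf("constant projection image: Otsu threshold undefined, keeping all pixels")
    background <- matrix(FALSE, d[1], d[2])
  } else {
    background <- proj < thr
  }

  sat <- matrix(FALSE, d[1], d[2])
  for (k in seq_len(K)) {
    sat <- sat | (pixels[, , k] > thresholds[k])
  }

  mask <- matrix(1L, d[1], d[2])
  mask[background | sat] <- 0L
  structure(
    list(mask = mask,
         n_background = sum(background),
         n_saturated = sum(sat),
         otsu_threshold = thr,
         constant = constant),
    class = "tissue_mask"
  )
}

#' Summarize tissue masks per scan
#'
#' QC table over a set of masks: the mean fraction of pixels kept and the
#' total pixels removed by the background and saturation rules.
#'
#' @param masks List of `tissue_mask` objects (one scan's HPFs).
#' @return A one-row data.frame with `n_hpf`, `kept_fraction`,
#'   `n_background`, `n_saturated`.
#' @export
mask_summary <- function(masks) {
  if (length(masks) == 0L) stopf("need at least one mask")
  fracs <- vapply(masks, function(m) mean(m$mask), 0)
  data.frame(
    n_hpf = length(masks),
    kept_fraction = mean(fracs),
    n_background = sum(vapply(masks, function(m) m$n_background, 0)),
    n_saturated = sum(vapply(masks, function(m) m$n_saturated, 0))
  )
}
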