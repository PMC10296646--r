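#' Simulation configuration
#'
#' Dimensions and acquisition parameters for a simulated multi-microscope
#' scanning experiment. The defaults emulate the structure of a
#' desk-scale study: 8 samples scanned twice on each of 3 microscopes
#' (48 scans), 12 narrowband layers in 3 broadband groups, 64 x 64 pixel
#' tiles, 4 tiles per scan. Full-size tiles (1872 x 1404, 43 layers, 7
#' groups) are configurable but not the default.
#'
#' @param N,M,R Numbers of samples, microscopes, scan repeats.
#' @param K Number of narrowband layers.
#' @param n_groups Number of broadband groups.
#' @param H,W Tile dimensions in pixels.
#' @param hpfs_per_scan Tiles per scan; scalar or length-N*M*R vector (in
#'   scan order) to exercise tile-share weighting.
#' @param tissue_fraction Fraction of each tile covered by tissue.
#' @param scene_sdlog Log-scale spread of the spatial scene texture within
#'   tissue. Kept moderate (0.2) so the tissue flux distribution stays
#'   clearly separated from empty background, as in real sections; much
#'   wider textures push the low tissue tail toward the background mode,
#'   which Otsu masking then clips at a sample-dependent quantile.
#' @param flux_scale Typical tissue flux in counts/ms.
#' @param background_flux Background flux level in counts/ms.
#' @param noise_cv Per-pixel multiplicative noise coefficient of variation.
#' @param scan_jitter_cv Per-scan amplitude jitter CV (re-scan
#'   repeatability).
#' @param sat_frac Fraction of pixels per tile planted as saturated.
#' @param exposure_range Range (ms) for per-(scan, group) exposure times.
#' @param quantize Round/clip counts to unsigned 16-bit (TRUE, the
#'   physical case) or keep exact real-valued counts (useful for
#'   noise-free model checks).
#' @param Kprime If non-NULL, generate component-mixture tissue (this many
#'   components including autofluorescence) for unmixing studies.
#' @param layout Filter layout; defaults to contiguous near-equal groups.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(N = 8L, M = 3L, R = 2L, K = 12L, n_groups = 3L,
                              H = 64L, W = 64L, hpfs_per_scan = 4L,
                              tissue_fraction = 0.6, scene_sdlog = 0.2,
                              flux_scale = 200,
                              background_flux = 0.2, noise_cv = 0.01,
                              scan_jitter_cv = 0.005, sat_frac = 0.002,
                              exposure_range = c(5, 15), quantize = TRUE,
                              Kprime = NULL, layout = NULL) {
  layout <- layout %||% default_filter_layout(K, n_groups)
  stopifnot(layout$K == K)
  structure(
    list(N = as.integer(N), M = as.integer(M), R = as.integer(R),
         K = as.integer(K), H = as.integer(H), W = as.integer(W),
         hpfs_per_scan = as.integer(hpfs_per_scan),
         tissue_fraction = tissue_fraction, scene_sdlog = scene_sdlog,
         flux_scale = flux_scale,
         background_flux = background_flux, noise_cv = noise_cv,
         scan_jitter_cv = scan_jitter_cv, sat_frac = sat_frac,
         exposure_range = exposure_range, quantize = quantize,
         Kprime = if (is.null(Kprime)) NULL else as.integer(Kprime),
         layout = layout),
    class = "sim_config"
  )
}

.smooth_ripple <- function(K, sd_target, width = max(3L, round(K / 6))) {
  width <- min(width, K)
  x <- stats::rnorm(K)
  y <- as.numeric(stats::filter(x, rep(1 / width, width), circular = TRUE))
  if (stats::sd(y) == 0) return(rep(1, K))
  exp(y * sd_target / stats::sd(y))
}

.smooth_field <- function(H, W, sdlog, width = 9L) {
  e <- matrix(stats::rnorm(H * W), H, W)
  # a circular kernel spanning a full dimension would flatten the field
  wh <- max(1L, min(width, H %/% 2))
  ww <- max(1L, min(width, W %/% 2))
  e <- apply(e, 2, function(col) as.numeric(stats::filter(col, rep(1 / wh, wh),
                                                          circular = TRUE)))
  e <- t(apply(e, 1, function(row) as.numeric(stats::filter(row, rep(1 / ww, ww),
                                                            circular = TRUE))))
  s <- stats::sd(e)
  if (s < 1e-9) return(matrix(1, H, W))
  exp(e * sdlog / s)
}

# Tissue footprint with exactly n_pix pixels: a raster band at a random
# offset (wrapping), so every sample covers an identical pixel count.
.tissue_region <- function(H, W, n_pix) {
  n_pix <- min(max(n_pix, 1L), H * W)
  off <- sample.int(H * W, 1L) - 1L
  idx <- (off + seq_len(n_pix) - 1L) %% (H * W)
  reg <- matrix(FALSE, H, W)
  reg[idx + 1L] <- TRUE
  reg
}

#' Random ground-truth factor model
#'
#' Draws the multiplicative truth behind a simulated dataset: per-sample
#' amplitudes, per-microscope amplitudes, smooth per-sample spectral
#' profiles, and per-microscope profiles built as broadband group offsets
#' (drawn uniformly within +/- `bb_max`) times a small smooth narrowband
#' ripple. In component mode the per-sample spectral profile arises from a
#' random reference library and per-sample component compositions instead.
#'
#' Microscope amplitudes default to a small (2%) spread: the scanners
#' auto-expose each broadband cube, so overall brightness differences
#' between instruments are largely absorbed into exposure times (which the
#' generator varies independently per scan and group), leaving only a
#' percent-scale residual illumination difference. Spectral differences,
#' by contrast, are dominated by the broadband filter offsets, which can
#' reach 20%.
#'
#' @param config A `sim_config`.
#' @param an_sdlog,gm_sdlog Log-scale spread of sample / microscope
#'   amplitudes.
#' @param tissue_ripple_sd Log-scale spread of per-sample spectral
#'   profiles.
#' @param bb_max Maximum broadband group offset (default 0.20). Offsets are
#'   drawn per (microscope, group) and the resulting profile is normalized
#'   to unit layer mean per microscope: broadband differences are spectral
#'   shape, the overall illumination scale stays near 1 as per-filter
#'   auto-exposure equalizes brightness between instruments.
#' @param nb_ripple_sd Log-scale spread of the narrowband ripple.
#' @return A list of class `truth_model` with `An`, `gm`, `tnk`, `wmk`,
#'   `bb`, `nb` and, in component mode, `ref_library` and `comp` (N x K'
#'   compositions); `tnk` is always the effective per-sample spectral
#'   profile.
#' @export
random_truth <- function(config, an_sdlog = 0.25, gm_sdlog = 0.02,
                         tissue_ripple_sd = 0.10, bb_max = 0.20,
                         nb_ripple_sd = 0.02) {
  N <- config$N; M <- config$M; K <- config$K
  G <- length(config$layout$groups)
  An <- exp(stats::rnorm(N, 0, an_sdlog))
  gm <- exp(stats::rnorm(M, 0, gm_sdlog))
  bb <- matrix(stats::runif(M * G, 1 - bb_max, 1 + bb_max), M, G)
  nb <- t(vapply(seq_len(M), function(m) .smooth_ripple(K, nb_ripple_sd),
                 numeric(K)))
  wmk <- bb[, config$layout$group_of, drop = FALSE] * nb
  # broadband offsets are spectral-shape differences: each microscope's
  # profile is normalized to unit layer mean (illumination ~ 1), with
  # overall brightness differences carried by gm and the exposure times
  wmk <- wmk / rowMeans(wmk)
  ref_library <- NULL; comp <- NULL
  if (is.null(config$Kprime)) {
    tnk <- t(vapply(seq_len(N), function(n) .smooth_ripple(K, tissue_ripple_sd),
                    numeric(K)))
  } else {
    Kp <- config$Kprime
    lib <- matrix(0.05, K, Kp)
    centers <- stats::runif(Kp, 1, K)
    width <- K / 5
    for (c in seq_len(Kp - 1L)) {
      lib[, c] <- lib[, c] + exp(-(seq_len(K) - centers[c])^2 / (2 * width^2))
    }
    lib[, Kp] <- 0.3                    # broad autofluorescence column
    comp <- matrix(exp(stats::rnorm(N * Kp, 0, tissue_ripple_sd)), N, Kp)
    tnk <- comp %*% t(lib)              # effective per-sample spectral profile
    tnk <- tnk / rowMeans(tnk)
    comps <- c(paste0("marker", seq_len(Kp - 1L)), "autofluorescence")
    ref_library <- spectral_library(lib, comps, microscope_id = "reference")
  }
  structure(
    list(An = An, gm = gm, tnk = tnk, wmk = wmk, bb = bb, nb = nb,
         ref_library = ref_library, comp = comp),
    class = "truth_model"
  )
}

#' Simulate a multi-microscope tiled scanning dataset
#'
#' Generates pixel counts for every tile of every scan under the
#' multiplicative model
#' `counts = clip16(exposure * (background + tissue * An*gm*tnk*wmk * scene)
#' * jitter * noise)`:
#' each sample has a fixed tissue footprint and per-tile log-normal scene
#' texture shared across microscopes and scans (the same physical slide is
#' re-scanned), each scan draws per-broadband-group exposure times and a
#' small amplitude jitter, each pixel gets multiplicative counting noise,
#' and a configured fraction of pixels is planted as saturated. The same
#' seed reproduces the dataset exactly.
#'
#' @param config A `sim_config`.
#' @param truth A `truth_model`, or NULL to draw one from the seed.
#' @param seed Integer seed controlling all randomness.
#' @param dir Optional directory: when given, the dataset is also written
#'   to disk ([write_dataset()]).
#' @return A `mif_dataset` with in-memory tiles and the truth (plus the
#'   config and seed) stored in `$truth`.
#' @export
simulate_dataset <- function(config, truth = NULL, seed = 1L, dir = NULL) {
  ds <- with_seed(seed, .simulate_dataset_impl(config, truth))
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

.simulate_dataset_impl <- function(config, truth) {
  N <- config$N; M <- config$M; R <- config$R; K <- config$K
  H <- config$H; W <- config$W
  if (is.null(truth)) truth <- random_truth(config)
  n_scans <- N * M * R
  hp <- rep_len(config$hpfs_per_scan, n_scans)
  n_pix_tissue <- round(config$tissue_fraction * H * W)

  # Per-sample slide content, shared across microscopes and scans.
  regions <- vector("list", N)
  scenes <- vector("list", N)      # [[n]][[h]] : H x W, mean 1 over the footprint
  abunds <- vector("list", N)      # component mode: [[n]][[h]] : H*W x K'
  max_h <- max(hp)
  for (n in seq_len(N)) {
    regions[[n]] <- .tissue_region(H, W, n_pix_tissue)
    scenes[[n]] <- vector("list", max_h)
    if (!is.null(config$Kprime)) abunds[[n]] <- vector("list", max_h)
    for (h in seq_len(max_h)) {
      s <- .smooth_field(H, W, config$scene_sdlog)
      s <- s / mean(s[regions[[n]]])
      scenes[[n]][[h]] <- s
      if (!is.null(config$Kprime)) {
        Kp <- config$Kprime
        ab <- matrix(0, H * W, Kp)
        for (c in seq_len(Kp)) {
          f <- .smooth_field(H, W, config$scene_sdlog)
          ab[, c] <- truth$comp[n, c] * as.numeric(f) / mean(f[regions[[n]]])
        }
        abunds[[n]][[h]] <- ab
      }
    }
  }

  group_names <- names(config$layout$groups)
  scans <- vector("list", n_scans)
  si <- 0L
  all_saturated <- TRUE
  for (n in seq_len(N)) for (m in seq_len(M)) for (r in seq_len(R)) {
    si <- si + 1L
    exposures <- stats::runif(length(group_names),
                              config$exposure_range[1], config$exposure_range[2])
    names(exposures) <- group_names
    jitter <- if (config$scan_jitter_cv > 0) {
      1 + config$scan_jitter_cv * stats::rnorm(1)
    } else 1
    per_layer_exp <- exposures[config$layout$group_of]
    region <- as.numeric(regions[[n]])
    n_hpf <- hp[si]
    hpfs <- vector("list", n_hpf)
    for (h in seq_len(n_hpf)) {
      if (is.null(config$Kprime)) {
        base_k <- config$flux_scale * truth$An[n] * truth$gm[m] *
          truth$tnk[n, ] * truth$wmk[m, ]
        signal <- outer(as.numeric(scenes[[n]][[h]]) * region, base_k)
      } else {
        spec <- abunds[[n]][[h]] %*% t(truth$ref_library$values)   # H*W x K
        amp_k <- config$flux_scale * truth$An[n] * truth$gm[m] * truth$wmk[m, ]
        signal <- (spec * region) * rep(amp_k, each = H * W)
      }
      flux <- config$background_flux + signal
      counts <- flux * rep(per_layer_exp, each = H * W) * jitter
      if (config$noise_cv > 0) {
        counts <- counts * (1 + config$noise_cv * stats::rnorm(length(counts)))
      }
      counts <- array(counts, dim = c(H, W, K))
      if (config$quantize) {
        counts <- round(pmin(pmax(counts, 0), 65535))
        storage.mode(counts) <- "integer"
      }
      if (config$sat_frac > 0) {
        n_sat <- round(config$sat_frac * H * W)
        if (n_sat > 0) {
          pix <- sample.int(H * W, n_sat)
          lay <- sample.int(K, n_sat, replace = TRUE)
          counts[pix + (lay - 1L) * H * W] <-
            if (config$quantize) 65535L else 65535
        }
      }
      if (any(counts < 65535)) all_saturated <- FALSE
      hpfs[[h]] <- counts
    }
    scans[[si]] <- list(
      n = n, m = m, r = r,
      sample_id = sprintf("sample%02d", n),
      microscope_id = sprintf("scope%d", m),
      exposures = exposures, hpfs = hpfs, n_hpf = n_hpf
    )
  }
  if (all_saturated) stopf("simulation saturated every pixel; lower flux_scale or exposures")
  truth$config <- config
  mif_dataset(scans, config$layout,
              samples = sprintf("sample%02d", seq_len(N)),
              microscopes = sprintf("scope%d", seq_len(M)),
              n_scan_reps = R, H = H, W = W, truth = truth)
}

#' Gauge-fix a truth model to the estimator normalization
#'
#' The multiplicative model identifies its factors only up to the
#' normalization conventions of the sequential estimators (mean-1
#' amplitudes, per-layer mean-1 profiles), and the estimators couple the
#' tissue and microscope profiles through layer means of their product.
#' The gauge-fixed truth is therefore defined operationally: the exact
#' noise-free spectra tensor implied by the truth factors is pushed
#' through the calibration chain, and the factors it returns are the
#' reference against which fits on noisy data are compared. The factor
#' product is preserved up to one global scalar.
#'
#' @param truth A `truth_model` (with `$config` attached, as stored in a
#'   simulated dataset) or alongside an explicit `config`.
#' @param config A `sim_config`; defaults to `truth$config`.
#' @return A list of class `gauge_truth`: `Bn`, `Cm`, `bnk`, `wmk`.
#' @export
gauge_fix_truth <- function(truth, config = NULL) {
  config <- config %||% truth$config
  N <- config$N; M <- config$M; R <- config$R; K <- config$K
  P <- array(0, dim = c(N, M, R, K))
  for (n in seq_len(N)) for (m in seq_len(M)) {
    row <- truth$An[n] * truth$gm[m] * truth$tnk[n, ] * truth$wmk[m, ]
    for (r in seq_len(R)) P[n, m, r, ] <- row
  }
  X <- grand_normalize(spectra_tensor(P, "Xtilde"))
  fit <- fit_calibration(X)
  structure(list(Bn = fit$amplitude$Bn, Cm = fit$amplitude$Cm,
                 bnk = fit$tissue$bnk, wmk = fit$microscope$wmk),
            class = "gauge_truth")
}

#' Expected residual noise floor of a simulated dataset
#'
#' The per-spectrum noise level implied by the generator settings: scan
#' amplitude jitter plus pixel counting noise averaged over the tissue
#' pixels contributing to one scan's layer mean. Residual (stage-z) layer
#' stds on simulated data should sit near this floor.
#'
#' @param config A `sim_config`.
#' @return Scalar noise floor (fractional).
#' @export
expected_noise_floor <- function(config) {
  n_pix <- round(config$tissue_fraction * config$H * config$W) *
    min(rep_len(config$hpfs_per_scan, 1L))
  sqrt(config$scan_jitter_cv^2 + config$noise_cv^2 / max(n_pix, 1))
}
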