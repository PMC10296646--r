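#' Spectral unmixing library
#'
#' A library of pure component emission spectra: a K x K' non-negative
#' matrix whose columns are the spectra of each fluorophore plus one
#' autofluorescence column, as measured on a particular microscope.
#'
#' @param values K x K' non-negative numeric matrix.
#' @param components Character vector of K' unique component names.
#' @param microscope_id Optional id of the microscope the library was
#'   measured on.
#' @return An object of class `spectral_library`.
#' @export
spectral_library <- function(values, components, microscope_id = NULL) {
  values <- as.matrix(values)
  if (any(values < 0)) stopf("library spectra must be non-negative")
  if (length(components) != ncol(values)) stopf("one name per library column required")
  if (anyDuplicated(components)) stopf("library component names must be unique")
  if (any(colSums(values) == 0)) stopf("library contains an all-zero column")
  structure(list(values = values, components = as.character(components),
                 microscope_id = microscope_id),
            class = "spectral_library")
}

#' Project a reference library through a microscope's response
#'
#' Emulates measuring the library slides on another microscope: each layer
#' of the reference spectra is scaled by that microscope's amplitude and
#' per-layer profile factor, optionally with multiplicative measurement
#' noise (libraries are physically measured, so real ones are not exact).
#'
#' @param ref_library A `spectral_library`.
#' @param amplitude Scalar microscope amplitude factor.
#' @param wmk_row Length-K per-layer profile factors of the microscope.
#' @param noise_cv Coefficient of variation of multiplicative measurement
#'   noise (0 = exact projection).
#' @param seed Seed for the measurement noise.
#' @param microscope_id Id for the projected library.
#' @return A `spectral_library`.
#' @export
microscope_library <- function(ref_library, amplitude, wmk_row,
                               noise_cv = 0, seed = 1L, microscope_id = NULL) {
  v <- ref_library$values * (amplitude * wmk_row)
  if (noise_cv > 0) {
    v <- with_seed(seed, v * pmax(1 + noise_cv * stats::rnorm(length(v)), 0.01))
  }
  spectral_library(v, ref_library$components, microscope_id)
}

# Lawson-Hanson NNLS for a single right-hand side; fallback for the rare
# pixel on which block pivoting cycles out of its iteration budget.
.nnls_single <- function(AtA, Atb, tol) {
  p <- length(Atb)
  P <- logical(p)
  x <- numeric(p)
  w <- Atb - AtA %*% x
  it <- 0L
  while (any(!P & w > tol) && it < 30L * p) {
    it <- it + 1L
    j <- which.max(ifelse(!P, w, -Inf))
    P[j] <- TRUE
    repeat {
      s <- numeric(p)
      s[P] <- solve(AtA[P, P, drop = FALSE], Atb[P])
      if (all(s[P] > tol)) { x <- s; break }
      Q <- P & s <= tol
      alpha <- min(x[Q] / (x[Q] - s[Q]))
      x <- x + alpha * (s - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
    }
    w <- Atb - AtA %*% x
  }
  x
}

#' Batch non-negative least squares with a shared design matrix
#'
#' Solves `min ||A x_j - b_j||^2, x_j >= 0` for every column `b_j` of `B`
#' simultaneously, using block principal pivoting on the normal equations
#' with columns grouped by passive set (one small Cholesky solve per
#' distinct pattern per sweep). This is the workhorse for per-pixel
#' spectral unmixing, where one library matrix is applied to hundreds of
#' thousands of pixel spectra.
#'
#' Rank-deficient `A` triggers a warning and a vanishing-ridge solve,
#' which returns (numerically) the minimum-Euclidean-norm point among the
#' optima.
#'
#' @param A K x p design matrix (the library).
#' @param B K x P matrix of right-hand sides (pixel spectra in columns).
#' @param tol Feasibility tolerance.
#' @return p x P matrix of non-negative coefficients.
#' @export
nnls_multi <- function(A, B, tol = 1e-10) {
  A <- as.matrix(A); B <- as.matrix(B)
  p <- ncol(A); P <- ncol(B)
  AtA <- crossprod(A)
  if (qr(A)$rank < p) {
    warnf("rank-deficient library: returning minimum-norm optimum via vanishing ridge")
    AtA <- AtA + diag(1e-10 * mean(diag(AtA)), p)
  }
  AtB <- crossprod(A, B)
  Fmat <- matrix(FALSE, p, P)
  X <- matrix(0, p, P)
  Y <- -AtB
  ninf <- rep.int(p + 1L, P)
  backup <- rep.int(3L, P)
  active <- rep.int(TRUE, P)
  pow2 <- 2^(seq_len(p) - 1)
  max_sweeps <- 10L * p + 50L
  sweep_i <- 0L
  while (any(active) && sweep_i < max_sweeps) {
    sweep_i <- sweep_i + 1L
    cols <- which(active)
    infeas <- (Fmat[, cols, drop = FALSE] & (X[, cols, drop = FALSE] < -tol)) |
      (!Fmat[, cols, drop = FALSE] & (Y[, cols, drop = FALSE] < -tol))
    n_new <- colSums(infeas)
    done <- n_new == 0L
    active[cols[done]] <- FALSE
    if (all(done)) break
    work <- which(!done)
    for (wi in work) {
      j <- cols[wi]
      if (n_new[wi] < ninf[j]) {
        ninf[j] <- n_new[wi]; backup[j] <- 3L
        Fmat[, j] <- xor(Fmat[, j], infeas[, wi])
      } else if (backup[j] > 0L) {
        backup[j] <- backup[j] - 1L
        Fmat[, j] <- xor(Fmat[, j], infeas[, wi])
      } else {
        jj <- max(which(infeas[, wi]))
        Fmat[jj, j] <- !Fmat[jj, j]
      }
    }
    upd <- cols[!done]
    keys <- as.vector(pow2 %*% Fmat[, upd, drop = FALSE])
    for (key in unique(keys)) {
      sel <- upd[keys == key]
      Fv <- Fmat[, sel[1]]
      if (!any(Fv)) {
        X[, sel] <- 0
        Y[, sel] <- -AtB[, sel, drop = FALSE]
      } else {
        sol <- solve(AtA[Fv, Fv, drop = FALSE], AtB[Fv, sel, drop = FALSE])
        X[, sel] <- 0
        X[Fv, sel] <- sol
        Y[, sel] <- AtA[, Fv, drop = FALSE] %*% sol - AtB[, sel, drop = FALSE]
        Y[Fv, sel] <- 0
      }
    }
  }
  if (any(active)) {
    for (j in which(active)) X[, j] <- .nnls_single(AtA, AtB[, j], tol)
  }
  X[X < 0] <- 0
  X
}

#' Unmix a multispectral stack into component layers
#'
#' Per-pixel non-negative linear decomposition: each pixel's K-layer
#' spectrum is modelled as a non-negative combination of the library's
#' pure component spectra, and the least-squares coefficients become the
#' K' layers of the unmixed image (one per marker plus autofluorescence).
#' This is a transparent linear surrogate for vendor unmixing software,
#' whose algorithm is proprietary; comparisons built on it are about
#' relative, not absolute, agreement.
#'
#' @param flux H x W x K numeric array (exposure-normalized flux).
#' @param library A `spectral_library` with K rows.
#' @return H x W x K' array with the component names in
#'   `dimnames(...)[[3]]`.
#' @export
unmix_stack <- function(flux, library) {
  d <- dim(flux)
  if (length(d) != 3L || d[3] != nrow(library$values)) {
    stopf("stack has %s layers, library expects %d",
          if (length(d) == 3L) d[3] else "?", nrow(library$values))
  }
  Bmat <- t(matrix(flux, nrow = d[1] * d[2], ncol = d[3]))
  coefs <- nnls_multi(library$values, Bmat)
  out <- array(t(coefs), dim = c(d[1], d[2], ncol(library$values)))
  dimnames(out) <- list(NULL, NULL, library$components)
  out
}

#' Compare unmixing scenarios across microscopes
#'
#' Quantifies how much of the cross-microscope variation in unmixed marker
#' expressions is removed by standardization, via three scenarios:
#' (A) unmix raw flux with the reference microscope's library;
#' (B) unmix raw flux with each microscope's own library;
#' (C) standardize raw flux to the reference microscope, then unmix with
#' the reference library.
#'
#' For each scenario the unmixed stacks are masked, reduced to K'-layer
#' spectra (mean image, layer means, tile-share weighting, grand
#' normalization), homogenized for tissue effects (sample amplitude and
#' per-sample spectral factors), and summarized by the residual layer std
#' with the autofluorescence layer excluded from the average.
#'
#' @param dataset A `mif_dataset`.
#' @param libraries List of `spectral_library`s indexed by microscope
#'   (length M).
#' @param std_factors `standardization_factors` referencing `ref_m`.
#' @param ref_m Reference microscope index.
#' @param exclude_component Component name excluded from the layer-averaged
#'   std (default `"autofluorescence"`; NULL to keep all).
#' @param thresholds,otsu_source,masks Passed to the masking stage.
#' @return A list of class `scenario_comparison`: `reports` (named list of
#'   `layer_std_report`s for A, B, C), `table` (data.frame scenario /
#'   mean_std_pct), `psi` (named list of homogenized spectra tensors).
#' @export
scenario_compare <- function(dataset, libraries, std_factors, ref_m,
                             exclude_component = "autofluorescence",
                             thresholds = NULL, otsu_source = "mean",
                             masks = c("otsu", "none")) {
  masks <- match.arg(masks)
  N <- length(dataset$samples); M <- length(dataset$microscopes)
  R <- dataset$n_scan_reps
  if (length(libraries) < M) stopf("need a library for every microscope")
  Kp <- ncol(libraries[[ref_m]]$values)
  comps <- libraries[[ref_m]]$components
  excl <- if (is.null(exclude_component)) NULL else {
    idx <- match(exclude_component, comps)
    if (is.na(idx)) NULL else idx
  }

  xbar <- list(A = array(NA_real_, c(N, M, R, Kp)),
               B = array(NA_real_, c(N, M, R, Kp)),
               C = array(NA_real_, c(N, M, R, Kp)))
  hmrn <- array(0, dim = c(N, M, R))

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
    unmixed <- list(A = vector("list", scan$n_hpf),
                    B = vector("list", scan$n_hpf),
                    C = vector("list", scan$n_hpf))
    if (is.null(libraries[[scan$m]])) {
      stopf("missing library for microscope %d (scenario B)", scan$m)
    }
    for (h in seq_len(scan$n_hpf)) {
      f <- flux_list[[h]]
      unmixed$A[[h]] <- unmix_stack(f, libraries[[ref_m]])
      unmixed$B[[h]] <- unmix_stack(f, libraries[[scan$m]])
      fc <- standardize_stack(f, scan$m, std_factors)
      unmixed$C[[h]] <- unmix_stack(fc, libraries[[ref_m]])
    }
    for (sc in names(unmixed)) {
      mi <- accumulate_mean_image(unmixed[[sc]], mask_list)
      xbar[[sc]][scan$n, scan$m, scan$r, ] <- layer_mean_spectrum(mi)
    }
    hmrn[scan$n, scan$m, scan$r] <- scan$n_hpf
  }

  reports <- list(); psis <- list()
  for (sc in names(xbar)) {
    Xp <- grand_normalize(hpf_fraction_weight(spectra_tensor(xbar[[sc]], "Xbar"),
                                              hmrn))
    Bn <- fit_amplitude_factors(amplitude_summary(Xp))$Bn
    hom <- tissue_homogenize(Xp, Bn)
    rep_sc <- layer_std(hom$psi, exclude_layers = excl)
    rep_sc$stage <- paste0("psi_unmixed_", sc)
    reports[[sc]] <- rep_sc
    psis[[sc]] <- hom$psi
  }
  structure(
    list(reports = reports,
         table = data.frame(scenario = names(reports),
                            mean_std_pct = vapply(reports,
                                                  function(r) r$mean_std_pct, 0)),
         psi = psis),
    class = "scenario_comparison"
  )
}
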