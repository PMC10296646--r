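#' Homogenize tissue effects before the microscope bootstrap
#'
#' Removes sample-specific structure from stage-X spectra so that only
#' microscope-dependent variation remains: divides by the sample amplitude
#' factors (`chi = X / B_n`), fits per-sample spectral factors
#' `beta_nk` (the per-(n,k) mean of chi over microscopes and scans divided
#' by the per-layer grand mean), and divides them out
#' (`psi = chi / beta_nk`).
#'
#' @param X Stage-X `spectra_tensor`.
#' @param Bn Positive sample amplitude factors (length N).
#' @return List with `chi`, `psi` (`spectra_tensor`s) and `beta_nk`
#'   (N x K matrix).
#' @export
tissue_homogenize <- function(X, Bn) {
  Bn <- .check_positive(Bn, "Bn")
  v <- unclass(X)
  chi <- v / c(Bn)                       # recycles over (m, r, k)
  Tnk <- apply(chi, c(1, 4), mean)
  layer_mean <- apply(chi, 4, mean)
  if (any(layer_mean == 0)) stopf("zero per-layer mean; cannot form beta_nk")
  beta_nk <- sweep(Tnk, 2, layer_mean, "/")
  if (any(beta_nk <= 0)) stopf("nonpositive beta_nk")
  chip <- aperm(chi, c(1, 4, 2, 3))
  chip <- chip / c(beta_nk)
  psi <- aperm(chip, c(1, 3, 4, 2))
  list(chi = .rewrap(chi, "chi"), psi = .rewrap(psi, "psi"),
       beta_nk = beta_nk)
}

#' Enumerate bootstrap fit subsets
#'
#' In exhaustive mode, all `choose(N, Nfit)` subsets of the samples in
#' deterministic lexicographic order; in random mode, `iterations` seeded
#' draws of `Nfit` samples without replacement (within each draw).
#'
#' @param N Total number of samples.
#' @param Nfit Fit-subset size, `1 <= Nfit < N`.
#' @param mode `"exhaustive"` (default) or `"random"`.
#' @param iterations Number of draws in random mode.
#' @param seed Seed for random mode.
#' @return List of integer vectors (sample indices).
#' @export
enumerate_fit_subsets <- function(N, Nfit, mode = c("exhaustive", "random"),
                                  iterations = 100L, seed = 1L) {
  mode <- match.arg(mode)
  if (!is_count(N) || !is_count(Nfit) || Nfit < 1 || Nfit >= N) {
    stopf("need 1 <= Nfit < N")
  }
  if (mode == "exhaustive") {
    cmb <- utils::combn(N, Nfit)
    lapply(seq_len(ncol(cmb)), function(j) as.integer(cmb[, j]))
  } else {
    with_seed(seed, {
      lapply(seq_len(iterations),
             function(i) sort(sample.int(N, Nfit)))
    })
  }
}

#' One bootstrap iteration of the microscope-factor fit
#'
#' Computes microscope amplitude factors `C_m^s` (mean of the per-scan
#' amplitudes over the fit samples and scans) and microscope profile
#' factors `omega_mk^s` (per-(m,k) mean of psi over fit samples and scans,
#' divided by the per-layer fit-set grand mean), then applies them to all
#' samples, `z = psi / (C_m^s * omega_mk^s)`, and reports the residual
#' layer std separately over the fit and held-out test samples.
#'
#' @param psi Stage-psi `spectra_tensor` (tissue-homogenized).
#' @param amps `amplitude_table` of the full dataset.
#' @param fit_set Integer vector of fit-sample indices.
#' @return A list of class `bootstrap_iteration`: `fit_set`, `test_set`,
#'   `Cms`, `omega_mks`, `z`, `fit_std`, `test_std` (layer_std_reports;
#'   `test_std` NULL when the test set is empty).
#' @export
bootstrap_iteration <- function(psi, amps, fit_set) {
  v <- unclass(psi)
  d <- dim(v)
  N <- d[1]
  fit_set <- sort(unique(as.integer(fit_set)))
  if (length(fit_set) == 0L || any(fit_set < 1L | fit_set > N)) {
    stopf("invalid fit set")
  }
  test_set <- setdiff(seq_len(N), fit_set)
  a <- unclass(amps)
  Cms <- apply(a[fit_set, , , drop = FALSE], 2, mean)
  sub <- v[fit_set, , , , drop = FALSE]
  omega_num <- apply(sub, c(2, 4), mean)
  omega_den <- apply(sub, 4, mean)
  if (any(omega_den == 0) || any(Cms == 0)) stopf("zero denominator in bootstrap fit")
  omega_mks <- sweep(omega_num, 2, omega_den, "/")
  zp <- aperm(v, c(2, 4, 1, 3))
  zp <- zp / c(Cms * omega_mks)          # (m,k) factors; C recycles over k via product below
  z <- aperm(zp, c(3, 1, 4, 2))
  fit_std <- layer_std(spectra_tensor(z[fit_set, , , , drop = FALSE], "z_fit"))
  test_std <- if (length(test_set) > 0L) {
    layer_std(spectra_tensor(z[test_set, , , , drop = FALSE], "z_test"))
  } else NULL
  structure(
    list(fit_set = fit_set, test_set = test_set, Cms = Cms,
         omega_mks = omega_mks, z = .rewrap(z, "z_boot"),
         fit_std = fit_std, test_std = test_std),
    class = "bootstrap_iteration"
  )
}

#' Aggregate bootstrap iterations
#'
#' Summarizes per-iteration results: the mean and standard deviation (over
#' iterations) of the layer-averaged fit and test residual stds, and the
#' elementwise means over iterations of the `C_m^s` and `omega_mk^s`
#' factors. Both the product-of-means (default standardization input) and
#' the mean of per-iteration products are reported.
#'
#' @param iters List of `bootstrap_iteration`s.
#' @return A list of class `bootstrap_summary`: `n_iter`, `fit_mean_std`,
#'   `fit_std_of_std`, `test_mean_std`, `test_std_of_std` (percent scale),
#'   `Cm_mean`, `omega_mk_mean`, `factor_product_mean` (mean over
#'   iterations of `C_m^s * omega_mk^s`), `iterations` (the records).
#' @export
aggregate_bootstrap <- function(iters) {
  if (length(iters) == 0L) stopf("need at least one iteration")
  fit_vals <- vapply(iters, function(it) it$fit_std$mean_std_pct, 0)
  test_vals <- vapply(iters, function(it) {
    if (is.null(it$test_std)) NA_real_ else it$test_std$mean_std_pct
  }, 0)
  Cm_stack <- vapply(iters, function(it) it$Cms, iters[[1]]$Cms)
  Cm_mean <- if (is.matrix(Cm_stack)) rowMeans(Cm_stack) else mean(Cm_stack)
  omega_sum <- Reduce(`+`, lapply(iters, function(it) it$omega_mks))
  omega_mk_mean <- omega_sum / length(iters)
  prod_sum <- Reduce(`+`, lapply(iters, function(it) it$Cms * it$omega_mks))
  structure(
    list(n_iter = length(iters),
         fit_mean_std = mean(fit_vals),
         fit_std_of_std = if (length(iters) > 1L) stats::sd(fit_vals) else 0,
         test_mean_std = mean(test_vals, na.rm = TRUE),
         test_std_of_std = if (sum(!is.na(test_vals)) > 1L) {
           stats::sd(test_vals, na.rm = TRUE)
         } else 0,
         Cm_mean = Cm_mean,
         omega_mk_mean = omega_mk_mean,
         factor_product_mean = prod_sum / length(iters),
         iterations = iters),
    class = "bootstrap_summary"
  )
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("bootstrap_summary: %d iterations\n", x$n_iter))
  cat(sprintf("  fit  std %.3f +/- %.3f %%\n", x$fit_mean_std, x$fit_std_of_std))
  cat(sprintf("  test std %.3f +/- %.3f %%\n", x$test_mean_std, x$test_std_of_std))
  invisible(x)
}

#' Run the full subset bootstrap of the microscope factors
#'
#' Homogenizes tissue effects (via the full-dataset `B_n`), enumerates fit
#' subsets, runs every iteration, and aggregates.
#'
#' @param X Stage-X `spectra_tensor`.
#' @param Nfit Fit-subset size (default 5).
#' @param mode,iterations,seed Passed to [enumerate_fit_subsets()].
#' @return A `bootstrap_summary`, with the homogenization attached as
#'   attribute `"homogenized"`.
#' @export
run_bootstrap <- function(X, Nfit = 5L, mode = c("exhaustive", "random"),
                          iterations = 100L, seed = 1L) {
  mode <- match.arg(mode)
  amps <- amplitude_summary(X)
  Bn <- fit_amplitude_factors(amps)$Bn
  hom <- tissue_homogenize(X, Bn)
  subsets <- enumerate_fit_subsets(dim(X)[1], Nfit, mode, iterations, seed)
  iters <- lapply(subsets, function(s) bootstrap_iteration(hom$psi, amps, s))
  out <- aggregate_bootstrap(iters)
  attr(out, "homogenized") <- hom
  out
}
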