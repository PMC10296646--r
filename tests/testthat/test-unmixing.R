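well_conditioned_library <- function(K = 8, Kp = 3, seed = 61) {
  set.seed(seed)
  centers <- seq(1.5, K - 0.5, length.out = Kp)
  v <- sapply(centers, function(cc) 0.02 + exp(-(seq_len(K) - cc)^2 / 2))
  spectral_library(v, c(paste0("marker", seq_len(Kp - 1)), "autofluorescence"))
}

test_that("library construction validates its inputs", {
  expect_error(spectral_library(matrix(-1, 2, 1), "a"), "non-negative")
  expect_error(spectral_library(matrix(0, 2, 1), "a"), "all-zero")
  expect_error(spectral_library(matrix(1, 2, 2), c("a", "a")), "unique")
})

test_that("nnls recovers exact members, zeros, and noiseless mixtures", {
  lib <- well_conditioned_library()
  A <- lib$values

  one <- nnls_multi(A, 3.5 * A[, 2, drop = FALSE])
  expect_equal(as.numeric(one), c(0, 3.5, 0), tolerance = 1e-8)

  expect_equal(as.numeric(nnls_multi(A, matrix(0, nrow(A), 1))), c(0, 0, 0))

  set.seed(62)
  coefs <- matrix(runif(3 * 50, 0, 5), 3, 50)
  got <- nnls_multi(A, A %*% coefs)
  expect_equal(got, coefs, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("nnls matches the reference single-pixel solver on active-constraint cases", {
  skip_if_not_installed("pracma")
  set.seed(63)
  A <- matrix(runif(6 * 4), 6, 4)
  B <- matrix(rnorm(6 * 40), 6, 40)       # many pixels want negative coefficients
  got <- nnls_multi(A, B)
  for (j in seq_len(ncol(B))) {
    ref <- pracma::lsqnonneg(A, B[, j])$x
    expect_equal(got[, j], ref, tolerance = 1e-8)
  }
})

test_that("nnls two-component solutions beat an exhaustive grid search", {
  set.seed(64)
  A <- cbind(c(1, 0.4, 0.1, 0), c(0, 0.3, 0.8, 1))
  for (i in 1:5) {
    b <- A %*% runif(2, 0, 3) + rnorm(4, 0, 0.2)
    x <- nnls_multi(A, b)
    grid <- oracle_nnls_grid(A, as.numeric(b), upper = 5)
    r_impl <- sum((A %*% x - b)^2)
    expect_lte(r_impl, grid$resid + 1e-10)
    expect_equal(as.numeric(x), grid$x, tolerance = 5 / 200 + 1e-8)
  }
})

test_that("nnls solutions are scale-equivariant and locally optimal", {
  lib <- well_conditioned_library()
  A <- lib$values
  set.seed(65)
  B <- matrix(runif(nrow(A) * 20, 0, 10), nrow(A), 20)
  X1 <- nnls_multi(A, B)
  X3 <- nnls_multi(A, 3 * B)
  expect_equal(X3, 3 * X1, tolerance = 1e-9)

  delta <- 1e-5
  for (j in c(1, 7, 20)) {
    x <- X1[, j]; b <- B[, j]
    r0 <- sum((A %*% x - b)^2)
    for (p in seq_along(x)) {
      for (s in c(-1, 1)) {
        xp <- x; xp[p] <- xp[p] + s * delta
        if (xp[p] < 0) next                    # infeasible direction
        expect_gte(sum((A %*% xp - b)^2), r0 - 1e-12)
      }
    }
  }
})

test_that("a rank-deficient library warns and still returns a valid optimum", {
  A <- cbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1))   # duplicated column
  b <- matrix(c(2, 2, 1), 3, 1)
  expect_warning(x <- nnls_multi(A, b), "rank-deficient")
  expect_true(all(x >= 0))
  expect_equal(as.numeric(A %*% x), c(2, 2, 1), tolerance = 1e-4)
})

test_that("unmix_stack reshapes per-pixel coefficients into component layers", {
  lib <- well_conditioned_library()
  set.seed(66)
  ab <- array(runif(4 * 5 * 3, 0, 2), c(4, 5, 3))
  flux <- array(0, c(4, 5, nrow(lib$values)))
  for (i in 1:4) for (j in 1:5) {
    flux[i, j, ] <- lib$values %*% ab[i, j, ]
  }
  um <- unmix_stack(flux, lib)
  expect_equal(dim(um), c(4, 5, 3))
  expect_equal(dimnames(um)[[3]], lib$components)
  expect_equal(um, ab, tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("microscope projection scales library rows by the planted response", {
  lib <- well_conditioned_library()
  w <- exp(seq(-0.2, 0.2, length.out = nrow(lib$values)))
  proj <- microscope_library(lib, 1.1, w)
  expect_equal(proj$values, lib$values * (1.1 * w))
  noisy1 <- microscope_library(lib, 1.1, w, noise_cv = 0.05, seed = 2)
  noisy2 <- microscope_library(lib, 1.1, w, noise_cv = 0.05, seed = 2)
  expect_identical(noisy1$values, noisy2$values)
  expect_false(identical(noisy1$values, proj$values))
})

test_that("identical microscopes give identical near-zero scenario reports", {
  cfg <- simulation_config(N = 3, M = 2, R = 2, K = 6, n_groups = 2,
                           H = 16, W = 16, hpfs_per_scan = 2, Kprime = 3,
                           noise_cv = 0, scan_jitter_cv = 0, sat_frac = 0,
                           background_flux = 0, quantize = FALSE)
  truth <- random_truth(cfg)
  truth$gm <- rep(1, 2)
  truth$wmk <- matrix(1, 2, 6)
  ds <- simulate_dataset(cfg, truth = truth, seed = 5)
  lib <- ds$truth$ref_library
  sf <- structure(list(factors = matrix(1, 2, 6), ref_m = 1L,
                       microscope_ids = ds$microscopes),
                  class = "standardization_factors")
  scen <- scenario_compare(ds, list(lib, lib), sf, ref_m = 1L)
  expect_lt(max(scen$table$mean_std_pct), 1e-6)
  expect_equal(scen$reports$A$sigma_k, scen$reports$B$sigma_k,
               tolerance = 1e-9)
})

test_that("standardization beats no correction in the scenario comparison", {
  ds <- scenario_dataset()
  sp <- normalized_spectra(ds)
  boot <- run_bootstrap(sp$X, Nfit = 5)
  sf <- reference_standardization_factors(boot, 2L)
  tr <- ds$truth
  libs <- lapply(1:3, function(m) {
    microscope_library(tr$ref_library, tr$gm[m], tr$wmk[m, ],
                       microscope_id = ds$microscopes[m])
  })
  scen <- scenario_compare(ds, libs, sf, ref_m = 2L)
  stds <- scen$table$mean_std_pct
  names(stds) <- scen$table$scenario
  # corrected-then-reference-unmixed (C) and microscope-specific libraries
  # (B) must both improve sharply on uncorrected reference unmixing (A)
  expect_lt(stds["C"], stds["A"])
  expect_lt(stds["B"], stds["A"])
  # autofluorescence exclusion is honoured
  expect_equal(scen$reports$A$excluded,
               match("autofluorescence", tr$ref_library$components))
})
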