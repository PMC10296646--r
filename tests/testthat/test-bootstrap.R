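test_that("tissue homogenization removes sample structure and round-trips", {
  ones <- spectra_tensor(array(1, c(2, 2, 2, 3)), "X")
  hom <- tissue_homogenize(ones, rep(1, 2))
  expect_equal(tensor_values(hom$chi), array(1, c(2, 2, 2, 3)))
  expect_equal(tensor_values(hom$psi), array(1, c(2, 2, 2, 3)))
  expect_equal(hom$beta_nk, matrix(1, 2, 3))

  # sample-amplitude-only data: psi is exactly 1
  Bn <- c(1.4, 0.6)
  v <- array(0, c(2, 1, 2, 3))
  v[1, , , ] <- Bn[1]; v[2, , , ] <- Bn[2]
  hom2 <- tissue_homogenize(spectra_tensor(v, "X"), Bn)
  expect_equal(tensor_values(hom2$psi), array(1, c(2, 1, 2, 3)), tolerance = 1e-12)

  X <- random_tensor(N = 3, M = 2, R = 2, K = 4)
  Bn3 <- c(0.9, 1.0, 1.1)
  hom3 <- tissue_homogenize(X, Bn3)
  expect_equal(colMeans(hom3$beta_nk), rep(1, 4), tolerance = 1e-12)
  back <- aperm(aperm(tensor_values(hom3$psi), c(1, 4, 2, 3)) * c(hom3$beta_nk),
                c(1, 3, 4, 2)) * c(Bn3)
  expect_equal(back, tensor_values(X), tolerance = 1e-12)
})

test_that("exhaustive subsets enumerate C(N, Nfit) distinct sets in order", {
  subs <- enumerate_fit_subsets(8, 5)
  expect_length(subs, 56L)
  expect_equal(length(unique(lapply(subs, paste, collapse = ","))), 56L)
  expect_equal(subs[[1]], 1:5)
  expect_equal(subs[[56]], 4:8)

  expect_equal(enumerate_fit_subsets(2, 1), list(1L, 2L))

  for (N in 4:10) for (Nf in 1:(N - 1)) {
    expect_length(enumerate_fit_subsets(N, Nf), oracle_choose(N, Nf))
  }

  r1 <- enumerate_fit_subsets(10, 4, mode = "random", iterations = 7, seed = 5)
  r2 <- enumerate_fit_subsets(10, 4, mode = "random", iterations = 7, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(vapply(r1, length, 0L) == 4L))

  expect_error(enumerate_fit_subsets(4, 4), "Nfit < N")
})

test_that("bootstrap iterations recover planted microscope factors", {
  # trivial data: unit factors and zero residual everywhere
  psi1 <- spectra_tensor(array(1, c(4, 2, 2, 3)), "psi")
  a1 <- structure(array(1, c(4, 2, 2)), class = c("amplitude_table", "array"))
  it1 <- bootstrap_iteration(psi1, a1, 1:2)
  expect_equal(it1$Cms, rep(1, 2))
  expect_equal(it1$omega_mks, matrix(1, 2, 3))
  expect_equal(it1$fit_std$mean_std, 0)
  expect_equal(it1$test_std$mean_std, 0)

  # planted noiseless profiles: every subset recovers the same factors and
  # held-out samples correct to zero residual
  set.seed(71)
  N <- 6; M <- 3; R <- 2; K <- 4
  wmk <- matrix(exp(rnorm(M * K, 0, 0.15)), M, K)
  wmk <- sweep(wmk, 2, colMeans(wmk), "/")      # per-layer microscope mean 1
  v <- array(0, c(N, M, R, K))
  for (n in 1:N) for (m in 1:M) for (r in 1:R) v[n, m, r, ] <- wmk[m, ]
  psi <- spectra_tensor(v, "psi")
  amps <- structure(array(1, c(N, M, R)), class = c("amplitude_table", "array"))
  subs <- enumerate_fit_subsets(N, 3)
  iters <- lapply(subs, function(s) bootstrap_iteration(psi, amps, s))
  omegas <- lapply(iters, function(it) it$omega_mks)
  spread <- max(vapply(omegas, function(o) max(abs(o - omegas[[1]])), 0))
  expect_lt(spread, 1e-12)
  expect_equal(iters[[1]]$omega_mks, wmk, tolerance = 1e-12)
  expect_lt(max(vapply(iters, function(it) it$test_std$mean_std, 0)), 1e-12)

  # correction round trip on arbitrary spectra
  psr <- random_tensor(N = 4, M = 2, R = 2, K = 3, stage = "psi")
  ar <- amplitude_summary(psr)
  it <- bootstrap_iteration(psr, ar, c(1, 3))
  back <- aperm(aperm(tensor_values(it$z), c(2, 4, 1, 3)) *
                  c(it$Cms * it$omega_mks), c(3, 1, 4, 2))
  expect_equal(back, tensor_values(psr), tolerance = 1e-12)
  expect_equal(it$test_set, c(2L, 4L))
})

test_that("bootstrap aggregation summarizes iteration records", {
  mk_iter <- function(fit_pct, test_pct, C, om) {
    structure(list(fit_set = 1:2, test_set = 3:4, Cms = C, omega_mks = om,
                   fit_std = list(mean_std_pct = fit_pct),
                   test_std = list(mean_std_pct = test_pct)),
              class = "bootstrap_iteration")
  }
  om <- matrix(1, 2, 3)
  same <- aggregate_bootstrap(list(mk_iter(2, 3, c(1, 1), om),
                                   mk_iter(2, 3, c(1, 1), om)))
  expect_equal(same$fit_std_of_std, 0)
  expect_equal(same$test_std_of_std, 0)

  two <- aggregate_bootstrap(list(mk_iter(1, 2, c(0.9, 1.1), om),
                                  mk_iter(3, 4, c(1.1, 0.9), om * 2)))
  expect_equal(two$test_mean_std, 3)
  expect_equal(two$test_std_of_std, sqrt(2))
  expect_equal(two$fit_mean_std, 2)
  expect_equal(two$Cm_mean, c(1, 1))
  expect_equal(two$omega_mk_mean, om * 1.5)
  expect_equal(two$factor_product_mean,
               (c(0.9, 1.1) * om + c(1.1, 0.9) * 2 * om) / 2)
})

test_that("an exhaustive run is recomputable from its records", {
  pipe <- recovery_pipeline()
  boot <- run_bootstrap(pipe$sp$X, Nfit = 5)
  expect_equal(boot$n_iter, 56L)
  fit_vals <- vapply(boot$iterations, function(it) it$fit_std$mean_std_pct, 0)
  expect_equal(boot$fit_mean_std, mean(fit_vals), tolerance = 1e-12)
  expect_equal(boot$fit_std_of_std, sd(fit_vals), tolerance = 1e-12)
  om_sum <- Reduce(`+`, lapply(boot$iterations, function(it) it$omega_mks))
  expect_equal(boot$omega_mk_mean, om_sum / 56, tolerance = 1e-12)
  # per-layer microscope mean of omega on the fit set is 1 by construction
  for (it in boot$iterations[c(1, 30, 56)]) {
    sub <- unclass(attr(boot, "homogenized")$psi)[it$fit_set, , , , drop = FALSE]
    denom <- apply(sub, 4, mean)
    num <- apply(sub, c(2, 4), mean)
    expect_equal(sweep(num, 2, denom, "/"), it$omega_mks, tolerance = 1e-12)
    expect_equal(colMeans(it$omega_mks), rep(1, ncol(it$omega_mks)),
                 tolerance = 1e-9)
  }
})

test_that("subset-to-subset factor spread collapses on noiseless image data", {
  pipe <- recovery_pipeline()
  boot_noisy <- run_bootstrap(pipe$sp$X, Nfit = 5)
  cfg0 <- simulation_config(noise_cv = 0, scan_jitter_cv = 0, sat_frac = 0,
                            background_flux = 0, quantize = FALSE)
  ds0 <- simulate_dataset(cfg0, seed = 1)
  boot0 <- run_bootstrap(normalized_spectra(ds0)$X, Nfit = 5)
  om0 <- lapply(boot0$iterations, function(it) it$omega_mks)
  spread0 <- max(vapply(om0, function(o) max(abs(o - om0[[1]])), 0))
  omn <- lapply(boot_noisy$iterations, function(it) it$omega_mks)
  spread_n <- max(vapply(omn, function(o) max(abs(o - omn[[1]])), 0))
  expect_lt(spread0, 1e-10)
  expect_gt(spread_n, spread0)
})

test_that("the test-over-fit residual margin shrinks with the noise level", {
  # planted microscope profiles with unit amplitudes, so the residual is
  # purely noise-driven: held-out samples must do slightly worse than the
  # fit samples, with the margin vanishing as the noise vanishes
  margins <- vapply(c(0.02, 0.005, 0), function(sigma) {
    set.seed(73)
    N <- 8; M <- 3; R <- 2; K <- 6
    wmk <- matrix(exp(rnorm(M * K, 0, 0.15)), M, K)
    wmk <- sweep(wmk, 2, colMeans(wmk), "/")
    v <- array(0, c(N, M, R, K))
    for (n in 1:N) for (m in 1:M) for (r in 1:R) v[n, m, r, ] <- wmk[m, ]
    v <- v * (1 + sigma * rnorm(length(v)))
    psi <- spectra_tensor(v, "psi")
    amps <- structure(array(1, c(N, M, R)),
                      class = c("amplitude_table", "array"))
    iters <- lapply(enumerate_fit_subsets(N, 5),
                    function(s) bootstrap_iteration(psi, amps, s))
    agg <- aggregate_bootstrap(iters)
    agg$test_mean_std - agg$fit_mean_std
  }, 0)
  expect_true(all(diff(margins) < 0))
  expect_gt(margins[1], 0)
  expect_lt(abs(margins[3]), 1e-10)
})
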