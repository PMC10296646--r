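test_that("amplitude factors are row and column means of the amplitude table", {
  a <- structure(array(1, c(3, 2, 2)), class = c("amplitude_table", "array"))
  f <- fit_amplitude_factors(a)
  expect_equal(f$Bn, rep(1, 3))
  expect_equal(f$Cm, rep(1, 2))

  a2 <- structure(array(c(1.2, 1.1, 0.8, 0.9), c(2, 2, 1)),
                  class = c("amplitude_table", "array"))
  f2 <- fit_amplitude_factors(a2)
  expect_equal(f2$Bn, c(1.0, 1.0))
  expect_equal(f2$Cm, c(1.15, 0.85))

  # table depending only on n -> microscope factors exactly 1
  a3 <- structure(array(rep(c(0.7, 1.3), 4), c(2, 2, 2)),
                  class = c("amplitude_table", "array"))
  expect_equal(fit_amplitude_factors(a3)$Cm, c(1, 1))

  a_bad <- a2; a_bad[2, 1, 1] <- NA
  expect_error(fit_amplitude_factors(a_bad), "n=2, m=1, r=1")
})

test_that("amplitude correction divides by the factor product and round-trips", {
  X <- random_tensor(N = 3, M = 2, R = 2, K = 4)
  ident <- apply_amplitude(X, list(Bn = rep(1, 3), Cm = rep(1, 2)))
  expect_equal(tensor_values(ident), tensor_values(X))

  f <- list(Bn = c(0.8, 1.0, 1.2), Cm = c(1.1, 0.9))
  x <- apply_amplitude(X, f)
  back <- tensor_values(x) * c(outer(f$Bn, f$Cm))
  expect_equal(back, tensor_values(X), tolerance = 1e-12)

  # gauge freedom: only the product Bn*Cm matters
  g <- list(Bn = f$Bn * 3, Cm = f$Cm / 3)
  expect_equal(tensor_values(apply_amplitude(X, g)), tensor_values(x), tolerance = 1e-12)

  expect_error(apply_amplitude(X, list(Bn = c(1, -1, 1), Cm = f$Cm)),
               "positive")
})

test_that("tissue and microscope profiles normalize to mean 1 per layer and round-trip", {
  x <- random_tensor(N = 4, M = 3, R = 2, K = 5, stage = "x")
  ft <- fit_tissue_profile(x)
  expect_equal(colMeans(ft$bnk), rep(1, 5), tolerance = 1e-12)
  y <- apply_tissue_profile(x, ft)
  yp <- aperm(tensor_values(y), c(1, 4, 2, 3)) * c(ft$bnk)
  expect_equal(aperm(yp, c(1, 3, 4, 2)), tensor_values(x), tolerance = 1e-12)

  fm <- fit_microscope_profile(y)
  expect_equal(colMeans(fm$wmk), rep(1, 5), tolerance = 1e-12)
  z <- apply_microscope_profile(y, fm)
  zp <- aperm(tensor_values(z), c(2, 4, 1, 3)) * c(fm$wmk)
  expect_equal(aperm(zp, c(3, 1, 4, 2)), tensor_values(y), tolerance = 1e-12)

  # two-sample symmetric case: bnk equals the planted ratios
  v <- array(1, c(2, 2, 1, 3)); v[1, , , ] <- 1.2; v[2, , , ] <- 0.8
  ft2 <- fit_tissue_profile(spectra_tensor(v, "x"))
  expect_equal(ft2$bnk[, 1], c(1.2, 0.8))

  # microscope mean-1 case: wmk equals the planted values
  v3 <- array(1, c(2, 3, 1, 2))
  v3[, 1, , ] <- 1.2; v3[, 2, , ] <- 1.0; v3[, 3, , ] <- 0.8
  fm3 <- fit_microscope_profile(spectra_tensor(v3, "y"))
  expect_equal(fm3$wmk[, 1], c(1.2, 1.0, 0.8))
})

test_that("refitting on corrected spectra returns unit factors", {
  # exact multiplicative data: the sequential chain reduces z to a purely
  # layer-dependent profile, so a second pass finds nothing left to correct
  set.seed(67)
  N <- 4; M <- 3; R <- 2; K <- 5
  P <- array(0, c(N, M, R, K))
  An <- exp(rnorm(N, 0, 0.2)); gm <- exp(rnorm(M, 0, 0.1))
  tnk <- matrix(exp(rnorm(N * K, 0, 0.1)), N, K)
  wmk <- matrix(exp(rnorm(M * K, 0, 0.1)), M, K)
  for (n in 1:N) for (m in 1:M) for (r in 1:R) {
    P[n, m, r, ] <- An[n] * gm[m] * tnk[n, ] * wmk[m, ]
  }
  fit <- fit_calibration(grand_normalize(spectra_tensor(P, "Xtilde")))
  refit <- fit_calibration(spectra_tensor(unclass(fit$z), "X"))
  expect_equal(refit$amplitude$Bn, rep(1, 4), tolerance = 1e-9)
  expect_equal(refit$amplitude$Cm, rep(1, 3), tolerance = 1e-9)
  expect_equal(refit$tissue$bnk, matrix(1, 4, 5), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(refit$microscope$wmk, matrix(1, 3, 5), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("factors are recovered from tensor-level multiplicative data with noise", {
  set.seed(7)
  N <- 8; M <- 3; R <- 2; K <- 12
  Bn <- exp(rnorm(N, 0, 0.2)); Cm <- exp(rnorm(M, 0, 0.1))
  bnk <- matrix(exp(rnorm(N * K, 0, 0.1)), N, K)
  wmk <- matrix(exp(rnorm(M * K, 0, 0.1)), M, K)
  sigma <- 0.01
  P <- array(0, c(N, M, R, K))
  for (n in 1:N) for (m in 1:M) for (r in 1:R) {
    P[n, m, r, ] <- Bn[n] * Cm[m] * bnk[n, ] * wmk[m, ]
  }
  truth <- fit_calibration(grand_normalize(spectra_tensor(P, "Xtilde")))
  noisy <- P * (1 + sigma * rnorm(length(P)))
  fit <- fit_calibration(grand_normalize(spectra_tensor(noisy, "Xtilde")))
  expect_lt(max(abs(fit$amplitude$Bn - truth$amplitude$Bn)),
            3 * sigma / sqrt(M * R * K))
  expect_lt(max(abs(fit$amplitude$Cm - truth$amplitude$Cm)),
            3 * sigma / sqrt(N * R * K))
  expect_lt(max(abs(fit$tissue$bnk - truth$tissue$bnk)),
            3 * sigma / sqrt(M * R))
  expect_lt(max(abs(fit$microscope$wmk - truth$microscope$wmk)),
            3 * sigma / sqrt(N * R))

  # sequential variance reduction is strict on data with nontrivial factors
  stds <- vapply(fit[c("X", "x", "y", "z")],
                 function(s) layer_std(s)$mean_std, 0)
  expect_true(all(diff(stds) < 0))
})

test_that("microscope profile decomposition reconstructs wmk exactly", {
  lay <- filter_layout(list(g1 = 1:2, g2 = 3:4))
  prof <- list(wmk = matrix(c(1.2, 1.2, 0.8, 0.8), 1, 4), Pmk = NULL)
  dec <- decompose_microscope_profile(prof, lay)
  expect_equal(dec$wmill, 1.0)
  expect_equal(dec$wmkBB[1, ], c(1.2, 1.2, 0.8, 0.8))
  expect_equal(dec$wmkNB[1, ], rep(1, 4))

  const <- list(wmk = matrix(3, 2, 4))
  dc <- decompose_microscope_profile(const, lay)
  expect_equal(dc$wmill, c(3, 3))
  expect_equal(dc$wmkBB, matrix(1, 2, 4))
  expect_equal(dc$wmkNB, matrix(1, 2, 4))

  set.seed(77)
  lay2 <- default_filter_layout(K = 14, n_groups = 4)
  for (i in 1:100) {
    wmk <- matrix(exp(rnorm(3 * 14, 0, 0.2)), 3, 14)
    d <- decompose_microscope_profile(list(wmk = wmk), lay2)
    recon <- d$wmill * d$wmkBB * d$wmkNB
    expect_equal(recon, wmk, tolerance = 1e-12)
    for (g in lay2$groups) {
      # broadband part constant within each group, narrowband mean 1 within it
      expect_equal(apply(d$wmkBB[, g, drop = FALSE], 1, function(r) max(r) - min(r)),
                   rep(0, 3))
      expect_equal(rowMeans(d$wmkNB[, g, drop = FALSE]), rep(1, 3),
                   tolerance = 1e-9)
    }
  }
})
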