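# Shared simulated datasets, built once per test session. Seeds are fixed
# study conditions, not tuned per test.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# paper-analogue study conditions: N=8 samples x M=3 microscopes x R=2
# scans, K=12 layers in 3 broadband groups, 64x64 tiles, 4 tiles/scan,
# broadband offsets up to +/-20%, 1% pixel noise
recovery_dataset <- function() {
  cached_fixture("recovery_ds", simulate_dataset(simulation_config(), seed = 1L))
}

recovery_pipeline <- function() {
  cached_fixture("recovery_pipe", {
    ds <- recovery_dataset()
    sp <- normalized_spectra(ds)
    fit <- fit_calibration(sp$X, layout = ds$layout)
    list(ds = ds, sp = sp, fit = fit, truth = gauge_fix_truth(ds$truth))
  })
}

# component-mode dataset for unmixing scenarios, 32x32 tiles
scenario_dataset <- function() {
  cached_fixture("scenario_ds",
                 simulate_dataset(simulation_config(H = 32L, W = 32L,
                                                    Kprime = 5L), seed = 1L))
}

# small tensor of positive random spectra for operator-level tests
random_tensor <- function(N = 2, M = 2, R = 2, K = 3, seed = 99,
                          stage = "X") {
  set.seed(seed)
  spectra_tensor(array(runif(N * M * R * K, 0.5, 1.5), c(N, M, R, K)), stage)
}

# plain numeric array from a spectra_tensor (drops class/stage attributes)
tensor_values <- function(x) {
  a <- unclass(x)
  attr(a, "stage") <- NULL
  a
}

flat_truth <- function(config) {
  structure(
    list(An = rep(1, config$N), gm = rep(1, config$M),
         tnk = matrix(1, config$N, config$K),
         wmk = matrix(1, config$M, config$K),
         bb = matrix(1, config$M, length(config$layout$groups)),
         nb = matrix(1, config$M, config$K),
         ref_library = NULL, comp = NULL),
    class = "truth_model"
  )
}
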