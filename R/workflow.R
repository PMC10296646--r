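.run_id <- function(...) {
  # short deterministic id from the run parameters (FNV-1a over the
  # deparsed arguments), stamped into every exported table
  s <- paste(vapply(list(...), function(x) paste(deparse(x), collapse = ""), ""),
             collapse = "|")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full calibration workflow on a dataset
#'
#' End-to-end orchestration: masking and spectra reduction, the sequential
#' calibration fit (amplitude, tissue profile, microscope profile) with
#' the broadband/narrowband decomposition, residual layer-std reports at
#' every stage, layer-projected covariance matrices, the exhaustive subset
#' bootstrap of the microscope factors, reference standardization factors,
#' and (when libraries are supplied) the three-scenario unmixing
#' comparison. The run is deterministic given the dataset and
#' configuration.
#'
#' @param dataset A `mif_dataset`.
#' @param ref_m Reference microscope index (default 2, the middle scope of
#'   a three-scope setup).
#' @param Nfit Bootstrap fit-subset size (default 5).
#' @param bootstrap_mode,bootstrap_iterations,bootstrap_seed Passed to
#'   [run_bootstrap()].
#' @param libraries Optional per-microscope `spectral_library` list for
#'   the unmixing comparison.
#' @param thresholds,otsu_source,masks Masking options (see
#'   [compute_tissue_mask()]).
#' @param out_dir Optional directory: when given, all result tables are
#'   exported as CSV ([export_run()]).
#' @return A list of class `mif_run` with elements `spectra` (X, amps,
#'   hmrn, qc), `fit` (`calibration_fit`), `stds` (data.frame of
#'   layer-averaged stds per stage, in correction order), `layer_stds`
#'   (named list of `layer_std_report`s), `covariances`, `bootstrap`,
#'   `std_factors`, `scenarios` (or NULL), `run_id`.
#' @export
run_full_calibration <- function(dataset, ref_m = 2L, Nfit = 5L,
                                 bootstrap_mode = "exhaustive",
                                 bootstrap_iterations = 100L,
                                 bootstrap_seed = 1L,
                                 libraries = NULL, thresholds = NULL,
                                 otsu_source = "mean",
                                 masks = c("otsu", "none"),
                                 out_dir = NULL) {
  masks <- match.arg(masks)
  run_id <- .run_id(length(dataset$samples), length(dataset$microscopes),
                    dataset$n_scan_reps, dataset$layout$groups, ref_m, Nfit,
                    bootstrap_mode, bootstrap_iterations, bootstrap_seed,
                    thresholds, otsu_source, masks)
  sp <- normalized_spectra(dataset, thresholds, otsu_source, masks)
  fit <- fit_calibration(sp$X, layout = dataset$layout)
  stages <- list(X = fit$X, x = fit$x, y = fit$y, z = fit$z)
  layer_stds <- lapply(stages, layer_std)
  covariances <- lapply(stages, covariance_matrix)
  boot <- run_bootstrap(sp$X, Nfit = Nfit, mode = bootstrap_mode,
                        iterations = bootstrap_iterations, seed = bootstrap_seed)
  hom <- attr(boot, "homogenized")
  layer_stds$psi <- layer_std(hom$psi)
  std_factors <- reference_standardization_factors(
    boot, ref_m, microscope_ids = dataset$microscopes)
  scenarios <- if (!is.null(libraries)) {
    scenario_compare(dataset, libraries, std_factors, ref_m,
                     thresholds = thresholds, otsu_source = otsu_source,
                     masks = masks)
  } else NULL
  stds <- data.frame(
    stage = c("X", "x", "y", "z", "psi", "z_fit", "z_test"),
    mean_std_pct = c(vapply(layer_stds[c("X", "x", "y", "z", "psi")],
                            function(r) r$mean_std_pct, 0),
                     boot$fit_mean_std, boot$test_mean_std)
  )
  run <- structure(
    list(spectra = sp, fit = fit, stds = stds, layer_stds = layer_stds,
         covariances = covariances, bootstrap = boot,
         std_factors = std_factors, scenarios = scenarios, run_id = run_id),
    class = "mif_run"
  )
  if (!is.null(out_dir)) export_run(run, out_dir, dataset)
  run
}

#' @export
print.mif_run <- function(x, ...) {
  cat(sprintf("mif_run %s\n", x$run_id))
  cat("layer-averaged residual std by stage:\n")
  for (i in seq_len(nrow(x$stds))) {
    cat(sprintf("  %-6s %6.2f %%\n", x$stds$stage[i], x$stds$mean_std_pct[i]))
  }
  if (!is.null(x$scenarios)) {
    cat("unmixing scenarios (autofluorescence excluded):\n")
    t <- x$scenarios$table
    for (i in seq_len(nrow(t))) {
      cat(sprintf("  %s %6.2f %%\n", t$scenario[i], t$mean_std_pct[i]))
    }
  }
  invisible(x)
}

#' Export a calibration run as CSV tables
#'
#' Writes the factor tables, per-stage std reports, covariance matrices,
#' bootstrap summary and scenario table to `dir`, each row carrying the
#' run id. Deterministic: re-running the same configuration reproduces
#' byte-identical files.
#'
#' @param run A `mif_run`.
#' @param dir Output directory.
#' @param dataset The dataset the run came from (for ids).
#' @return `dir`, invisibly.
#' @export
export_run <- function(run, dir, dataset) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- run$run_id
  w <- function(df, name) {
    df$run_id <- id
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  fit <- run$fit
  N <- length(dataset$samples); M <- length(dataset$microscopes)
  K <- dataset$layout$K
  w(data.frame(sample_id = dataset$samples, B = fit$amplitude$Bn),
    "factors_sample_amplitude.csv")
  w(data.frame(microscope_id = dataset$microscopes, C = fit$amplitude$Cm),
    "factors_microscope_amplitude.csv")
  w(data.frame(sample_id = rep(dataset$samples, K),
               layer = rep(seq_len(K), each = N),
               b = as.vector(fit$tissue$bnk)),
    "factors_tissue_profile.csv")
  dec <- fit$decomposition
  w(data.frame(microscope_id = rep(dataset$microscopes, K),
               layer = rep(seq_len(K), each = M),
               w = as.vector(fit$microscope$wmk),
               w_ill = rep(dec$wmill, K),
               w_BB = as.vector(dec$wmkBB),
               w_NB = as.vector(dec$wmkNB)),
    "factors_microscope_profile.csv")
  sig <- do.call(rbind, lapply(names(run$layer_stds), function(st) {
    r <- run$layer_stds[[st]]
    data.frame(stage = st, layer = seq_along(r$sigma_k),
               sigma_pct = 100 * r$sigma_k)
  }))
  w(sig, "layer_stds.csv")
  w(run$stds, "stage_stds.csv")
  boot <- run$bootstrap
  w(data.frame(
    iteration = rep(seq_len(boot$n_iter),
                    vapply(boot$iterations, function(it) length(it$fit_set), 0L)),
    fit_sample = unlist(lapply(boot$iterations, function(it) it$fit_set))),
    "bootstrap_subsets.csv")
  w(data.frame(microscope_id = rep(dataset$microscopes, K),
               layer = rep(seq_len(K), each = M),
               omega_mean = as.vector(boot$omega_mk_mean),
               C_mean = rep(boot$Cm_mean, K)),
    "bootstrap_factors.csv")
  w(data.frame(set = c("fit", "test"),
               mean_std_pct = c(boot$fit_mean_std, boot$test_mean_std),
               std_of_std_pct = c(boot$fit_std_of_std, boot$test_std_of_std)),
    "bootstrap_summary.csv")
  w(data.frame(microscope_id = rep(dataset$microscopes, K),
               layer = rep(seq_len(K), each = M),
               factor = as.vector(run$std_factors$factors),
               reference_id = dataset$microscopes[run$std_factors$ref_m]),
    "standardization_factors.csv")
  if (!is.null(run$scenarios)) w(run$scenarios$table, "scenario_stds.csv")
  if (!is.null(run$spectra$qc)) w(run$spectra$qc, "mask_qc.csv")
  invisible(dir)
}
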