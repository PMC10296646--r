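#' Read and write high-power-field (HPF) image stacks
#'
#' An HPF is one tiled field of view from a whole-slide multispectral scan:
#' an H x W x K stack of unsigned 16-bit pixel counts, one page per
#' narrowband layer. Stacks are stored as multi-page grayscale TIFF with the
#' page order defining the layer order.
#'
#' @param pixels Integer array with dimensions H x W x K, counts in
#'   0..65535.
#' @param path File path for the TIFF.
#' @return `write_hpf()` returns `path` invisibly; `read_hpf()` returns the
#'   integer pixel array.
#' @export
write_hpf <- function(pixels, path) {
  d <- dim(pixels)
  if (length(d) != 3L) stopf("HPF pixels must be an H x W x K array")
  if (any(pixels < 0 | pixels > 65535)) stopf("HPF counts must lie in 0..65535")
  pages <- lapply(seq_len(d[3]), function(k) pixels[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_hpf
#' @export
read_hpf <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  storage.mode(arr) <- "integer"
  arr
}

#' Write and read real-valued image stacks
#'
#' Corrected (standardized) stacks are real-valued. They are stored as
#' 32-bit float TIFF pages scaled into [0, 1], with the scale factor
#' recorded in a small YAML sidecar (`<path>.yaml`) so values round-trip to
#' float precision.
#'
#' @param values Numeric H x W x K array, finite and non-negative.
#' @param path File path for the TIFF; the sidecar is written next to it.
#' @return `write_float_stack()` returns `path` invisibly;
#'   `read_float_stack()` returns the numeric array.
#' @export
write_float_stack <- function(values, path) {
  d <- dim(values)
  if (length(d) != 3L) stopf("stack must be an H x W x K array")
  if (any(!is.finite(values)) || any(values < 0)) {
    stopf("stack values must be finite and non-negative")
  }
  scale <- max(values, 1e-12)
  pages <- lapply(seq_len(d[3]), function(k) values[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  yaml::write_yaml(list(scale = scale, layers = d[3]), paste0(path, ".yaml"),
                   precision = 15L)
  invisible(path)
}

#' @rdname write_float_stack
#' @export
read_float_stack <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr * meta$scale
}

#' Convert raw counts to flux by exposure normalization
#'
#' Divides each layer's counts by the exposure time (in milliseconds) of the
#' broadband group the layer belongs to, yielding flux in counts/ms.
#' Exposure is set per broadband filter during acquisition (the scanner
#' auto-exposes each broadband cube), so one exposure value is broadcast to
#' all member layers of a group.
#'
#' @param pixels Numeric or integer H x W x K array of counts.
#' @param exposures Named numeric vector of exposure times in ms, one entry
#'   per broadband group name; all strictly positive.
#' @param layout A `filter_layout` for the stack.
#' @return Numeric H x W x K array of flux values (counts/ms).
#' @export
exposure_normalize <- function(pixels, exposures, layout) {
  layout <- validate_layout(layout)
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != layout$K) {
    stopf("pixel stack has %s layers, layout expects %d",
          if (length(d) == 3L) d[3] else "?", layout$K)
  }
  missing <- setdiff(names(layout$groups), names(exposures))
  if (length(missing) > 0L) {
    stopf("missing exposure entry for group '%s'", missing[1])
  }
  ex <- as.numeric(exposures[names(layout$groups)])
  if (any(!is.finite(ex)) || any(ex <= 0)) {
    stopf("exposure times must be finite and > 0")
  }
  per_layer <- ex[layout$group_of]
  flux <- array(as.numeric(pixels), dim = d)
  flux <- sweep(flux, 3L, per_layer, "/")
  flux
}

.scan_label <- function(scan) {
  sprintf("%s/%s/scan%d", scan$sample_id, scan$microscope_id, scan$r)
}

.get_hpf <- function(scan, h) {
  if (!is.null(scan$hpfs)) return(scan$hpfs[[h]])
  read_hpf(scan$hpf_files[[h]])
}

#' Assemble an in-memory multi-scan dataset
#'
#' @param scans List of scan records; each a list with 1-based indices `n`
#'   (sample), `m` (microscope), `r` (scan repeat), ids `sample_id` and
#'   `microscope_id`, a named `exposures` vector (ms per broadband group),
#'   and either `hpfs` (list of pixel arrays) or `hpf_files` (paths).
#' @param layout A `filter_layout`.
#' @param samples,microscopes Character vectors of sample / microscope ids.
#' @param n_scan_reps Number of scan repeats per (sample, microscope).
#' @param H,W Tile pixel dimensions.
#' @param truth Optional ground-truth model (simulated data only).
#' @return An object of class `mif_dataset`.
#' @export
mif_dataset <- function(scans, layout, samples, microscopes, n_scan_reps,
                        H, W, truth = NULL) {
  keys <- vapply(scans, function(s) sprintf("%d|%d|%d", s$n, s$m, s$r), "")
  if (anyDuplicated(keys)) stopf("duplicate (sample, microscope, scan) record")
  for (s in scans) {
    s$n_hpf <- s$n_hpf %||% length(s$hpfs %||% s$hpf_files)
  }
  structure(
    list(scans = scans, layout = validate_layout(layout),
         samples = samples, microscopes = microscopes,
         n_scan_reps = as.integer(n_scan_reps),
         H = as.integer(H), W = as.integer(W), truth = truth),
    class = "mif_dataset"
  )
}

#' @export
print.mif_dataset <- function(x, ...) {
  cat(sprintf(
    "mif_dataset: %d samples x %d microscopes x %d scans (%d scan records)\n",
    length(x$samples), length(x$microscopes), x$n_scan_reps, length(x$scans)))
  cat(sprintf("  tiles: %d x %d pixels, %d layers in %d broadband groups\n",
              x$H, x$W, x$layout$K, length(x$layout$groups)))
  cat(sprintf("  HPFs per scan: %s\n",
              paste(range(vapply(x$scans, function(s) s$n_hpf, 0L)),
                    collapse = "-")))
  invisible(x)
}

#' Write a dataset to disk as TIFF tiles plus a YAML manifest
#'
#' @param dataset A `mif_dataset` with in-memory pixel stacks.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scans_meta <- list()
  for (si in seq_along(dataset$scans)) {
    scan <- dataset$scans[[si]]
    sub <- sprintf("%s__%s__scan%d", scan$sample_id, scan$microscope_id, scan$r)
    scan_dir <- file.path(dir, sub)
    dir.create(scan_dir, showWarnings = FALSE)
    n_hpf <- length(scan$hpfs)
    for (h in seq_len(n_hpf)) {
      write_hpf(scan$hpfs[[h]], file.path(scan_dir, sprintf("hpf_%04d.tif", h)))
    }
    scans_meta[[si]] <- list(
      sample_id = scan$sample_id, microscope_id = scan$microscope_id,
      scan = scan$r, dir = sub, n_hpf = n_hpf,
      exposures = as.list(scan$exposures)
    )
  }
  manifest <- list(
    H = dataset$H, W = dataset$W, K = dataset$layout$K,
    samples = as.list(dataset$samples),
    microscopes = as.list(dataset$microscopes),
    n_scan_reps = dataset$n_scan_reps,
    layout = lapply(dataset$layout$groups, as.list),
    scans = scans_meta
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path, precision = 15L)
  invisible(path)
}

#' Read a dataset manifest
#'
#' Parses the YAML manifest written by [write_dataset()] (or assembled by
#' hand for real scans), validates the filter layout, checks that every scan
#' directory resolves, that the recorded HPF count matches the TIFF files
#' found, and that an exposure entry exists for every (scan, broadband
#' group) pair. Pixel data are left on disk; scans carry `hpf_files` paths
#' that downstream operations read one tile at a time.
#'
#' @param path Path to `manifest.yaml` (or its directory).
#' @return A `mif_dataset` whose scans reference TIFF files.
#' @export
read_dataset_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.yaml")
  if (!file.exists(path)) stopf("manifest error: '%s' not found", path)
  man <- yaml::read_yaml(path)
  root <- dirname(path)
  layout <- filter_layout(lapply(man$layout, function(g) as.integer(unlist(g))),
                          K = man$K)
  samples <- as.character(unlist(man$samples))
  microscopes <- as.character(unlist(man$microscopes))
  scans <- vector("list", length(man$scans))
  for (si in seq_along(man$scans)) {
    sm <- man$scans[[si]]
    scan_dir <- file.path(root, sm$dir)
    if (!dir.exists(scan_dir)) {
      stopf("manifest error: scan directory '%s' not found", sm$dir)
    }
    files <- sort(list.files(scan_dir, pattern = "\\.tiff?$", full.names = TRUE))
    if (length(files) != sm$n_hpf) {
      stopf("manifest error: scan %s/%s/scan%d lists %d HPFs but %d files found",
            sm$sample_id, sm$microscope_id, sm$scan, sm$n_hpf, length(files))
    }
    if (length(files) == 0L) {
      warnf("scan %s/%s/scan%d has no HPFs", sm$sample_id, sm$microscope_id,
            sm$scan)
    }
    ex <- unlist(sm$exposures)
    missing <- setdiff(names(layout$groups), names(ex))
    if (length(missing) > 0L) {
      stopf("manifest error: missing exposure for scan %s/%s/scan%d group '%s'",
            sm$sample_id, sm$microscope_id, sm$scan, missing[1])
    }
    if (any(ex[names(layout$groups)] <= 0)) {
      stopf("manifest error: nonpositive exposure in scan %s/%s/scan%d",
            sm$sample_id, sm$microscope_id, sm$scan)
    }
    n <- match(sm$sample_id, samples)
    m <- match(sm$microscope_id, microscopes)
    if (is.na(n) || is.na(m)) {
      stopf("manifest error: scan %d references unknown sample or microscope", si)
    }
    scans[[si]] <- list(
      n = n, m = m, r = as.integer(sm$scan),
      sample_id = sm$sample_id, microscope_id = sm$microscope_id,
      exposures = ex, hpf_files = files, n_hpf = length(files)
    )
  }
  mif_dataset(scans, layout, samples, microscopes,
              n_scan_reps = man$n_scan_reps, H = man$H, W = man$W)
}
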