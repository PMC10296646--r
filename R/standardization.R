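#' Standardization factors relative to a reference microscope
#'
#' Converts bootstrap-aggregated microscope factors into per-(microscope,
#' layer) standardization factors: the product of the mean `C_m` and mean
#' `omega_mk` factors, divided by the same product for the chosen
#' reference microscope, so that the reference microscope's factors are
#' exactly 1 and its data pass through unaltered.
#'
#' @param summary A `bootstrap_summary`.
#' @param ref_m Index (or id, when `microscope_ids` given) of the
#'   reference microscope.
#' @param microscope_ids Optional character vector naming the microscopes.
#' @param aggregation `"product_of_means"` (default): mean C times mean
#'   omega; `"mean_of_products"`: the mean over iterations of the
#'   per-iteration products.
#' @return A list of class `standardization_factors`: `factors` (M x K),
#'   `ref_m`, `microscope_ids`.
#' @export
reference_standardization_factors <- function(summary, ref_m,
                                              microscope_ids = NULL,
                                              aggregation = c("product_of_means",
                                                              "mean_of_products")) {
  aggregation <- match.arg(aggregation)
  prod_mk <- switch(aggregation,
    product_of_means = summary$Cm_mean * summary$omega_mk_mean,
    mean_of_products = summary$factor_product_mean
  )
  M <- nrow(prod_mk)
  if (!is.null(microscope_ids) && is.character(ref_m)) {
    ref_m <- match(ref_m, microscope_ids)
  }
  if (is.na(ref_m) || ref_m < 1 || ref_m > M) stopf("invalid reference microscope")
  ref_row <- prod_mk[ref_m, ]
  if (any(ref_row == 0)) stopf("zero reference factor")
  factors <- sweep(prod_mk, 2, ref_row, "/")
  factors[ref_m, ] <- 1
  if (any(factors <= 0)) stopf("standardization factors must be positive")
  structure(list(factors = factors, ref_m = ref_m,
                 microscope_ids = microscope_ids),
            class = "standardization_factors")
}

#' Standardize an image stack to the reference microscope
#'
#' Divides each layer of a raw (count) or flux stack by the per-layer
#' standardization factor of the microscope it was scanned on. Because the
#' factor is a per-layer scalar this commutes with exposure normalization.
#' The output is real-valued; pass `quantize = TRUE` to re-quantize to
#' unsigned 16-bit counts (round-half-even, clipped at 65535, with the
#' clipped-pixel count attached as attribute `"n_clipped"`).
#'
#' @param stack H x W x K numeric array (counts or flux).
#' @param m Microscope index (or id) of the stack.
#' @param std_factors A `standardization_factors` object.
#' @param quantize Re-quantize to 16-bit counts (default FALSE).
#' @return Numeric (or integer, when quantized) H x W x K array.
#' @export
standardize_stack <- function(stack, m, std_factors, quantize = FALSE) {
  fac <- std_factors$factors
  if (is.character(m)) m <- match(m, std_factors$microscope_ids)
  if (is.na(m) || m < 1 || m > nrow(fac)) stopf("unknown microscope for standardization")
  d <- dim(stack)
  if (length(d) != 3L || d[3] != ncol(fac)) stopf("stack layers do not match factors")
  out <- sweep(array(as.numeric(stack), d), 3L, fac[m, ], "/")
  if (quantize) {
    n_clipped <- sum(out > 65535)
    out <- pmin(pmax(round(out), 0), 65535)
    storage.mode(out) <- "integer"
    attr(out, "n_clipped") <- n_clipped
  }
  out
}
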