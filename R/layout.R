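#' Construct a broadband filter layout
#'
#' A filter layout records how the K narrowband image layers of a
#' multispectral stack are grouped by the static broadband filter cube
#' through which they were acquired. Exposure times are set per broadband
#' group during acquisition, so the layout drives exposure normalization and
#' the broadband/narrowband decomposition of microscope correction factors.
#'
#' Layers are indexed 1-based, following the R convention; the order of
#' layers in the layout defines the layer index `k` used everywhere else.
#'
#' @param groups Named list of integer vectors; each element is one broadband
#'   group and holds the (1-based) indices of its member layers.
#' @param K Total number of layers. Defaults to the number of layer indices
#'   present in `groups`.
#' @return An object of class `filter_layout` with fields `groups`, `K`, and
#'   `group_of` (integer vector of length K mapping each layer to its group).
#' @examples
#' lay <- filter_layout(list(blue = 1:3, red = 4:6))
#' lay$K
#' @export
filter_layout <- function(groups, K = NULL) {
  if (!is.list(groups) || length(groups) == 0L) {
    stopf("layout error: 'groups' must be a non-empty list of layer index vectors")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  groups <- lapply(groups, function(g) as.integer(g))
  K <- as.integer(K %||% length(unlist(groups)))
  layout <- structure(
    list(groups = groups, K = K,
         group_of = integer(K)),
    class = "filter_layout"
  )
  validate_layout(layout)
}

#' Validate a filter layout
#'
#' Checks that the broadband groups partition the layer set exactly: every
#' layer 1..K appears in exactly one non-empty group.
#'
#' @param layout A `filter_layout`.
#' @return The layout, with its `group_of` map filled in.
#' @export
validate_layout <- function(layout) {
  if (!inherits(layout, "filter_layout")) stopf("layout error: not a filter_layout")
  K <- layout$K
  if (!is_count(K) || K < 1L) stopf("layout error: K must be a positive integer")
  seen <- integer(0)
  group_of <- integer(K)
  for (gi in seq_along(layout$groups)) {
    g <- layout$groups[[gi]]
    if (length(g) == 0L) {
      stopf("layout error: group '%s' is empty", names(layout$groups)[gi])
    }
    bad <- g[g < 1L | g > K]
    if (length(bad) > 0L) {
      stopf("layout error: layer %d outside 1..%d in group '%s'",
            bad[1], K, names(layout$groups)[gi])
    }
    dup <- intersect(g, seen)
    if (length(dup) > 0L) {
      stopf("layout error: layer %d appears in more than one group", dup[1])
    }
    seen <- c(seen, g)
    group_of[g] <- gi
  }
  missing <- setdiff(seq_len(K), seen)
  if (length(missing) > 0L) {
    stopf("layout error: layer %d is not assigned to any group", missing[1])
  }
  layout$group_of <- group_of
  layout
}

#' Default filter layout
#'
#' A placeholder layout partitioning `K` layers into `n_groups` contiguous,
#' near-equal blocks. The true layer-to-broadband-filter mapping of a given
#' scanner model is instrument documentation and should replace this default
#' via [filter_layout()] in any real analysis; the shipped default exists so
#' the pipeline runs end to end with the conventional 43 layers and 7
#' broadband cubes.
#'
#' @param K Number of layers (default 43).
#' @param n_groups Number of broadband groups (default 7).
#' @return A `filter_layout`.
#' @export
default_filter_layout <- function(K = 43L, n_groups = 7L) {
  K <- as.integer(K); n_groups <- as.integer(n_groups)
  if (n_groups > K) stopf("layout error: more groups than layers")
  sizes <- rep(K %/% n_groups, n_groups)
  extra <- K %% n_groups
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  groups <- Map(function(s, e) s:e, starts, ends)
  names(groups) <- paste0("BB", seq_len(n_groups))
  filter_layout(groups, K = K)
}

#' @export
print.filter_layout <- function(x, ...) {
  cat(sprintf("filter_layout: K = %d layers in %d broadband groups\n",
              x$K, length(x$groups)))
  for (nm in names(x$groups)) {
    g <- x$groups[[nm]]
    cat(sprintf("  %s: %d layers (%s)\n", nm, length(g),
                paste(range(g), collapse = "-")))
  }
  invisible(x)
}
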