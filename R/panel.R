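#' Cytometry panel configuration
#'
#' Bundles everything the preprocessing and gating stages need to know about
#' an acquisition panel: the fluorescence channels, linear spillover terms,
#' per-channel normalization bounds and positivity thresholds, and (for
#' nearest-centroid gating of singly marked populations) per-population
#' reference positions in log10 intensity space.
#'
#' @param channels Character vector of fluorescence channel names, in the
#'   order they appear in event tables.
#' @param colors Optional named character vector mapping colour letters onto
#'   channels, e.g. `c(R = "mCherry", G = "Venus", B = "Cerulean")`. Required
#'   for octant gating and cube coordinates.
#' @param spillover Optional data frame with columns `target`, `source`,
#'   `coefficient` describing linear spillover of `source` emission into the
#'   `target` detector. Row order is the order in which compensation is
#'   applied (see [compensate()]).
#' @param bounds Optional named list; each element is `c(I_lower, I_upper)`
#'   in raw intensity units for one channel, with `0 < I_lower < I_upper`.
#'   Used by [normalize_intensity()] / [cube_coordinates()].
#' @param thresholds Optional named numeric vector of positivity thresholds
#'   (raw intensity units). Defaults to the lower bound of each channel.
#' @param centroids Optional numeric matrix of log10 intensities, one row per
#'   population (rownames are the population labels), one column per channel.
#'   Used by [classify_four_color()].
#' @param floor_value Small positive intensity to which non-positive values
#'   are floored after compensation so log transforms stay defined.
#'
#' @return An object of class `panel_config`.
#' @seealso [case1_panel()], [case2_panel()]
#' @export
panel_config <- function(channels, colors = NULL, spillover = NULL,
                         bounds = NULL, thresholds = NULL,
                         centroids = NULL, floor_value = 1) {
  stopifnot(is.character(channels), length(channels) > 0)
  if (anyDuplicated(channels)) stop("duplicated channel names")
  if (!is.null(spillover)) {
    spillover <- as.data.frame(spillover)
    if (!all(c("target", "source", "coefficient") %in% names(spillover)))
      stop("spillover needs columns target, source, coefficient")
    if (any(spillover$coefficient < 0))
      stop("spillover coefficients must be >= 0")
    bad <- setdiff(unique(c(spillover$target, spillover$source)), channels)
    if (length(bad))
      stop("spillover refers to unknown channel(s): ",
           paste(bad, collapse = ", "))
  }
  if (!is.null(bounds)) {
    stopifnot(is.list(bounds), !is.null(names(bounds)))
    for (ch in names(bounds)) {
      b <- bounds[[ch]]
      if (length(b) != 2 || !is.finite(b[1]) || !is.finite(b[2]) ||
          !(0 < b[1] && b[1] < b[2]))
        stop("bounds for ", ch, " must satisfy 0 < I_lower < I_upper")
    }
  }
  if (is.null(thresholds) && !is.null(bounds))
    thresholds <- vapply(bounds, function(b) b[1], numeric(1))
  if (!is.null(thresholds)) {
    if (any(thresholds <= 0)) stop("positivity thresholds must be > 0")
    if (is.null(names(thresholds))) stop("thresholds must be named")
  }
  if (!is.null(colors)) {
    if (is.null(names(colors)) || !all(colors %in% channels))
      stop("colors must be a named map onto panel channels")
  }
  if (!is.null(centroids)) {
    centroids <- as.matrix(centroids)
    if (is.null(rownames(centroids)))
      stop("centroids need rownames (population labels)")
    if (is.null(colnames(centroids))) colnames(centroids) <- channels
    if (!all(colnames(centroids) %in% channels))
      stop("centroid columns must be panel channels")
  }
  stopifnot(is.numeric(floor_value), floor_value > 0)
  structure(
    list(channels = channels, colors = colors, spillover = spillover,
         bounds = bounds, thresholds = thresholds, centroids = centroids,
         floor_value = floor_value),
    class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat("<panel_config> channels:", paste(x$channels, collapse = ", "), "\n")
  if (!is.null(x$spillover))
    cat("  spillover terms:", nrow(x$spillover), "\n")
  if (!is.null(x$bounds))
    cat("  bounds for:", paste(names(x$bounds), collapse = ", "), "\n")
  if (!is.null(x$centroids))
    cat("  centroids for:", paste(rownames(x$centroids), collapse = ", "), "\n")
  invisible(x)
}

#' Three-colour RGB-marking panel (case study I)
#'
#' The panel used for octant gating of RGB-marked cells: mCherry (red,
#' 488 nm / 690/50), Venus (green, 488 nm / 585/40) and Cerulean (blue,
#' 405 nm / 525/40). Spillover is compensated sequentially, Venus minus
#' 0.15 x mCherry first, then Cerulean minus 0.039 x Venus. Normalization
#' bounds are I_lower = 1e3 for all channels and I_upper = 2e5 (mCherry),
#' 1e7 (Venus) and 2e5 (Cerulean); positivity is defined as intensity above
#' I_lower.
#'
#' @return A [panel_config()] object.
#' @export
case1_panel <- function() {
  panel_config(
    channels = c("mCherry", "Venus", "Cerulean"),
    colors = c(R = "mCherry", G = "Venus", B = "Cerulean"),
    spillover = data.frame(
      target = c("Venus", "Cerulean"),
      source = c("mCherry", "Venus"),
      coefficient = c(0.15, 0.039)),
    bounds = list(mCherry  = c(1e3, 2e5),
                  Venus    = c(1e3, 1e7),
                  Cerulean = c(1e3, 2e5)))
}

#' Two-channel four-population panel (case study II)
#'
#' Two detectors suffice to separate four singly marked populations:
#' the 405 nm laser with a 450/45 filter (mTagBFP and Cerulean, at
#' different intensities) and the 488 nm laser with a 585/42 filter
#' (Venus and mOrange2). No compensation is applied. Centroids are the
#' expected log10 positions of the four clusters; events are assigned by
#' nearest centroid in log space.
#'
#' @return A [panel_config()] object.
#' @export
case2_panel <- function() {
  centroids <- rbind(
    "Cerulean-EX" = c(3.8, 2.2),
    "mOrange2-LE" = c(2.2, 3.8),
    "mTagBFP-TP"  = c(5.0, 2.2),
    "Venus-SP"    = c(2.2, 5.2))
  colnames(centroids) <- c("FL_450_45", "FL_585_42")
  panel_config(
    channels = c("FL_450_45", "FL_585_42"),
    bounds = list(FL_450_45 = c(1e2, 1e6), FL_585_42 = c(1e2, 1e7)),
    centroids = centroids)
}
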